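#' Combined bacteria / leukocyte screening rule
#'
#' The combined screen flags a sample when either channel reaches its
#' cut-off: positive iff `bacteria >= t_bac` OR `wbc >= t_wbc`. Setting one
#' threshold to `+Inf` silences that channel, degrading the rule to a
#' single-marker screen. An `"and"` combiner is available for completeness
#' but the OR form is the one screening laboratories report.
#'
#' @param t_bac,t_wbc Channel cut-offs in counts/uL; `+Inf` allowed.
#' @param combiner `"or"` (default) or `"and"`.
#' @return An object of class `dual_rule`.
#' @examples
#' dual_rule(138, 119.8)
#' @export
dual_rule <- function(t_bac, t_wbc, combiner = c("or", "and")) {
  combiner <- match.arg(combiner)
  for (nm in c("t_bac", "t_wbc")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      abort_contract("`", nm, "` must be a single non-negative number (Inf allowed)")
  }
  structure(list(t_bac = as.numeric(t_bac), t_wbc = as.numeric(t_wbc),
                 combiner = combiner),
            class = "dual_rule")
}

#' @export
print.dual_rule <- function(x, ...) {
  cat("<dual_rule> bacteria >= ", format(x$t_bac), "/uL ",
      toupper(x$combiner), " WBC >= ", format(x$t_wbc), "/uL\n", sep = "")
  invisible(x)
}

#' Apply a screening rule to counts or to a cohort
#'
#' @param rule A [dual_rule()].
#' @param bacteria Numeric bacteria counts (counts/uL), or a
#'   [urine_cohort()] whose count columns are used.
#' @param wbc Numeric WBC counts, required unless `bacteria` is a cohort.
#' @return Integer 0/1 screen labels.
#' @examples
#' apply_rule(dual_rule(138, 119.8), bacteria = c(150, 0, 0), wbc = c(0, 0, 200))
#' @export
apply_rule <- function(rule, bacteria, wbc = NULL) {
  if (!inherits(rule, "dual_rule"))
    abort_contract("`rule` must be a dual_rule")
  if (inherits(bacteria, "urine_cohort")) {
    wbc <- bacteria$samples$wbc_per_uL
    bacteria <- bacteria$samples$bacteria_per_uL
  }
  if (!is.numeric(bacteria) || !is.numeric(wbc))
    abort_contract("`bacteria` and `wbc` must be numeric")
  if (length(bacteria) != length(wbc))
    abort_contract("`bacteria` and `wbc` must have equal length")
  if (anyNA(bacteria) || anyNA(wbc))
    abort_contract("missing count: both channels are required to apply a rule")
  hit <- if (rule$combiner == "or") {
    bacteria >= rule$t_bac | wbc >= rule$t_wbc
  } else {
    bacteria >= rule$t_bac & wbc >= rule$t_wbc
  }
  as.integer(hit)
}

# Candidate threshold grid: the distinct observed values plus the +Inf
# sentinel (so every reported cut-off is a realizable machine reading),
# sorted decreasing. An explicit grid overrides the observed values.
threshold_grid <- function(values, grid = NULL) {
  g <- if (is.null(grid)) c(Inf, values) else grid
  sort(unique(g), decreasing = TRUE)
}

# Exhaustive product-grid search for the OR rule with incremental confusion
# updates. Rows sweep the bacteria grid top-down; samples caught by the
# bacteria channel leave the per-WBC-bin tallies, so each row costs one
# cumulative sum over the WBC grid: O(|grid_bac| * |grid_wbc|) overall.
# All comparisons use integer cell counts, making tie-breaks exact.
dual_search <- function(bac, wbc, truth, criterion = c("se_floor", "youden"),
                        se_target = 0.95, bac_grid = NULL, wbc_grid = NULL,
                        pareto = FALSE) {
  criterion <- if (pareto) NULL else match.arg(criterion)
  truth <- as_binary01(truth, "truth")
  n <- length(truth)
  if (length(bac) != n || length(wbc) != n)
    abort_contract("count vectors and truth must have equal length")
  if (anyNA(bac) || anyNA(wbc))
    abort_contract("missing counts in cohort")
  P <- sum(truth == 1L); N <- n - P
  if (P == 0L || N == 0L)
    abort_contract("optimization undefined: need both culture classes present")

  tb <- threshold_grid(bac, bac_grid)
  tw <- threshold_grid(wbc, wbc_grid)
  B <- length(tb); W <- length(tw)

  # first grid row/bin at which each sample is at or above the threshold
  row_of <- function(x, thr_desc) {
    k <- findInterval(x, rev(thr_desc))     # number of thresholds <= x
    ifelse(k == 0L, 0L, length(thr_desc) - k + 1L)
  }
  i0 <- row_of(bac, tb)   # 0 = never caught by bacteria channel
  j0 <- row_of(wbc, tw)   # 0 = never counted by WBC channel

  pos_bins <- tabulate(j0[truth == 1L], nbins = W)
  neg_bins <- tabulate(j0[truth == 0L], nbins = W)
  caught_at <- split(seq_len(n), factor(i0, levels = seq_len(B)))

  if (!pareto) {
    se_floor <- !is.null(criterion) && criterion == "se_floor"
    if (se_floor) {
      se_target <- check_scalar_number(se_target, "se_target")
      if (se_target <= 0 || se_target > 1)
        abort_contract("`se_target` must lie in (0, 1], got ", format(se_target))
      tp_min <- ceiling(se_target * P - 1e-9)
    }
    best <- NULL          # list(key1, key2, i, j)
    max_tp <- 0L
  } else {
    pareto_tp <- vector("list", B); pareto_fp <- vector("list", B)
    pareto_i <- vector("list", B); pareto_j <- vector("list", B)
  }

  P_caught <- 0L; N_caught <- 0L
  for (i in seq_len(B)) {
    newly <- caught_at[[i]]
    if (length(newly)) {
      np <- newly[truth[newly] == 1L]
      nn <- newly[truth[newly] == 0L]
      P_caught <- P_caught + length(np)
      N_caught <- N_caught + length(nn)
      if (length(np)) pos_bins <- pos_bins - tabulate(j0[np], nbins = W)
      if (length(nn)) neg_bins <- neg_bins - tabulate(j0[nn], nbins = W)
    }
    tp_row <- P_caught + cumsum(pos_bins)
    fp_row <- N_caught + cumsum(neg_bins)

    if (pareto) {
      keep <- which(!duplicated(tp_row))   # lowest fp for each distinct tp
      pareto_tp[[i]] <- tp_row[keep]; pareto_fp[[i]] <- fp_row[keep]
      pareto_i[[i]] <- rep.int(i, length(keep)); pareto_j[[i]] <- keep
      next
    }
    if (se_floor) {
      max_tp <- max(max_tp, tp_row[W])
      ok <- tp_row >= tp_min
      if (!any(ok)) next
      j <- order(-ok, fp_row, -tp_row, seq_len(W))[1L]
      key <- c(-fp_row[j], tp_row[j])
    } else {
      j <- order(-(tp_row * N - fp_row * P), -tp_row, seq_len(W))[1L]
      key <- c(tp_row[j] * N - fp_row[j] * P, tp_row[j])
    }
    # strict lexicographic improvement; ties keep the earlier row
    # (higher t_bac), then the earlier column (higher t_wbc)
    if (is.null(best) || key[1L] > best$key[1L] ||
        (key[1L] == best$key[1L] && key[2L] > best$key[2L])) {
      best <- list(key = key, i = i, j = j,
                   tp = tp_row[j], fp = fp_row[j])
    }
  }

  if (pareto) {
    cand <- list(tp = unlist(pareto_tp), fp = unlist(pareto_fp),
                 i = unlist(pareto_i), j = unlist(pareto_j))
    # dominance filter: sort by se desc then fp asc then stricter rule;
    # sweep keeping strict improvements in fp (dedupes equal (se, sp))
    ord <- order(-cand$tp, cand$fp, cand$i, cand$j)
    keep <- logical(length(ord))
    min_fp <- Inf
    for (k in ord) {
      if (cand$fp[k] < min_fp) { keep[k] <- TRUE; min_fp <- cand$fp[k] }
    }
    idx <- which(keep)
    idx <- idx[order(-cand$tp[idx], cand$i[idx])]
    return(list(tb = tb, tw = tw, P = P, N = N,
                tp = cand$tp[idx], fp = cand$fp[idx],
                i = cand$i[idx], j = cand$j[idx]))
  }

  if (is.null(best))
    abort_contract("sensitivity floor ", format(se_target),
                   " unachievable: max achievable se = ", format(max_tp / P))
  cm <- confusion_matrix(tp = best$tp, fp = best$fp,
                         tn = N - best$fp, fn = P - best$tp)
  list(rule = dual_rule(tb[best$i], tw[best$j]),
       metrics = metrics_from_confusion(cm),
       confusion = cm,
       criterion = criterion,
       se_target = if (se_floor) se_target else NULL,
       grid_size = c(bacteria = B, wbc = W))
}

#' Jointly optimal dual-threshold screening rule
#'
#' Exhaustively evaluates every pair of candidate cut-offs (observed values
#' plus `+Inf` in each channel) for the OR rule and returns the optimum
#' under the chosen criterion. `"se_floor"` (the default) maximizes
#' specificity subject to sensitivity at or above `se_target`, matching the
#' guideline that a culture screen keep sensitivity above 90--95%;
#' `"youden"` maximizes Se + Sp - 1. Ties prefer higher sensitivity, then
#' higher bacteria cut-off, then higher WBC cut-off.
#'
#' @param cohort A [urine_cohort()].
#' @param criterion `"se_floor"` or `"youden"`.
#' @param se_target Sensitivity floor in `(0, 1]`.
#' @param bac_grid,wbc_grid Optional explicit candidate threshold vectors
#'   replacing the observed-value grids (e.g. `wbc_grid = Inf` restricts
#'   the search to a bacteria-only rule).
#' @return A list of class `dual_opt` with `rule` ([dual_rule()]),
#'   `metrics` (`metric_set`), `confusion`, `criterion`, and `grid_size`.
#' @export
optimize_dual <- function(cohort, criterion = c("se_floor", "youden"),
                          se_target = 0.95, bac_grid = NULL, wbc_grid = NULL) {
  if (!inherits(cohort, "urine_cohort"))
    abort_contract("`cohort` must be a urine_cohort")
  res <- dual_search(cohort$samples$bacteria_per_uL,
                     cohort$samples$wbc_per_uL,
                     culture_truth(cohort),
                     criterion = match.arg(criterion),
                     se_target = se_target,
                     bac_grid = bac_grid, wbc_grid = wbc_grid)
  class(res) <- "dual_opt"
  res
}

#' @export
print.dual_opt <- function(x, ...) {
  cat("<dual_opt> criterion:", x$criterion,
      if (!is.null(x$se_target)) paste0("(se >= ", x$se_target, ")"), "\n")
  print(x$rule)
  print(x$metrics)
  invisible(x)
}

#' Pareto front of dual-threshold operating points
#'
#' All (sensitivity, specificity) operating points over the product grid of
#' candidate cut-offs that are not dominated by any other pair; every grid
#' pair is dominated by, or ties, some member. Equal (Se, Sp) duplicates
#' keep the stricter rule (higher cut-offs).
#'
#' @param cohort A [urine_cohort()].
#' @param bac_grid,wbc_grid Optional explicit candidate grids.
#' @return A tibble with columns `t_bac`, `t_wbc`, `se`, `sp`, `ppv`,
#'   `npv`, `reduction`, ordered by decreasing sensitivity.
#' @export
pareto_front <- function(cohort, bac_grid = NULL, wbc_grid = NULL) {
  if (!inherits(cohort, "urine_cohort"))
    abort_contract("`cohort` must be a urine_cohort")
  res <- dual_search(cohort$samples$bacteria_per_uL,
                     cohort$samples$wbc_per_uL,
                     culture_truth(cohort),
                     bac_grid = bac_grid, wbc_grid = wbc_grid,
                     pareto = TRUE)
  n <- res$P + res$N
  tn <- res$N - res$fp
  fn <- res$P - res$tp
  ppv <- ifelse(res$tp + res$fp == 0, NA_real_, res$tp / (res$tp + res$fp))
  npv <- ifelse(tn + fn == 0, NA_real_, tn / (tn + fn))
  tibble::tibble(t_bac = res$tb[res$i], t_wbc = res$tw[res$j],
                 se = res$tp / res$P, sp = tn / res$N,
                 ppv = ppv, npv = npv,
                 reduction = (tn + fn) / n)
}
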