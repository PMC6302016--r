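# Fixture builders and independent brute-force oracles. The oracles share no
# code with the package's sweep/search implementations: AUC is counted over
# all positive-negative pairs, and the dual-rule optimum is found by a naive
# double loop that re-screens the whole cohort at every grid pair.

make_cohort <- function(bac, wbc, truth, device = "DEV", contaminated = FALSE,
                        cfu = NULL, label_config = culture_config()) {
  n <- length(bac)
  truth <- as.integer(truth)
  if (is.null(cfu)) cfu <- ifelse(truth == 1L, 2e5, 1e3)
  urine_cohort(tibble::tibble(
    sample_id = sprintf("t%04d", seq_len(n)),
    device = device,
    bacteria_per_uL = bac,
    wbc_per_uL = wbc,
    culture_cfu_per_mL = cfu,
    contaminated = contaminated
  ), label_config = label_config)
}

random_instance <- function(n, p_pos = 0.4, max_val = 20, allow_ties = TRUE) {
  truth <- rbinom(n, 1, p_pos)
  if (all(truth == 1)) truth[1] <- 0L
  if (all(truth == 0)) truth[1] <- 1L
  draw <- function(shift) {
    v <- if (allow_ties) sample(0:max_val, n, replace = TRUE)
         else runif(n, 0, max_val)
    v + shift * truth
  }
  list(bac = draw(sample(0:max_val, 1)), wbc = draw(sample(0:max_val, 1)),
       truth = truth)
}

# AUC as the Mann-Whitney pair count: P(pos > neg) + 0.5 P(pos = neg)
auc_pair_oracle <- function(values, truth) {
  pos <- values[truth == 1]
  neg <- values[truth == 0]
  total <- 0
  for (x in pos) total <- total + sum(x > neg) + 0.5 * sum(x == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive single-marker scan under the package's stated tie-break
# (criterion, then higher se, then higher threshold), on integer counts.
single_cutoff_oracle <- function(values, truth, criterion, se_target = 0.95) {
  thr <- sort(unique(c(Inf, values)), decreasing = TRUE)
  P <- sum(truth == 1); N <- sum(truth == 0)
  tp <- vapply(thr, function(t) sum(truth == 1 & values >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(truth == 0 & values >= t), numeric(1))
  if (criterion == "youden") {
    ord <- order(-(tp * N - fp * P), -tp, seq_along(thr))
    k <- ord[1]
  } else {
    ok <- tp >= ceiling(se_target * P - 1e-9)
    ord <- order(-ok, fp, -tp, seq_along(thr))
    k <- ord[1]
  }
  list(threshold = thr[k], se = tp[k] / P, sp = 1 - fp[k] / N)
}

# Naive double-loop optimum of the OR rule over the full product grid.
dual_oracle <- function(bac, wbc, truth, criterion, se_target = 0.95) {
  tb <- sort(unique(c(Inf, bac)), decreasing = TRUE)
  tw <- sort(unique(c(Inf, wbc)), decreasing = TRUE)
  P <- sum(truth == 1); N <- sum(truth == 0)
  best <- NULL
  for (i in seq_along(tb)) {
    for (j in seq_along(tw)) {
      scr <- bac >= tb[i] | wbc >= tw[j]
      tp <- sum(scr & truth == 1)
      fp <- sum(scr & truth == 0)
      key <- if (criterion == "youden") c(tp * N - fp * P, tp)
             else if (tp >= ceiling(se_target * P - 1e-9)) c(-fp, tp)
             else NULL
      if (is.null(key)) next
      if (is.null(best) || key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2])) {
        best <- list(key = key, t_bac = tb[i], t_wbc = tw[j],
                     se = tp / P, sp = 1 - fp / N)
      }
    }
  }
  best
}

# O(grid^2) dominance filter over all distinct (se, sp) grid points.
pareto_oracle <- function(bac, wbc, truth) {
  tb <- sort(unique(c(Inf, bac)), decreasing = TRUE)
  tw <- sort(unique(c(Inf, wbc)), decreasing = TRUE)
  P <- sum(truth == 1); N <- sum(truth == 0)
  g <- expand.grid(i = seq_along(tb), j = seq_along(tw))
  se <- sp <- numeric(nrow(g))
  for (k in seq_len(nrow(g))) {
    scr <- bac >= tb[g$i[k]] | wbc >= tw[g$j[k]]
    se[k] <- sum(scr & truth == 1) / P
    sp[k] <- sum(!scr & truth == 0) / N
  }
  pts <- unique(data.frame(se = se, sp = sp))
  dominated <- vapply(seq_len(nrow(pts)), function(k) {
    any(pts$se >= pts$se[k] & pts$sp >= pts$sp[k] &
          (pts$se > pts$se[k] | pts$sp > pts$sp[k]))
  }, logical(1))
  front <- pts[!dominated, ]
  front[order(-front$se, front$sp), ]
}
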