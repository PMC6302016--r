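#' Evaluate a screening rule on a cohort
#'
#' Runs the full accounting for one device and one culture threshold:
#' screen labels from the rule, confusion against culture truth, the
#' metric set, and Wilson intervals for Se, Sp, PPV and NPV. Percentage
#' fields are rounded views; the underlying proportions keep full
#' precision.
#'
#' @param cohort A [urine_cohort()].
#' @param rule A [dual_rule()], or a single number interpreted as a
#'   bacteria-only cut-off (`dual_rule(t, Inf)`).
#' @param label_config Optional [culture_config()] overriding the
#'   cohort's own (e.g. to re-score truth at 1e4 CFU/mL).
#' @param ci_level Confidence level for the Wilson intervals.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_rule <- function(cohort, rule, label_config = NULL, ci_level = 0.95) {
  if (!inherits(cohort, "urine_cohort"))
    abort_contract("`cohort` must be a urine_cohort")
  if (is.numeric(rule) && length(rule) == 1L)
    rule <- dual_rule(rule, Inf)
  if (!inherits(rule, "dual_rule"))
    abort_contract("`rule` must be a dual_rule or a single bacteria cut-off")
  cfg <- label_config %||% cohort$label_config
  truth <- culture_truth(cohort, cfg)
  screen <- apply_rule(rule, cohort)
  cm <- confusion_from_predictions(truth, screen)
  metrics <- metrics_from_confusion(cm)
  ci <- list(
    se = proportion_ci(cm$tp, cm$tp + cm$fn, ci_level),
    sp = proportion_ci(cm$tn, cm$tn + cm$fp, ci_level),
    ppv = if (cm$tp + cm$fp > 0) proportion_ci(cm$tp, cm$tp + cm$fp, ci_level),
    npv = if (cm$tn + cm$fn > 0) proportion_ci(cm$tn, cm$tn + cm$fn, ci_level)
  )
  structure(list(
    device = unique(cohort$samples$device),
    culture_threshold = cfg$cfu_threshold,
    rule = rule,
    metrics = metrics,
    confusion = cm,
    ci = ci,
    ci_level = ci_level,
    cohort_summary = list(
      n = nrow(cohort$samples),
      positives = sum(truth == 1L),
      negatives = sum(truth == 0L),
      contaminated = sum(cohort$samples$contaminated)
    )
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$cohort_summary
  cat("<evaluation_report> device:", paste(x$device, collapse = "/"),
      "| truth at", format(x$culture_threshold), "CFU/mL\n")
  cat("  cohort: n =", s$n, "(", s$positives, "positive,", s$negatives,
      "negative;", s$contaminated, "contaminated )\n")
  print(x$rule)
  print(x$metrics)
  fmt_ci <- function(ci) if (is.null(ci)) "undef" else
    paste0("[", paste(format(as_pct(ci)), collapse = ", "), "]%")
  cat("  ", 100 * x$ci_level, "% Wilson CIs: SE ", fmt_ci(x$ci$se),
      "  SP ", fmt_ci(x$ci$sp), "  PPV ", fmt_ci(x$ci$ppv),
      "  NPV ", fmt_ci(x$ci$npv), "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "evaluation_report"))
    abort_contract("`report` must be an evaluation_report")
  obj <- list(
    device = report$device,
    culture_threshold = report$culture_threshold,
    rule = list(t_bac = unbox_inf(report$rule$t_bac),
                t_wbc = unbox_inf(report$rule$t_wbc),
                combiner = report$rule$combiner),
    metrics = c(as.list(metric_row(report$metrics)),
                list(undefined = report$metrics$undefined)),
    confusion = report$confusion[c("tp", "fp", "tn", "fn")],
    ci = lapply(report$ci, function(x) if (is.null(x)) NULL else as.list(x)),
    ci_level = report$ci_level,
    cohort_summary = report$cohort_summary
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# JSON has no Inf literal; the sentinel threshold is stored as "Inf".
unbox_inf <- function(x) if (is.infinite(x)) "Inf" else x

#' Read an evaluation report written by [write_report()]
#'
#' @param path JSON path.
#' @return An `evaluation_report` equal to the one written.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    abort_io("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_num_inf <- function(x) if (identical(x, "Inf")) Inf else as.numeric(x)
  cm <- confusion_matrix(tp = obj$confusion$tp, fp = obj$confusion$fp,
                         tn = obj$confusion$tn, fn = obj$confusion$fn)
  ci <- lapply(obj$ci, function(x)
    if (is.null(x)) NULL else c(lower = x$lower, upper = x$upper))
  structure(list(
    device = obj$device,
    culture_threshold = obj$culture_threshold,
    rule = dual_rule(as_num_inf(obj$rule$t_bac), as_num_inf(obj$rule$t_wbc),
                     combiner = obj$rule$combiner),
    metrics = metrics_from_confusion(cm),
    confusion = cm,
    ci = ci[c("se", "sp", "ppv", "npv")],
    ci_level = obj$ci_level,
    cohort_summary = obj$cohort_summary
  ), class = "evaluation_report")
}

#' Compare two devices at matched sensitivity
#'
#' Optimizes each device's combined rule independently under the
#' sensitivity-floor criterion at `se_target` and reports the operating
#' points side by side -- the comparison screening studies make ("at the
#' same level of sensitivity, which device keeps specificity higher?").
#' Differences (A minus B) in specificity and workload reduction carry
#' bootstrap percentile intervals: samples are resampled with replacement
#' within each cohort and the metrics recomputed at the fixed optimized
#' rules.
#'
#' @param cohort_a,cohort_b [urine_cohort()] objects, one per device.
#' @param se_target Sensitivity floor used on both devices.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param ci_level Percentile interval level.
#' @return A list of class `device_comparison`: per-device `dual_opt`
#'   results, a side-by-side tibble, the differences, and their intervals.
#' @export
compare_devices <- function(cohort_a, cohort_b, se_target = 0.95,
                            n_boot = 1000, seed = 1L, ci_level = 0.95) {
  for (c_ in list(cohort_a, cohort_b))
    if (!inherits(c_, "urine_cohort"))
      abort_contract("both cohorts must be urine_cohort objects")
  opt <- lapply(list(a = cohort_a, b = cohort_b), function(co) {
    tryCatch(
      optimize_dual(co, criterion = "se_floor", se_target = se_target),
      uroscreen_contract_error = function(e)
        abort_contract("device '", paste(unique(co$samples$device), collapse = "/"),
                       "': ", conditionMessage(e))
    )
  })
  flds <- c("se", "sp", "ppv", "npv", "reduction")
  side_by_side <- tibble::tibble(
    device = vapply(list(cohort_a, cohort_b),
                    function(co) paste(unique(co$samples$device), collapse = "/"),
                    character(1)),
    t_bac = c(opt$a$rule$t_bac, opt$b$rule$t_bac),
    t_wbc = c(opt$a$rule$t_wbc, opt$b$rule$t_wbc)
  )
  for (f in flds)
    side_by_side[[f]] <- c(opt$a$metrics[[f]], opt$b$metrics[[f]])

  diffs <- c(sp = opt$a$metrics$sp - opt$b$metrics$sp,
             reduction = opt$a$metrics$reduction - opt$b$metrics$reduction)

  boot_stat <- function(cohort, rule, idx) {
    truth <- culture_truth(cohort)[idx]
    screen <- apply_rule(rule,
                         cohort$samples$bacteria_per_uL[idx],
                         cohort$samples$wbc_per_uL[idx])
    n <- length(idx)
    neg <- sum(truth == 0L)
    c(sp = if (neg == 0) NA_real_ else sum(truth == 0L & screen == 0L) / neg,
      reduction = sum(screen == 0L) / n)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  na <- nrow(cohort_a$samples); nb <- nrow(cohort_b$samples)
  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("sp", "reduction")))
  for (b in seq_len(n_boot)) {
    sa <- boot_stat(cohort_a, opt$a$rule, sample.int(na, na, replace = TRUE))
    sb <- boot_stat(cohort_b, opt$b$rule, sample.int(nb, nb, replace = TRUE))
    boot[b, ] <- sa - sb
  }
  alpha <- (1 - ci_level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE)
  structure(list(
    se_target = se_target,
    device_a = opt$a, device_b = opt$b,
    side_by_side = side_by_side,
    differences = diffs,
    ci = list(sp = c(lower = unname(ci[1, "sp"]), upper = unname(ci[2, "sp"])),
              reduction = c(lower = unname(ci[1, "reduction"]),
                            upper = unname(ci[2, "reduction"]))),
    ci_level = ci_level, n_boot = n_boot, seed = as.integer(seed)
  ), class = "device_comparison")
}

#' @export
print.device_comparison <- function(x, ...) {
  cat("<device_comparison> se_floor(", x$se_target, "), ", x$n_boot,
      " bootstrap resamples\n", sep = "")
  print(x$side_by_side)
  cat("  A - B: SP ", format(round(x$differences[["sp"]], 4)),
      " [", paste(format(round(x$ci$sp, 4)), collapse = ", "), "]",
      " | reduction ", format(round(x$differences[["reduction"]], 4)),
      " [", paste(format(round(x$ci$reduction, 4)), collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}
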