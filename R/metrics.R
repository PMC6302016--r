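#' Confusion matrix for a screening rule against culture
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts; at least one cell
#'   must be positive.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (!is.numeric(cells) || length(cells) != 4L || anyNA(cells) ||
      any(cells < 0) || any(cells != round(cells)))
    abort_contract("confusion cells must be non-negative integers")
  if (sum(cells) < 1)
    abort_contract("confusion matrix must count at least one sample")
  cells <- stats::setNames(as.integer(cells), c("tp", "fp", "tn", "fn"))
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(screen = c("positive", "negative"),
                              culture = c("positive", "negative")))
  cat("<confusion_matrix> n =", x$tp + x$fp + x$tn + x$fn, "\n")
  print(m)
  invisible(x)
}

#' Tally a confusion matrix from paired truth and screen labels
#'
#' @param truth,screen Equal-length binary label vectors (logical, 0/1, or
#'   `"positive"`/`"negative"`); `truth` is the culture call, `screen` the
#'   analyser call.
#' @return A [confusion_matrix()].
#' @examples
#' confusion_from_predictions(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_from_predictions <- function(truth, screen) {
  truth <- as_binary01(truth, "truth")
  screen <- as_binary01(screen, "screen")
  if (length(truth) != length(screen))
    abort_contract("`truth` and `screen` must have equal length (",
                   length(truth), " vs ", length(screen), ")")
  if (length(truth) < 1L)
    abort_contract("need at least one sample")
  confusion_matrix(tp = sum(truth == 1L & screen == 1L),
                   fp = sum(truth == 0L & screen == 1L),
                   tn = sum(truth == 0L & screen == 0L),
                   fn = sum(truth == 1L & screen == 0L))
}

new_metric_set <- function(se, sp, ppv, npv, accuracy, reduction, prevalence,
                           undefined = character()) {
  structure(list(se = se, sp = sp, ppv = ppv, npv = npv, accuracy = accuracy,
                 reduction = reduction, prevalence = prevalence,
                 undefined = undefined),
            class = "metric_set")
}

#' Screening accuracy metrics from a confusion matrix
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value, accuracy, prevalence, and the culture-workload *reduction*: the
#' fraction of samples screened out, `(tn + fn) / n` -- every screen-negative
#' sample is a culture plate not set up. A metric whose denominator is zero
#' (e.g. PPV with no screen-positives) is returned as `NA` and named in the
#' `undefined` field rather than silently reported as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metric_set` with fields `se`, `sp`, `ppv`,
#'   `npv`, `accuracy`, `reduction`, `prevalence` (proportions in `[0, 1]`)
#'   and `undefined` (character vector of flagged metrics).
#' @examples
#' metrics_from_confusion(confusion_matrix(tp = 203, fp = 298, tn = 709, fn = 10))
#' @export
metrics_from_confusion <- function(cm) {
  if (!inherits(cm, "confusion_matrix"))
    abort_contract("`cm` must be a confusion_matrix")
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  se  <- safe_ratio(cm$tp, cm$tp + cm$fn)
  sp  <- safe_ratio(cm$tn, cm$tn + cm$fp)
  ppv <- safe_ratio(cm$tp, cm$tp + cm$fp)
  npv <- safe_ratio(cm$tn, cm$tn + cm$fn)
  vals <- c(se = se, sp = sp, ppv = ppv, npv = npv)
  new_metric_set(se, sp, ppv, npv,
                 accuracy = (cm$tp + cm$tn) / n,
                 reduction = (cm$tn + cm$fn) / n,
                 prevalence = (cm$tp + cm$fn) / n,
                 undefined = names(vals)[is.na(vals)])
}

#' Predictive values and workload reduction from rates alone
#'
#' The Bayes identities linking an operating point (sensitivity,
#' specificity) and a prevalence to the predictive values and the
#' screened-out fraction:
#' \deqn{PPV = \frac{Se\,p}{Se\,p + (1-Sp)(1-p)}, \quad
#'       NPV = \frac{Sp\,(1-p)}{Sp\,(1-p) + (1-Se)\,p},}
#' \deqn{reduction = Sp\,(1-p) + (1-Se)\,p, \quad
#'       accuracy = Se\,p + Sp\,(1-p).}
#' On any confusion matrix these reproduce [metrics_from_confusion()]
#' exactly; they also audit published Se/Sp/PPV/NPV tables for internal
#' consistency when the raw data are unavailable.
#'
#' @param se,sp,prevalence Proportions in `[0, 1]`.
#' @return A `metric_set` (see [metrics_from_confusion()]).
#' @examples
#' # a published combined-rule operating point at 17.4% prevalence
#' rates_to_predictive_values(0.953, 0.704, 213 / 1220)
#' @export
rates_to_predictive_values <- function(se, sp, prevalence) {
  se <- check_scalar_prob(se, "se")
  sp <- check_scalar_prob(sp, "sp")
  p <- check_scalar_prob(prevalence, "prevalence")
  num_ppv <- se * p
  den_ppv <- se * p + (1 - sp) * (1 - p)
  num_npv <- sp * (1 - p)
  den_npv <- sp * (1 - p) + (1 - se) * p
  ppv <- if (den_ppv == 0) NA_real_ else num_ppv / den_ppv
  npv <- if (den_npv == 0) NA_real_ else num_npv / den_npv
  undefined <- c("ppv", "npv")[c(is.na(ppv), is.na(npv))]
  new_metric_set(se, sp, ppv, npv,
                 accuracy = se * p + sp * (1 - p),
                 reduction = sp * (1 - p) + (1 - se) * p,
                 prevalence = p,
                 undefined = undefined)
}

#' @export
print.metric_set <- function(x, digits = 1, ...) {
  flds <- c("se", "sp", "ppv", "npv", "accuracy", "reduction")
  pct <- vapply(flds, function(f)
    if (is.na(x[[f]])) "undef" else paste0(format(as_pct(x[[f]], digits)), "%"),
    character(1))
  cat("<metric_set>", paste(toupper(flds), pct, collapse = " | "), "\n")
  cat("  prevalence:", paste0(format(as_pct(x$prevalence, digits)), "%"), "\n")
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  as.data.frame(metric_row(x))
}

metric_row <- function(x, digits = 1) {
  flds <- c("se", "sp", "ppv", "npv", "accuracy", "reduction", "prevalence")
  row <- as.list(stats::setNames(vapply(flds, function(f) x[[f]], numeric(1)), flds))
  for (f in flds) row[[paste0(f, "_pct")]] <- as_pct(row[[f]], digits)
  tibble::as_tibble(row)
}

#' Serialize a metric set to JSON or one-row CSV
#'
#' The CSV carries the proportions plus `*_pct` convenience columns rounded
#' half-up to one decimal; the JSON additionally records the undefined-flag
#' list.
#'
#' @param metrics A `metric_set`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`; defaults from the path extension.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, format = NULL) {
  if (!inherits(metrics, "metric_set"))
    abort_contract("`metrics` must be a metric_set")
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv")
  if (format == "json") {
    obj <- c(as.list(metric_row(metrics)), list(undefined = metrics$undefined))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "list")
  } else if (format == "csv") {
    readr::write_csv(metric_row(metrics), path, na = "")
  } else {
    abort_contract("`format` must be 'json' or 'csv'")
  }
  invisible(path)
}

#' Wilson score interval for a proportion
#'
#' @param successes,trials Non-negative integers, `successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level in `(0, 1)`, default 0.95.
#' @return Named numeric vector `c(lower, upper)`, a subset of `[0, 1]`
#'   containing `successes / trials`.
#' @examples
#' proportion_ci(203, 213)
#' @export
proportion_ci <- function(successes, trials, level = 0.95) {
  if (!is.numeric(successes) || !is.numeric(trials) ||
      length(successes) != 1L || length(trials) != 1L ||
      is.na(successes) || is.na(trials) ||
      successes != round(successes) || trials != round(trials))
    abort_contract("`successes` and `trials` must be single integers")
  if (trials < 1 || successes < 0 || successes > trials)
    abort_contract("need 0 <= successes <= trials with trials >= 1")
  level <- check_scalar_prob(level, "level", closed = FALSE)
  ci <- suppressWarnings(
    stats::prop.test(successes, trials, conf.level = level, correct = FALSE)$conf.int)
  c(lower = max(0, ci[1]), upper = min(1, ci[2]))
}
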