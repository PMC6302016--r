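#' Class-conditional log-normal channel model
#'
#' Analyser particle counts are non-negative and strongly right-skewed, so
#' each channel is modelled log-normally within each culture class. On the
#' log scale the class-conditional distributions are Gaussian, which makes
#' the channel's ROC binormal and its AUC available in closed form -- the
#' property the calibration below exploits.
#'
#' @param mu_neg,mu_pos Log-scale (natural log of counts/uL) means of the
#'   culture-negative and culture-positive classes.
#' @param sigma_neg,sigma_pos Log-scale standard deviations, `> 0`.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(mu_neg, mu_pos, sigma_neg = 1, sigma_pos = 1) {
  for (nm in c("mu_neg", "mu_pos"))
    check_scalar_number(get(nm), nm)
  for (nm in c("sigma_neg", "sigma_pos"))
    check_scalar_number(get(nm), nm, positive = TRUE)
  structure(list(mu_neg = as.numeric(mu_neg), mu_pos = as.numeric(mu_pos),
                 sigma_neg = as.numeric(sigma_neg),
                 sigma_pos = as.numeric(sigma_pos)),
            class = "channel_model")
}

#' Closed-form AUC of a binormal channel
#'
#' For Gaussian class-conditional scores the probability that a random
#' positive outranks a random negative is
#' \deqn{AUC = \Phi\!\left(\frac{\mu_{pos} - \mu_{neg}}
#'   {\sqrt{\sigma_{neg}^2 + \sigma_{pos}^2}}\right).}
#' Because AUC is invariant under strictly increasing transforms, the same
#' value holds for the log-normal counts themselves.
#'
#' @param mu_neg,mu_pos Class means (any common scale).
#' @param sigma_neg,sigma_pos Class standard deviations, `> 0`.
#' @return AUC in `(0, 1)`.
#' @examples
#' binormal_auc(0, 1.386, 1, 1)   # ~0.836
#' @export
binormal_auc <- function(mu_neg, mu_pos, sigma_neg = 1, sigma_pos = 1) {
  if (inherits(mu_neg, "channel_model")) {
    m <- mu_neg
    return(binormal_auc(m$mu_neg, m$mu_pos, m$sigma_neg, m$sigma_pos))
  }
  for (nm in c("mu_neg", "mu_pos"))
    check_scalar_number(get(nm), nm)
  for (nm in c("sigma_neg", "sigma_pos"))
    check_scalar_number(get(nm), nm, positive = TRUE)
  stats::pnorm((mu_pos - mu_neg) / sqrt(sigma_neg^2 + sigma_pos^2))
}

#' Class separation needed to hit a target AUC
#'
#' Inverse of [binormal_auc()] in the mean difference: returns
#' `mu_pos - mu_neg` such that the binormal AUC equals `target_auc`.
#'
#' @param target_auc Target AUC in `(0, 1)`.
#' @param sigma_neg,sigma_pos Class standard deviations, `> 0`.
#' @return The required mean difference (log scale).
#' @examples
#' calibrate_separation(0.943)   # ~2.24 with unit sigmas
#' @export
calibrate_separation <- function(target_auc, sigma_neg = 1, sigma_pos = 1) {
  target_auc <- check_scalar_prob(target_auc, "target_auc", closed = FALSE)
  for (nm in c("sigma_neg", "sigma_pos"))
    check_scalar_number(get(nm), nm, positive = TRUE)
  stats::qnorm(target_auc) * sqrt(sigma_neg^2 + sigma_pos^2)
}

#' Channel model calibrated to a target AUC and operating scale
#'
#' Builds a [channel_model()] whose binormal AUC equals `target_auc` and
#' whose population cut-off at sensitivity `se_level` sits at
#' `cutoff_at_se` counts/uL: the positive-class mean is anchored so that a
#' fraction `se_level` of positives lie at or above that cut-off,
#' `mu_pos = log(cutoff_at_se) + \Phi^{-1}(se_level)\,\sigma_{pos}`, and
#' the negative-class mean follows from [calibrate_separation()].
#'
#' @param target_auc AUC in `(0, 1)`.
#' @param cutoff_at_se Desired cut-off (counts/uL) at the `se_level`
#'   operating point, `> 0`.
#' @param se_level Sensitivity anchoring the cut-off, default 0.95.
#' @param sigma_neg,sigma_pos Log-scale standard deviations.
#' @return A `channel_model`.
#' @export
calibrated_channel <- function(target_auc, cutoff_at_se, se_level = 0.95,
                               sigma_neg = 1, sigma_pos = 1) {
  cutoff_at_se <- check_scalar_number(cutoff_at_se, "cutoff_at_se", positive = TRUE)
  se_level <- check_scalar_prob(se_level, "se_level", closed = FALSE)
  mu_pos <- log(cutoff_at_se) + stats::qnorm(se_level) * sigma_pos
  delta <- calibrate_separation(target_auc, sigma_neg, sigma_pos)
  channel_model(mu_neg = mu_pos - delta, mu_pos = mu_pos,
                sigma_neg = sigma_neg, sigma_pos = sigma_pos)
}

#' Device measurement profile
#'
#' Bundles the two channel models with a within-class correlation between
#' log-bacteria and log-WBC and an additive log-scale offset shared by both
#' channels. The offset models devices that report the same biology on
#' different count scales: it multiplies every count (hence every optimal
#' cut-off) by `exp(scale_shift)` while leaving AUC, sensitivity and
#' specificity at corresponding thresholds unchanged.
#'
#' @param name Device label.
#' @param bac_model,wbc_model [channel_model()] objects.
#' @param rho Within-class correlation of log-bacteria and log-WBC,
#'   in `(-1, 1)`.
#' @param scale_shift Additive log-scale offset applied to both channels.
#' @return An object of class `device_profile`.
#' @seealso [default_device_profile()]
#' @export
device_profile <- function(name, bac_model, wbc_model, rho = 0.3,
                           scale_shift = 0) {
  if (!is.character(name) || length(name) != 1L)
    abort_contract("`name` must be a single string")
  if (!inherits(bac_model, "channel_model") || !inherits(wbc_model, "channel_model"))
    abort_contract("`bac_model` and `wbc_model` must be channel_model objects")
  rho <- check_scalar_number(rho, "rho")
  if (abs(rho) >= 1)
    abort_contract("`rho` must lie in (-1, 1)")
  scale_shift <- check_scalar_number(scale_shift, "scale_shift")
  structure(list(name = name, bac_model = bac_model, wbc_model = wbc_model,
                 rho = rho, scale_shift = scale_shift),
            class = "device_profile")
}

#' Built-in device profiles
#'
#' Two profiles emulating the analyser contrast the package targets:
#' `"UF1000i"` (flow cytometry: bacteria AUC 0.943, WBC AUC 0.832, 95%-
#' sensitivity cut-offs anchored at 138 and 119.8 counts/uL) and
#' `"FUS200"` (flow imaging: bacteria AUC 0.864, WBC AUC 0.834, with a
#' shared scale shift of `-log(138 / 5.7)` placing its bacteria cut-off
#' near 5.7 counts/uL). The AUCs and cut-off scales are calibration inputs
#' taken from published figure captions; the distributions themselves are
#' this package's own modelling choice.
#'
#' @param name `"UF1000i"` or `"FUS200"`.
#' @return A [device_profile()].
#' @export
default_device_profile <- function(name = c("UF1000i", "FUS200")) {
  name <- match.arg(name)
  if (name == "UF1000i") {
    device_profile("UF1000i",
                   bac_model = calibrated_channel(0.943, cutoff_at_se = 138),
                   wbc_model = calibrated_channel(0.832, cutoff_at_se = 119.8),
                   rho = 0.3, scale_shift = 0)
  } else {
    device_profile("FUS200",
                   bac_model = calibrated_channel(0.864, cutoff_at_se = 138),
                   wbc_model = calibrated_channel(0.834, cutoff_at_se = 119.8),
                   rho = 0.3, scale_shift = -log(138 / 5.7))
  }
}

#' Synthetic cohort generator configuration
#'
#' @param n Cohort size, `>= 1`. Default 1220, the scale of a busy
#'   hospital-laboratory evaluation window.
#' @param prevalence Culture-positive proportion. Default `213/1220`
#'   (17.4%), typical of mixed inpatient/outpatient submissions.
#' @param contamination_rate Proportion of truth-negative samples flagged
#'   as contaminated cultures (>= 3 colony types). Default 0.05.
#' @param device A [device_profile()].
#' @param seed Integer seed; one seed determines the whole cohort, with
#'   per-sample substreams so that changing `n` never reshuffles earlier
#'   samples.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 1220, prevalence = 213 / 1220,
                             contamination_rate = 0.05,
                             device = default_device_profile("UF1000i"),
                             seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    abort_contract("`n` must be a single integer >= 1")
  prevalence <- check_scalar_prob(prevalence, "prevalence")
  contamination_rate <- check_scalar_prob(contamination_rate, "contamination_rate")
  if (!inherits(device, "device_profile"))
    abort_contract("`device` must be a device_profile")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed))
    abort_contract("`seed` must be a single integer")
  structure(list(n = as.integer(n), prevalence = prevalence,
                 contamination_rate = contamination_rate,
                 device = device, seed = as.integer(seed)),
            class = "generator_config")
}

# Substream seed for sample i: distinct, stable under changes of n, and
# kept inside the 32-bit signed range set.seed() accepts.
sample_substream_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 1000003 + i * 2654435761) %% 2147483647)
}

#' Generate a synthetic screening cohort
#'
#' Draws each sample independently: culture class from
#' Bernoulli(prevalence); log-counts from the class's bivariate normal
#' (channel means/sigmas, correlation `rho`) plus the device scale shift,
#' then exponentiated. Truth-negative samples are flagged contaminated with
#' probability `contamination_rate`; contaminated samples draw their counts
#' from an intermediate model whose log-means sit midway between the two
#' classes (cultures overgrown by mixed flora look neither cleanly negative
#' nor cleanly positive on the analyser). Colony counts are assigned
#' consistently with the class: at or above 1e5 CFU/mL for positives
#' (log10-uniform over 5--7.5), below for negatives (log10-uniform over
#' 0--5). Sample `i` draws from its own seeded substream, so cohorts are
#' reproducible and prefixes are stable when `n` changes.
#'
#' @param config A [generator_config()].
#' @return A [urine_cohort()] (metadata fields record the generating
#'   parameters).
#' @examples
#' cohort <- generate_cohort(generator_config(n = 50, seed = 42))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    abort_contract("`config` must be a generator_config")
  dev <- config$device
  bm <- dev$bac_model; wm <- dev$wbc_model
  rho <- dev$rho; shift <- dev$scale_shift
  n <- config$n

  bac <- numeric(n); wbc <- numeric(n); cfu <- numeric(n)
  positive <- logical(n); contaminated <- logical(n)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  for (i in seq_len(n)) {
    set.seed(sample_substream_seed(config$seed, i))
    u <- stats::runif(3)
    z <- stats::rnorm(2)
    z2 <- rho * z[1] + sqrt(1 - rho^2) * z[2]
    pos <- u[1] < config$prevalence
    cont <- !pos && u[2] < config$contamination_rate
    if (pos) {
      mu_b <- bm$mu_pos; mu_w <- wm$mu_pos
      s_b <- bm$sigma_pos; s_w <- wm$sigma_pos
    } else if (cont) {
      mu_b <- (bm$mu_neg + bm$mu_pos) / 2; mu_w <- (wm$mu_neg + wm$mu_pos) / 2
      s_b <- bm$sigma_neg; s_w <- wm$sigma_neg
    } else {
      mu_b <- bm$mu_neg; mu_w <- wm$mu_neg
      s_b <- bm$sigma_neg; s_w <- wm$sigma_neg
    }
    bac[i] <- exp(mu_b + s_b * z[1] + shift)
    wbc[i] <- exp(mu_w + s_w * z2 + shift)
    cfu[i] <- if (pos) 10^(5 + 2.5 * u[3]) else 10^(5 * u[3] * 0.9999)
    positive[i] <- pos
    contaminated[i] <- cont
  }

  samples <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    device = dev$name,
    bacteria_per_uL = bac,
    wbc_per_uL = wbc,
    culture_cfu_per_mL = cfu,
    contaminated = contaminated
  )
  cohort <- urine_cohort(samples, label_config = culture_config())
  cohort$generator <- config
  cohort
}
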