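#' Culture ground-truth labelling configuration
#'
#' Cultures are called positive at or above a colony-count threshold; the
#' conventional cut-off for significant bacteriuria in midstream urine is
#' 1e5 CFU/mL, with 1e4 CFU/mL a common alternative for symptomatic
#' populations. Contaminated cultures (three or more distinct colony types)
#' carry no reliable pathogen count; by default they are kept in the cohort
#' and treated as truth-negative rather than dropped.
#'
#' @param cfu_threshold Positive scalar, CFU/mL at or above which a culture
#'   is labelled positive. Default `1e5`.
#' @param contaminated_is_negative If `TRUE` (default) contaminated cultures
#'   are truth-negative; if `FALSE` they are truth-positive.
#' @return An object of class `culture_config`.
#' @examples
#' culture_config()               # the 1e5 CFU/mL convention
#' culture_config(1e4)            # the lower alternative threshold
#' @export
culture_config <- function(cfu_threshold = 1e5, contaminated_is_negative = TRUE) {
  cfu_threshold <- check_scalar_number(cfu_threshold, "cfu_threshold", positive = TRUE)
  if (!is.logical(contaminated_is_negative) || length(contaminated_is_negative) != 1L ||
      is.na(contaminated_is_negative))
    abort_contract("`contaminated_is_negative` must be TRUE or FALSE")
  structure(
    list(cfu_threshold = cfu_threshold,
         contaminated_is_negative = contaminated_is_negative),
    class = "culture_config"
  )
}

#' @export
print.culture_config <- function(x, ...) {
  cat("<culture_config> positive iff CFU/mL >=", format(x$cfu_threshold),
      "| contaminated ->", if (x$contaminated_is_negative) "negative" else "positive", "\n")
  invisible(x)
}

required_cohort_cols <- c("sample_id", "device", "bacteria_per_uL", "wbc_per_uL")

#' Build a urine screening cohort
#'
#' A cohort pairs one analyser measurement per sample (bacteria and
#' leukocyte counts, particles/uL) with its urine-culture ground truth,
#' given either as a quantitative colony count (`culture_cfu_per_mL`) or as
#' a categorical `culture_label` (`"positive"`, `"negative"`,
#' `"contaminated"`). Each sample must carry at least one of the two.
#'
#' @param samples A data frame with columns `sample_id`, `device`,
#'   `bacteria_per_uL`, `wbc_per_uL`, and `culture_cfu_per_mL` and/or
#'   `culture_label`; optional `contaminated` (logical), `sex`,
#'   `patient_setting`.
#' @param label_config A [culture_config()].
#' @return An object of class `urine_cohort`: a list with elements
#'   `samples` (a tibble) and `label_config`.
#' @seealso [read_cohort()], [culture_truth()], [generate_cohort()]
#' @export
urine_cohort <- function(samples, label_config = culture_config()) {
  if (!inherits(label_config, "culture_config"))
    abort_contract("`label_config` must be a culture_config object")
  if (!is.data.frame(samples))
    abort_contract("`samples` must be a data frame")
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0L)
    abort_contract("a cohort must contain at least one sample")

  missing_cols <- setdiff(required_cohort_cols, names(samples))
  if (length(missing_cols))
    abort_format("missing required column(s): ", paste(missing_cols, collapse = ", "))
  has_cfu <- "culture_cfu_per_mL" %in% names(samples)
  has_lab <- "culture_label" %in% names(samples)
  if (!has_cfu && !has_lab)
    abort_format("missing culture information: need `culture_cfu_per_mL` or `culture_label`")

  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    abort_contract("sample_id values must be unique")
  for (col in c("bacteria_per_uL", "wbc_per_uL")) {
    v <- samples[[col]]
    if (!is.numeric(v))
      abort_contract("`", col, "` must be numeric")
    if (anyNA(v))
      abort_contract("`", col, "` contains missing values (row ",
                     which(is.na(v))[1L], "); missing counts are rejected, not zeroed")
    if (any(v < 0))
      abort_contract("`", col, "` must be non-negative (row ", which(v < 0)[1L], ")")
  }
  if (!has_cfu) samples$culture_cfu_per_mL <- NA_real_
  if (!has_lab) samples$culture_label <- NA_character_
  if (!"contaminated" %in% names(samples)) samples$contaminated <- FALSE
  samples$contaminated <- parse_binary_flag(samples$contaminated, "contaminated")
  lab <- samples$culture_label
  if (!all(is.na(lab) | lab %in% c("positive", "negative", "contaminated")))
    abort_format("`culture_label` values must be positive/negative/contaminated")
  samples$contaminated <- samples$contaminated | (!is.na(lab) & lab == "contaminated")
  no_culture <- is.na(samples$culture_cfu_per_mL) & is.na(lab)
  if (any(no_culture))
    abort_contract("sample(s) without culture information (row ",
                   which(no_culture)[1L], ")")

  structure(list(samples = samples, label_config = label_config),
            class = "urine_cohort")
}

parse_binary_flag <- function(x, name) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x)))
      abort_format("`", name, "` must be 0/1")
    return(!is.na(x) & x == 1)
  }
  if (is.character(x)) {
    x <- tolower(trimws(x))
    ok <- x %in% c("0", "1", "true", "false", "") | is.na(x)
    if (!all(ok)) abort_format("`", name, "` must be 0/1 or TRUE/FALSE")
    return(!is.na(x) & x %in% c("1", "true"))
  }
  abort_format("`", name, "` must be logical or 0/1")
}

#' @export
print.urine_cohort <- function(x, ...) {
  tr <- culture_truth(x)
  cat("<urine_cohort> ", nrow(x$samples), " samples (",
      sum(tr), " culture-positive, ", sum(x$samples$contaminated),
      " contaminated) | truth at ", format(x$label_config$cfu_threshold),
      " CFU/mL\n", sep = "")
  invisible(x)
}

#' Label a culture result as positive or negative
#'
#' Applies the culture decision rule: positive iff the colony count is at or
#' above the configured threshold and the culture is not contaminated (under
#' the default configuration). Categorical labels are honoured where the
#' quantitative count is absent.
#'
#' @param cfu Numeric vector of colony counts (CFU/mL); may contain `NA`
#'   where `culture_label` is given.
#' @param contaminated Logical vector (recycled) flagging contaminated
#'   cultures.
#' @param culture_label Optional character vector
#'   (`positive`/`negative`/`contaminated`) used where `cfu` is `NA`.
#' @param config A [culture_config()].
#' @return Integer vector of 0/1 truth labels.
#' @examples
#' label_culture(c(1e5, 9.9e4))              # 1, 0
#' label_culture(2e5, contaminated = TRUE)   # 0: contaminated counts as negative
#' @export
label_culture <- function(cfu, contaminated = FALSE, culture_label = NULL,
                          config = culture_config()) {
  if (!inherits(config, "culture_config"))
    abort_contract("`config` must be a culture_config object")
  if (missing(cfu) || is.null(cfu)) {
    if (is.null(culture_label))
      abort_contract("culture information absent: supply `cfu` or `culture_label`")
    cfu <- rep(NA_real_, length(culture_label))
  }
  if (is.logical(cfu) && all(is.na(cfu))) cfu <- as.numeric(cfu)
  if (!is.numeric(cfu)) abort_contract("`cfu` must be numeric")
  n <- length(cfu)
  contaminated <- rep_len(as.logical(contaminated), n)
  if (is.null(culture_label)) {
    culture_label <- rep(NA_character_, n)
  } else {
    culture_label <- rep_len(as.character(culture_label), n)
    contaminated <- contaminated | (!is.na(culture_label) & culture_label == "contaminated")
  }
  missing_info <- is.na(cfu) & is.na(culture_label)
  if (any(missing_info))
    abort_contract("culture information absent for element ", which(missing_info)[1L])

  pos <- ifelse(is.na(cfu),
                culture_label == "positive",
                cfu >= config$cfu_threshold)
  if (config$contaminated_is_negative) {
    pos <- pos & !contaminated
  } else {
    pos <- pos | contaminated
  }
  as.integer(pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Culture truth labels of a cohort
#'
#' @param cohort A [urine_cohort()].
#' @param config Optional [culture_config()] overriding the cohort's own.
#' @return Integer 0/1 vector, one label per sample.
#' @export
culture_truth <- function(cohort, config = NULL) {
  if (!inherits(cohort, "urine_cohort"))
    abort_contract("`cohort` must be a urine_cohort")
  cfg <- config %||% cohort$label_config
  label_culture(cohort$samples$culture_cfu_per_mL,
                contaminated = cohort$samples$contaminated,
                culture_label = cohort$samples$culture_label,
                config = cfg)
}

#' Read a cohort from a delimited text file
#'
#' Expects a UTF-8 CSV (or TSV for `.tsv`/`.tab` paths) with a header naming
#' `sample_id`, `device`, `bacteria_per_uL`, `wbc_per_uL`, and either
#' `culture_cfu_per_mL` or `culture_label`. Optional columns: `contaminated`
#' (0/1), `qc_excluded` (0/1; flagged rows are dropped and counted),
#' `sex`, `patient_setting`. The decimal separator is `"."`.
#'
#' @param path Path to the file.
#' @param label_config A [culture_config()].
#' @param quiet Suppress the row-count log message.
#' @return A [urine_cohort()].
#' @export
read_cohort <- function(path, label_config = culture_config(), quiet = FALSE) {
  if (!is.character(path) || length(path) != 1L)
    abort_contract("`path` must be a single file path")
  if (!file.exists(path))
    abort_io("file not found: ", path)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(raw) == 0L)
    abort_format("empty data section in ", path)
  missing_cols <- setdiff(required_cohort_cols, names(raw))
  if (length(missing_cols))
    abort_format("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!any(c("culture_cfu_per_mL", "culture_label") %in% names(raw)))
    abort_format("missing culture information: need `culture_cfu_per_mL` or `culture_label`")

  n_total <- nrow(raw)
  n_qc <- 0L
  if ("qc_excluded" %in% names(raw)) {
    qc <- parse_binary_flag(raw$qc_excluded, "qc_excluded")
    n_qc <- sum(qc)
    raw <- raw[!qc, , drop = FALSE]
    raw$qc_excluded <- NULL
    if (nrow(raw) == 0L)
      abort_format("empty data section in ", path, " after QC exclusions")
  }
  for (col in intersect(c("bacteria_per_uL", "wbc_per_uL", "culture_cfu_per_mL"),
                        names(raw))) {
    chr <- raw[[col]]
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(!is.na(chr) & is.na(num))
    if (length(bad))
      abort_format("non-numeric value '", chr[bad[1L]], "' in column `", col,
                   "`, data row ", bad[1L])
    raw[[col]] <- num
  }
  if (!quiet)
    message("read_cohort: ", n_total, " data rows in ", basename(path),
            "; ", n_qc, " excluded by QC flag; ", nrow(raw), " retained")
  urine_cohort(raw, label_config = label_config)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: the written file round-trips through
#' `read_cohort()` with all fields preserved.
#'
#' @param cohort A [urine_cohort()].
#' @param path Output path; `.tsv`/`.tab` selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "urine_cohort"))
    abort_contract("`cohort` must be a urine_cohort")
  out <- cohort$samples
  out$contaminated <- as.integer(out$contaminated)
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
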