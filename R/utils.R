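# Internal condition helpers. Contract violations (bad arguments, broken
# invariants, malformed tables) and I/O failures raise distinct classes so
# callers -- in particular the CLI -- can map them to distinct exit codes.

abort_contract <- function(..., class = character()) {
  stop(errorCondition(paste0(...),
                      class = c(class, "uroscreen_contract_error", "uroscreen_error")))
}

abort_format <- function(...) {
  abort_contract(..., class = "uroscreen_format_error")
}

abort_io <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("uroscreen_io_error", "uroscreen_error")))
}

# Single scalar checks used all over the argument surface.
check_scalar_prob <- function(x, name, closed = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_contract("`", name, "` must be a single number")
  lo <- if (closed) x >= 0 else x > 0
  hi <- if (closed) x <= 1 else x < 1
  if (!lo || !hi)
    abort_contract("`", name, "` must lie in ", if (closed) "[0, 1]" else "(0, 1)",
                   ", got ", format(x))
  as.numeric(x)
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_contract("`", name, "` must be a single number")
  if (positive && x <= 0)
    abort_contract("`", name, "` must be positive, got ", format(x))
  as.numeric(x)
}

# Coerce truth/screen labels (logical, 0/1 numeric, or "positive"/"negative")
# to an integer 0/1 vector.
as_binary01 <- function(x, name = "labels") {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (anyNA(x) || !all(x %in% c(0, 1)))
      abort_contract("`", name, "` must contain only 0 and 1")
    return(as.integer(x))
  }
  if (is.character(x) || is.factor(x)) {
    x <- tolower(as.character(x))
    if (!all(x %in% c("positive", "negative")))
      abort_contract("`", name, "` must be 'positive'/'negative'")
    return(as.integer(x == "positive"))
  }
  abort_contract("`", name, "` must be logical, 0/1 numeric, or positive/negative")
}

# Round half-up at `digits` decimals; used only in the report layer so that
# printed percentages match clinical-paper style (full precision is kept in
# every computation).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

as_pct <- function(p, digits = 1) round_half_up(100 * p, digits)
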