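#' @keywords internal
"_PACKAGE"

# Argument checks shared across modules. All user-facing errors are
# classed "dosefreq_error" so callers can distinguish them from bugs.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("dosefreq_error", "error")))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(name, " must be a single non-missing number")
  }
  if (x < lower || x > upper) {
    stop_invalid(name, " must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_invalid(name, " must be an integer, got ", x)
  invisible(as.integer(x))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; dosage-group binning rounds
#' half-integer medians up (2.5 days/week -> 3), so this helper is used
#' wherever a median of day counts is binned.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties going up.
#' @examples
#' round_half_up(c(1.5, 2.5, 2.4))
#' @export
round_half_up <- function(x) floor(x + 0.5)

# Deterministic per-patient RNG substream: a small string hash folded into
# the root seed, kept below .Machine$integer.max.
derive_seed <- function(root_seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 1000000007
  as.integer((as.numeric(root_seed) * 2654435 + h) %% 2147483647)
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
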