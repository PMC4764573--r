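# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

abort_arg <- function(msg) stop(msg, call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_arg(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= min) abort_arg(sprintf("`%s` must be > %g", name, min))
  if (!strict && x < min) abort_arg(sprintf("`%s` must be >= %g", name, min))
  invisible(x)
}

# log-uniform draw on [lo, hi]
rlogunif <- function(n, lo, hi) {
  10^stats::runif(n, log10(lo), log10(hi))
}

# deterministic largest-remainder allocation of n items to fractions;
# exact multiples give exact counts
allocate_counts <- function(n, fractions) {
  if (any(fractions < 0)) abort_arg("stratum fractions must be non-negative")
  fractions <- fractions / sum(fractions)
  raw <- n * fractions
  counts <- floor(raw + 1e-9)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1L
  }
  stats::setNames(as.integer(counts), names(fractions))
}

sample_roles <- function() {
  c("nuclear", "cytosolic", "input", "bait_minus_ran", "bait_plus_ran",
    "standard")
}
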