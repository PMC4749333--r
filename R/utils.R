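#' @keywords internal
"_PACKAGE"

# geometric mean of strictly positive values
geomean <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  exp(mean(log(x)))
}

# sample SD (n-1 denominator) without the NA surprises of stats::sd on n = 1
sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# known sample-set labels used throughout
SET_LEVELS <- c("genotypes", "stress", "tissues", "all")

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
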