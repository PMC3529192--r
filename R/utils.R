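#' @keywords internal
"_PACKAGE"

#' @useDynLib closecall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate complete.cases cor fft lm mvfft quantile
#'   rbinom rnorm runif sd setNames var
#' @importFrom utils combn read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a normal distribution truncated below
#'
#' Resampling-based truncated normal draw. Used for durations, frequencies
#' and mix ratios, whose population standard deviations would otherwise
#' permit negative (physically meaningless) values.
#'
#' @param n number of draws
#' @param mean,sd normal parameters (`sd >= 0`)
#' @param lower lower truncation bound (draws are resampled until `> lower`)
#' @return numeric vector of `n` draws
#' @keywords internal
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  stopifnot(all(sd >= 0))
  if (all(sd == 0)) {
    out <- rep_len(mean, n)
    if (any(out <= lower)) stop("degenerate truncated draw: mean <= lower with sd = 0")
    return(out)
  }
  ## inverse-CDF draw from the truncated distribution (exact, and robust
  ## when the untruncated mass above `lower` is tiny)
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- p_lo + runif(n) * (1 - p_lo)
  out <- stats::qnorm(pmin(u, 1 - 1e-16), mean, sd)
  pmax(out, lower + .Machine$double.eps * abs(lower))
}

## deterministic child seed for a named pipeline stage, kept under 2^31
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 69069 + h * 101) %% 2147483647)
}

rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) ""
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else if (pi < 0.1) "•"
    else ""
  }, character(1))
}
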