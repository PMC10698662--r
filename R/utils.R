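#' nightfit: diary-vs-wearable sleep agreement analysis
#'
#' @keywords internal
#' @importFrom stats sd t.test qnorm rnorm runif rpois
#' @importFrom utils read.csv write.csv write.table head
"_PACKAGE"

# Round half away from zero, the convention used in the printed report tables
# (base round() is banker's rounding and disagrees on .5 ties).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percent with one decimal, e.g. 543/736 -> 73.8
percent1 <- function(num, den) round_half_away(100 * num / den, 1)

# Stable 31-bit string hash (polynomial, order-independent of R internals),
# used to derive per-participant RNG sub-streams.
stable_hash <- function(s) {
  vapply(s, function(one) {
    codes <- utf8ToInt(one)
    h <- 0
    for (cc in codes) h <- (h * 31 + cc) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) + as.numeric(stable_hash(key))) %% 2147483647L)
}

# Truncated-normal draw by rejection with a clamp fallback; adequate for the
# mild truncations used by the generator (WASO >= 0 etc.).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (all(sd == 0)) return(pmin(pmax(mean, lower), upper))
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(20)) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
  }
  pmin(pmax(x, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
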