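# Internal numerical helpers shared across modules.

# Row variances with the n-1 denominator (used for standardization checks,
# ANOVA sums of squares and eigenvalue normalization alike).
rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

colVars <- function(x) rowVars(t(x))

# Derive a reproducible sub-seed from a global seed and a purpose offset,
# kept within the 32-bit integer range.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset) * 10007) %% 2147483647L)
}

# Sample skewness (moment form); used only for the ICA sign convention.
momentSkewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^3) / m2^1.5
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
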