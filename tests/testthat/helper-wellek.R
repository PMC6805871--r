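# Independent reference for the Wellek Mann-Whitney equivalence test:
# a literal loop-level transcription of the published mawi routine
# (sign/trunc pair counting, triple concordance estimators, noncentral
# chi-squared critical bound). Kept deliberately un-vectorised and separate
# from the package implementation so the two routes share no code. The
# sign/trunc counting treats ties as 0 rather than 1/2, so comparisons are
# made on tie-free vectors where both conventions coincide.
wellek_reference_verdict <- function(exp, sim, p_lo, p_hi, alpha = 0.05) {
  x <- sim
  y <- exp
  m <- length(x)
  n <- length(y)
  eps1_ <- 0.5 - p_lo
  eps2_ <- p_hi - 0.5

  wxy <- 0
  pihxxy <- 0
  pihxyy <- 0
  for (i in 1:m) {
    for (j in 1:n) {
      wxy <- wxy + trunc(0.5 * (sign(x[i] - y[j]) + 1))
    }
  }
  for (i in 1:m) {
    for (j1 in 1:(n - 1)) {
      for (j2 in (j1 + 1):n) {
        pihxyy <- pihxyy + trunc(0.5 * (sign(x[i] - max(y[j1], y[j2])) + 1))
      }
    }
  }
  for (i1 in 1:(m - 1)) {
    for (i2 in (i1 + 1):m) {
      for (j in 1:n) {
        pihxxy <- pihxxy + trunc(0.5 * (sign(min(x[i1], x[i2]) - y[j]) + 1))
      }
    }
  }
  wxy <- wxy / (m * n)
  pihxxy <- pihxxy * 2 / (m * (m - 1) * n)
  pihxyy <- pihxyy * 2 / (n * (n - 1) * m)
  sigmah <- sqrt((wxy - (m + n - 1) * wxy^2 + (m - 1) * pihxxy +
                  (n - 1) * pihxyy) / (m * n))
  if (sigmah == 0) {
    return(wxy > p_lo && wxy < p_hi)
  }
  crit <- sqrt(qchisq(alpha, 1, ((eps1_ + eps2_) / (2 * sigmah))^2))
  abs((wxy - 0.5 + (eps2_ - eps1_) / 2) / sigmah) < crit
}
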