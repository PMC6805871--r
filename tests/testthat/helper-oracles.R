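# independently coded brute-force double loops over replicate/run pairs,
# kept free of the package's vectorised formulas
brute_cell <- function(name, e, s) {
  m <- length(e)
  n <- length(s)
  acc <- 0
  cnt <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d <- e[i] - s[j]
      acc <- acc + switch(name,
        PWSD = , SSQ = d^2,
        APWSD = abs(d),
        NPWSD = if (e[i] != 0) (d / e[i])^2 else 0,
        ANPWSD = if (e[i] != 0) abs(d / e[i]) else 0,
        CHISQ = (d / sd(e))^2,
        MNSE = (d / mean(e))^2,
        0
      )
      if (!(name %in% c("NPWSD", "ANPWSD")) || e[i] != 0) cnt <- cnt + 1
    }
  }
  switch(name,
    SDA = (sum(e) / m - sum(s) / n)^2,
    ADA = abs(sum(e) / m - sum(s) / n),
    PWSD = acc / (m * n),
    APWSD = acc / (m * n),
    NPWSD = acc / cnt,
    ANPWSD = acc / cnt,
    SSQ = acc,
    CHISQ = acc,
    MNSE = acc
  )
}
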