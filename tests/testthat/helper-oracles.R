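# Independent oracles: exact sign-flip enumeration for the paired test and
# label permutation for the one-way ANOVA, on small fixed datasets.

signFlipP <- function(d) {
  n <- length(d)
  tObs <- abs(mean(d) / (stats::sd(d) / sqrt(n)))
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tAll <- apply(flips, 1, function(s) {
    ds <- s * d
    abs(mean(ds) / (stats::sd(ds) / sqrt(n)))
  })
  mean(tAll >= tObs - 1e-12)
}

permAnovaP <- function(values, groups, nPerm = 10000L, seed = 99L) {
  set.seed(seed)
  k <- nlevels(groups); n <- length(values)
  fStat <- function(v) {
    gm <- tapply(v, groups, mean)
    ni <- tabulate(groups)
    ssb <- sum(ni * (gm - mean(v))^2)
    ssw <- sum((v - gm[as.integer(groups)])^2)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  fObs <- fStat(values)
  hits <- 0L
  for (i in seq_len(nPerm))
    if (fStat(sample(values)) >= fObs - 1e-12) hits <- hits + 1L
  hits / nPerm
}
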