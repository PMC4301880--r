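# Independent oracles and small fixtures shared across tests.

# Two-sided Fisher p by full enumeration of all 2x2 tables at the observed
# margins: sum the hypergeometric point probabilities of every table no more
# probable than the observed one (relative tolerance guards floating ties).
fisherEnumOracle <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1L, ])
  c1 <- sum(tab[, 1L])
  n <- sum(tab)
  aRange <- max(0L, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(aRange, function(a) {
    exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1))
  }, numeric(1L))
  pObs <- probs[aRange == tab[1L, 1L]]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exhaustive coverage distribution for tiny models: enumerate all n^m ordered
# hit sequences and weight each by its probability.
coverageEnumOracle <- function(p, m) {
  n <- length(p)
  if (m == 0L) return(c(1, rep(0, n)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), m)))
  w <- apply(seqs, 1L, function(s) prod(p[s]))
  covered <- apply(seqs, 1L, function(s) length(unique(s)))
  vapply(0:n, function(k) sum(w[covered == k]), numeric(1L))
}

gpiFixturePath <- function() {
  system.file("extdata", "gpi_gene_table.tsv", package = "satmut")
}

paperSteps <- function() {
  data.frame(alleles = c(22, 40, 71, 115), covered = c(11, 15, 18, 20))
}

# callset configuration whose read fractions sit far clear of the 0.90/0.95
# thresholds, so the filter must recover the truth labels exactly
clearMarginConfig <- function(...) {
  callsetConfig(trueAltShape = c(500, 4), decoyAltShape = c(40, 40),
                controlRefShape = c(2000, 10), ...)
}
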