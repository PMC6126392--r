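# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the rate oracle is a dense grid search over the
# RSS, the Fisher oracle enumerates the hypergeometric distribution with
# choose() directly.

# RSS-minimising k on a dense grid
grid_k_oracle <- function(time, ria, step = 1e-4, k_max = 2) {
  ks <- seq(0, k_max, by = step)
  rss <- vapply(ks, function(k) sum((ria - (1 - exp(-k * time)))^2),
                numeric(1))
  ks[which.min(rss)]
}

# two-sided Fisher exact p by full enumeration of the conditional
# (hypergeometric) distribution; same tie rule as the classical test
# (include tables whose probability does not exceed the observed one,
# with a 1e-7 relative tolerance)
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  xs <- max(0, c1 - r2):min(c1, r1)
  p <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  p_obs <- p[xs == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

cohens_kappa <- function(a, b) {
  la <- union(unique(a), unique(b))
  t <- table(factor(a, la), factor(b, la))
  po <- sum(diag(t)) / sum(t)
  pe <- sum(rowSums(t) * colSums(t)) / sum(t)^2
  (po - pe) / (1 - pe)
}

# noiseless evidence for one peptide following the labeling model exactly
model_points <- function(k, time = c(0.5, 1, 2, 6, 24)) {
  data.frame(time = time, ria = 1 - exp(-k * time))
}
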