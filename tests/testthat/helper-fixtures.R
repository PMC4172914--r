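# Small builders shared across test files.

# A hand-sized CtPanel: nf features, 3 + 3 samples, controls U44/U48.
tinyPanel <- function(nf = 10, seed = 1, shift = NULL, group = NULL) {
  set.seed(seed)
  n_samp <- if (is.null(group)) 6L else length(group)
  if (is.null(group)) group <- rep(c("newborn", "adult"), each = 3)
  ct <- matrix(rnorm(nf * n_samp, mean = 28, sd = 1), nrow = nf,
               dimnames = list(paste0("miR-", seq_len(nf)),
                               paste0("s", seq_len(n_samp))))
  if (!is.null(shift))
    ct[names(shift), group == "adult"] <-
      ct[names(shift), group == "adult"] +
      matrix(shift, nrow = length(shift), ncol = sum(group == "adult"))
  ctrl <- matrix(rnorm(2 * n_samp, mean = 20, sd = 0.3), nrow = 2,
                 dimnames = list(c("U44", "U48"), colnames(ct)))
  CtPanel(rbind(ct, ctrl), group = group, controlIds = c("U44", "U48"))
}

# Brute-force hypergeometric upper tail by explicit combinatorial sum.
bruteFisher <- function(nf, n, Nf, N) {
  ks <- nf:min(n, Nf)
  if (nf > min(n, Nf)) return(0)
  sum(exp(lchoose(Nf, ks) + lchoose(N - Nf, n - ks) - lchoose(N, n)))
}

# Step-up BH from its definition.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
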