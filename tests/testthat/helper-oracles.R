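# Independent oracles for separation quality, implemented apart from the
# package's code path.

# Amari separation error of P = unmixing %*% true_mixing: 0 iff P is a signed
# permutation matrix (scale- and permutation-invariant).
amari_error <- function(P) {
  P <- abs(as.matrix(P))
  k <- nrow(P)
  rowterm <- sum(rowSums(P / apply(P, 1, max)) - 1)
  colterm <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rowterm + colterm) / (2 * k * (k - 1))
}

# Best bipartite matching of estimated to true sources by absolute
# correlation, by exhaustive permutation search (fine for k <= 6).
# Returns the matched |correlation| per true source under the best
# permutation.
match_abs_cor <- function(est, true) {
  k <- nrow(true)
  cors <- abs(stats::cor(t(est), t(true)))  # est x true
  perms <- pracma::perms(seq_len(k))
  best <- NULL; best_sum <- -Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    s <- sum(cors[cbind(p, seq_len(k))])
    if (s > best_sum) { best_sum <- s; best <- p }
  }
  cors[cbind(best, seq_len(k))]
}
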