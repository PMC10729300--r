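# Independent brute-force oracles used to validate the fast paths.

# random canonical sequence(s)
random_seqs <- function(n, L) {
  vapply(seq_len(n), function(i)
    paste(sample(aa_alphabet(), L, replace = TRUE), collapse = ""),
    character(1))
}

# a set of random mutants (1-3 substitutions) of one random parent:
# the sequence-set shape the kernel is designed for
random_variant_set <- function(n, L) {
  chars <- sample(aa_alphabet(), L, replace = TRUE)
  vapply(seq_len(n), function(i) {
    s <- chars
    pos <- sample(L, sample(1:3, 1))
    s[pos] <- vapply(pos, function(p)
      sample(setdiff(aa_alphabet(), chars[p]), 1), "")
    paste(s, collapse = "")
  }, character(1))
}

# mid-ranks computed by explicit counting (no rank())
midranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, 0)
}

# Spearman via Pearson-of-midranks, spelled out
oracle_spearman <- function(a, b) {
  ra <- midranks(a); rb <- midranks(b)
  da <- ra - mean(ra); db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Kendall tau-b by explicit pair counting
oracle_kendall <- function(a, b) {
  n <- length(a)
  conc <- disc <- ta <- tb <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- sign(a[j] - a[i]); sb <- sign(b[j] - b[i])
      if (sa == 0 && sb == 0) { ta <- ta + 1; tb <- tb + 1 }
      else if (sa == 0) ta <- ta + 1
      else if (sb == 0) tb <- tb + 1
      else if (sa == sb) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  P <- n * (n - 1) / 2
  (conc - disc) / sqrt((P - ta) * (P - tb))
}

# dense-inverse GP oracle: solve() instead of Cholesky triangular solves
oracle_gp <- function(seqs, y, lambda, spec, new_seqs) {
  K <- unclass(gram(seqs, spec))
  z <- (y - mean(y)) / sd(y)
  Ainv <- solve(K + diag(lambda, nrow(K)))
  alpha <- Ainv %*% z
  Ks <- cross_gram(seqs, new_seqs, spec)
  mu <- drop(t(Ks) %*% alpha)
  s2 <- kernel_self(new_seqs, spec) - diag(t(Ks) %*% Ainv %*% Ks)
  list(alpha = drop(alpha), mu = mu, sigma = sqrt(pmax(s2, 0)))
}

# tiny deterministic training set over a fixed parent
toy_dataset <- function(n = 12, L = 8, seed = 42, noise = 0.2) {
  set.seed(seed)
  parent <- parent_sequence(paste(sample(aa_alphabet(), L, replace = TRUE),
                                  collapse = ""), id = "toy")
  cands <- enumerate_single_mutants(parent)
  rows <- cands[sample(nrow(cands), n), ]
  eff <- rnorm(n)
  d <- tibble::tibble(
    id = paste0("v", seq_len(n)),
    mutations = rows$mutation,
    sequence = rows$sequence,
    n_mutations = 1L,
    rate = 1 + eff + rnorm(n, 0, noise),
    atp_ratio = 4 - 0.5 * eff + rnorm(n, 0, noise))
  attr(d, "parent") <- parent
  d
}
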