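# Independent oracles used across the suite. These deliberately use naive
# algorithms (explicit loops, full enumeration) so they share no code with the
# implementation they check.

# all permutations of a vector (n! rows)
perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], perms(v[-i]))))
}

# concordance statistic by explicit double loop
brute_S <- function(x, r) {
  s <- 0
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(r[j] - r[i])
  s
}

# exact null pmf of S by full permutation enumeration
enum_null <- function(x, blocks) {
  r <- rep(seq_along(blocks), blocks)
  P <- perms(x)
  n <- length(x)
  Sv <- numeric(nrow(P))
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (r[i] != r[j])
      Sv <- Sv + sign(P[, j] - P[, i]) * sign(r[j] - r[i])
  tab <- table(Sv) / nrow(P)
  list(support = as.numeric(names(tab)), pmf = as.numeric(tab))
}

enum_two_sided_p <- function(null, S) {
  sum(null$pmf[abs(null$support) >= abs(S) - 1e-9])
}

# the six fundamental network concepts by explicit loops
brute_concepts <- function(A) {
  n <- nrow(A)
  k <- cc <- mar <- numeric(n)
  for (i in 1:n) {
    k[i] <- sum(A[i, -i])
    num <- 0
    for (j in 1:n) for (l in 1:n)
      if (j != i && l != i && l != j) num <- num + A[i, j] * A[j, l] * A[l, i]
    den <- k[i]^2 - sum(A[i, -i]^2)
    cc[i] <- if (den > 0) num / den else 0
    mar[i] <- if (k[i] > 0) sum(A[i, -i]^2) / k[i] else 0
  }
  dens <- sum(k) / (n * (n - 1))
  list(k = k, cc = cc, mar = mar, density = dens,
       centralization = n / (n - 2) * (max(k) / (n - 1) - dens),
       heterogeneity = sqrt(mean(k^2) / mean(k)^2 - 1))
}

# brute-force Eq.-1 proximity on a distance matrix
brute_dAB <- function(D, A, B) {
  sa <- 0
  for (a in A) sa <- sa + min(D[a, B])
  sb <- 0
  for (b in B) sb <- sb + min(D[A, b])
  (sa + sb) / (length(A) + length(B))
}

# brute-force d_s
brute_ds <- function(D, S) {
  tot <- 0
  for (a in S) tot <- tot + min(D[a, setdiff(S, a)])
  tot / length(S)
}

# Kolmogorov-Smirnov distance to Uniform(0,1)
ks_D <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(abs(s - (1:n) / n), abs(s - (0:(n - 1)) / n))
}

# random symmetric weighted adjacency with zero diagonal
random_adjacency <- function(n) {
  A <- matrix(stats::runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# small deterministic atlas fixture
toy_atlas <- function(n_genes = 6, n_organs = 4, zt = seq(0, 18, 6),
                      seed = 1) {
  set.seed(seed)
  vals <- array(stats::runif(n_genes * n_organs * length(zt), 1, 10),
                dim = c(n_genes, n_organs, length(zt)))
  expression_atlas(vals, paste0("g", seq_len(n_genes)),
                   paste0("o", seq_len(n_organs)), zt)
}
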