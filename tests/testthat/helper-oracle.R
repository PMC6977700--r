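# Independent brute-force oracle for the triplet scoring formulas: a
# straight transliteration using a quadrature-based normal CDF (64-node
# Gauss-Legendre integration of the density) and a log-scale root solve
# for the quantile. Shares no code path with the package implementation.

.gl64 <- pracma::gaussLegendre(64, 0, 1)

oracle_upper_tail <- function(x) {
  vapply(x, function(xx) {
    t <- xx + 12 * .gl64$x
    12 * sum(.gl64$w * exp(-t^2 / 2)) / sqrt(2 * pi)
  }, numeric(1L))
}

oracle_upper_root <- function(u) {
  stats::uniroot(function(w) log(oracle_upper_tail(w)) - log(u),
                 interval = c(-1, 16), tol = 1e-13)$root
}

oracle_tail_transform <- function(d, eps = 1e-15) {
  u2 <- 2 * oracle_upper_tail(d) # two-sided tail, 1 - q
  vapply(seq_along(d), function(i) {
    if (u2[i] <= 0.5) {
      oracle_upper_root(max(u2[i], eps))
    } else {
      -oracle_upper_root(max(1 - u2[i], eps))
    }
  }, numeric(1L))
}

oracle_node_score <- function(p, log2fc, eps = 1e-15) {
  oracle_tail_transform((-log10(pmax(p, 1e-300))) * abs(log2fc), eps)
}

oracle_fisher_z <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  0.5 * log((1 + r) / (1 - r))
}

oracle_edge <- function(r1, p1, n1, r2, p2, n2, eps = 1e-15) {
  xi <- (oracle_fisher_z(r2) * (-log10(pmax(p2, 1e-300))) -
           oracle_fisher_z(r1) * (-log10(pmax(p1, 1e-300)))) /
    sqrt(1 / (n2 - 3) + 1 / (n1 - 3))
  list(xi = xi, score = oracle_tail_transform(abs(xi), eps))
}

oracle_combined <- function(node_scores, edge_scores, omega) {
  omega * sum(node_scores) / 3 + (1 - omega) * sum(edge_scores) / 3
}
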