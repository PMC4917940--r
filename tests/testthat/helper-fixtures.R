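# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written from the definitions (sorting,
# enumeration, SVD), independent of the package's implementation paths.

# random interaction matrix satisfying the model's zero-sum constraints:
# sum_d n_d gamma_dg = 0 per gene, sum_g gamma_dg = 0 per condition
rand_gamma <- function(D, G, n_d) {
  g <- matrix(stats::rnorm(D * G), D, G)
  g <- g - matrix(colSums(g * n_d) / sum(n_d), D, G, byrow = TRUE)
  g - rowMeans(g)
}

# weighted best rank-1 approximation error via singular decomposition of
# the sqrt(n_d)-row-scaled matrix (oracle for the WLS objective)
svd_rank1_objective <- function(gamma, n_d) {
  s <- svd(sqrt(n_d) * gamma)$d
  sum(s^2) - s[1]^2
}

# brute-force TMM factor for one sample against a reference: drop zero
# counts, sort M-values, trim each tail, precision-weighted mean
tmm_oracle <- function(x, xr, trim = 0.3) {
  N <- sum(x); Nr <- sum(xr)
  ok <- x > 0 & xr > 0
  x <- x[ok]; xr <- xr[ok]
  M <- log2((x / N) / (xr / Nr))
  v <- (N - x) / (N * x) + (Nr - xr) / (Nr * xr)
  ord <- order(M)
  k <- floor(length(M) * trim)
  keep <- ord[(k + 1):(length(M) - k)]
  2^(stats::weighted.mean(M[keep], 1 / v[keep]))
}

# small two-condition count matrix used across validation tests
tiny_cm <- function() {
  counts <- matrix(c(10, 20, 30, 40,
                     5, 6, 7, 8), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  count_matrix(counts, condition = c("a", "a", "b", "b"))
}

# a normalized_counts object built directly from a value matrix
make_nc <- function(values, condition, subject = NULL) {
  if (is.null(dimnames(values))) {
    dimnames(values) <- list(paste0("g", seq_len(nrow(values))),
                             paste0("s", seq_len(ncol(values))))
  }
  normalized_counts(values, condition, subject)
}

# checks every identifiability constraint of a fitted model
expect_fit_constraints <- function(fit, tol = 1e-8) {
  n_d <- fit$n_d
  expect_lt(abs(sum(n_d * fit$alpha)), tol)
  expect_lt(abs(sum(fit$beta)), tol)
  expect_lt(max(abs(colSums(fit$gamma * n_d))), tol)
  expect_lt(max(abs(rowSums(fit$gamma))), tol)
  expect_equal(unname(fit$u[fit$reference]), 1, tolerance = tol)
  expect_lt(abs(sum(n_d * fit$u)), tol)
  expect_lt(abs(sum(fit$v)), tol)
}

# minimal hand-built rank1_fit for the variance formulas
fake_fit <- function(u, n_d, mu_dg, v = NULL) {
  G <- ncol(mu_dg)
  if (is.null(colnames(mu_dg))) colnames(mu_dg) <- paste0("g", seq_len(G))
  if (is.null(v)) v <- stats::setNames(rep(0.1, G), colnames(mu_dg))
  structure(list(u = u, n_d = n_d, mu_dg = mu_dg, v = v,
                 conditions = paste0("cond", seq_along(u)), reference = 1),
            class = "rank1_fit")
}

fake_phi <- function(phi, genes) {
  structure(list(phi = stats::setNames(rep(phi, length.out = length(genes)),
                                       genes),
                 method = "supplied", prior_df = 0, floor = 1e-8),
            class = "dispersion_set")
}
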