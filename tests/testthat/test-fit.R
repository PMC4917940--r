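test_that("condition-mean log expressions match hand evaluation", {
  nc <- make_nc(matrix(c(2, 4), 1), c("a", "a"))
  ee <- estimate_eta(nc)
  expect_equal(unname(ee$mu_dg[1, 1]), 3)
  expect_equal(unname(ee$eta[1, 1]), log(3))

  ncc <- make_nc(matrix(7, 1, 3), rep("a", 3))
  expect_equal(unname(estimate_eta(ncc)$eta[1, 1]), log(7))

  nc0 <- make_nc(matrix(c(0, 0, 1, 2), 1), c("a", "a", "b", "b"))
  expect_error(estimate_eta(nc0), "zero mean")
})

test_that("moment effects reproduce three hand-worked decompositions", {
  # rows = conditions, cols = genes
  me <- moment_effects(rbind(c(1, 2), c(3, 4)), n_d = c(1, 1))
  expect_equal(me$mu, 2.5)
  expect_equal(unname(me$alpha), c(-1, 1))
  expect_equal(unname(me$beta), c(-0.5, 0.5))
  expect_equal(unname(me$gamma), matrix(0, 2, 2))

  me2 <- moment_effects(rbind(c(0, 2), c(2, 0)), n_d = c(1, 1))
  expect_equal(me2$mu, 1)
  expect_equal(unname(me2$alpha), c(0, 0))
  expect_equal(unname(me2$beta), c(0, 0))
  expect_equal(unname(me2$gamma), rbind(c(-1, 1), c(1, -1)))

  # sample-size-weighted decomposition
  me3 <- moment_effects(rbind(c(0, 0), c(4, 4)), n_d = c(1, 3))
  expect_equal(me3$mu, 3)
  expect_equal(unname(me3$alpha), c(-3, 1))
  expect_equal(sum(c(1, 3) * me3$alpha), 0)
  expect_equal(unname(me3$beta), c(0, 0))
  expect_equal(unname(me3$gamma), matrix(0, 2, 2))
})

test_that("moment effects satisfy the zero-sum identities exactly", {
  set.seed(12)
  for (i in 1:10) {
    D <- sample(2:5, 1)
    n_d <- sample(2:6, D, replace = TRUE)
    eta <- matrix(rnorm(D * 40), D, 40)
    me <- moment_effects(eta, n_d)
    expect_lt(abs(sum(n_d * me$alpha)), 1e-10)
    expect_lt(abs(sum(me$beta)), 1e-10)
    expect_lt(max(abs(colSums(me$gamma * n_d))), 1e-10)
    expect_lt(max(abs(rowSums(me$gamma))), 1e-10)
  }
})

test_that("rank-1 WLS solves the exact two-condition case by hand", {
  gamma <- rbind(c(-1, 1), c(1, -1))
  w <- wls_rank1(gamma, n_d = c(1, 1))
  expect_equal(unname(w$u), c(1, -1))
  expect_equal(unname(w$v), c(-1, 1))
  expect_lt(tail(w$objective_trace, 1), 1e-20)
})

test_that("any two-condition interaction is fitted exactly (rank <= 1)", {
  set.seed(42)
  for (i in 1:10) {
    n_d <- sample(2:8, 2)
    gamma <- rand_gamma(2, 50, n_d)
    w <- wls_rank1(gamma, n_d)
    expect_lt(max(abs(gamma - outer(w$u, w$v))), 1e-10)
  }
})

test_that("WLS objective matches the weighted SVD oracle on 200 instances", {
  set.seed(314)
  for (i in 1:200) {
    D <- sample(3:5, 1)
    G <- sample(20:100, 1)
    n_d <- sample(2:8, D, replace = TRUE)
    gamma <- rand_gamma(D, G, n_d)
    w <- wls_rank1(gamma, n_d)
    obj <- sum(n_d * (gamma - outer(w$u, w$v))^2)
    expect_lt(abs(obj - svd_rank1_objective(gamma, n_d)), 1e-8)
  }
})

test_that("power-iteration initialization reaches the same optimum", {
  set.seed(99)
  for (i in 1:20) {
    n_d <- sample(2:6, 4, replace = TRUE)
    gamma <- rand_gamma(4, 60, n_d)
    w <- wls_rank1(gamma, n_d, init = "means", tol = 1e-14,
                   max_iter = 5000)
    obj <- sum(n_d * (gamma - outer(w$u, w$v))^2)
    expect_lt(abs(obj - svd_rank1_objective(gamma, n_d)), 1e-6)
  }
})

test_that("the WLS objective trace is non-increasing", {
  set.seed(8)
  gamma <- rand_gamma(5, 80, rep(4, 5))
  w <- wls_rank1(gamma, rep(4, 5), init = "means")
  expect_true(all(diff(w$objective_trace) <= 1e-12))
})

test_that("degenerate interactions are rejected", {
  expect_error(wls_rank1(matrix(0, 3, 10), c(2, 2, 2)), "identically zero")
  nc <- make_nc(matrix(5, 4, 4), c("a", "a", "b", "b"))
  expect_error(fit_rank1(nc), "identically zero")
})

test_that("restricted u update reduces to and collapses from the full one", {
  set.seed(17)
  n_d <- c(3, 4, 5)
  gamma <- rand_gamma(3, 40, n_d)
  w <- wls_rank1(gamma, n_d)
  # S = all genes is the unrestricted update
  expect_equal(refine_u(gamma, w$v, seq_len(40)), w$u)
  # singleton S collapses to gamma_dg / v_g, rescaled
  g <- 7
  u1 <- refine_u(gamma, w$v, g)
  expect_equal(unname(u1), unname((gamma[, g] / w$v[g]) /
                                    (gamma[1, g] / w$v[g])))
  # empty S falls back with a warning
  expect_warning(u0 <- refine_u(gamma, w$v, integer(0)), "empty")
  expect_equal(u0, w$u)
})

test_that("restricting u to true DE genes reduces its sampling variance", {
  cfg <- sim_config(D = 3, G = 400, n_ee = 200, n_up = 100, n_down = 100,
                    design = "matched")
  u_full <- u_sub <- matrix(NA_real_, 50, 3)
  for (r in 1:50) {
    sim <- simulate_rank1(cfg, seed = 6000 + r)
    nc <- normalize_counts(sim$cm, size_factors(sim$cm, "median"))
    full <- fit_rank1(nc)
    sub <- fit_rank1(nc, de_set = which(sim$truth$v != 0))
    u_full[r, ] <- full$u
    u_sub[r, ] <- sub$u
  }
  # compare the non-reference coordinates' variance across replicates
  expect_lt(sum(apply(u_sub[, 2:3], 2, var)),
            sum(apply(u_full[, 2:3], 2, var)))
})

test_that("full fits satisfy every identifiability constraint", {
  for (seed in 1:5) {
    D <- 2 + (seed %% 3)
    cfg <- sim_config(D = D, G = 500, n_ee = 400, n_up = 50, n_down = 50,
                      design = if (seed %% 2) "matched" else "unmatched")
    sim <- simulate_rank1(cfg, seed = 100 + seed)
    nc <- normalize_counts(sim$cm, size_factors(sim$cm, "median"))
    fit <- fit_rank1(nc)
    expect_fit_constraints(fit, tol = 1e-8)
    expect_true(fit$converged)
  }
})

test_that("de_set covering all genes equals the unrestricted fit", {
  sim <- simulate_rank1(sim_config(D = 3, G = 300, n_ee = 240, n_up = 30,
                                   n_down = 30), seed = 77)
  nc <- normalize_counts(sim$cm, size_factors(sim$cm, "median"))
  f1 <- fit_rank1(nc)
  f2 <- fit_rank1(nc, de_set = seq_len(300))
  expect_equal(f1$u, f2$u)
  expect_equal(f1$v, f2$v)
})

test_that("u and v recover the generative values on rank-1 data", {
  errs <- vapply(1:5, function(r) {
    sim <- simulate_rank1(sim_config(D = 3, G = 2000, n_ee = 1800,
                                     n_up = 100, n_down = 100),
                          seed = 2024 + r)
    nc <- normalize_counts(sim$cm, size_factors(sim$cm, "median"))
    fit <- fit_rank1(nc)
    max(abs(fit$u - sim$truth$u))
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})
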