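test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(D = 3, G = 200, n_ee = 160, n_up = 20, n_down = 20)
  a <- simulate_rank1(cfg, seed = 99)
  b <- simulate_rank1(cfg, seed = 99)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_rank1(cfg, seed = 100)
  expect_false(identical(a$cm$counts, c$cm$counts))
})

test_that("configuration constraints are validated", {
  expect_error(sim_config(D = 3, u = c(2, 0.2, -1.2)), "u\\[1\\] = 1")
  expect_error(sim_config(D = 3, u = c(1, 1, 1)), "constraint")
  expect_error(sim_config(D = 3, G = 100, n_ee = 50, n_up = 10,
                          n_down = 10), "must equal G")
  # default u tables satisfy the constraints for both designs
  for (D in 2:5) {
    for (design in c("matched", "unmatched")) {
      cfg <- sim_config(D = D, design = design, G = 100, n_ee = 80,
                        n_up = 10, n_down = 10)
      expect_equal(cfg$u[1], 1)
      expect_lt(abs(sum(cfg$n_d * cfg$u)), 1e-10)
    }
  }
})

test_that("generative truth satisfies the model constraints", {
  for (design in c("matched", "unmatched")) {
    sim <- simulate_rank1(sim_config(D = 4, G = 300, n_ee = 240, n_up = 30,
                                     n_down = 30, design = design),
                          seed = 5)
    tr <- sim$truth
    cfg_n <- samples_per_condition(sim$cm)
    expect_lt(max(abs(colSums(tr$gamma * as.integer(cfg_n)))), 1e-10)
    expect_equal(tr$v == 0, tr$de_label == "EE")
    expect_true(all(tr$v[tr$de_label == "up"] < 0))
    expect_true(all(tr$v[tr$de_label == "down"] > 0))
    expect_true(all(tr$phi > 0) && all(tr$delta > 0))
  }
})

test_that("simulated counts match the NB mean and variance identities", {
  # many matched subjects act as replicate draws of each (d, g) cell
  cfg <- sim_config(D = 3, G = 4, n = 6000, n_ee = 4, n_up = 0, n_down = 0,
                    rho = diag(1, 3))
  sim <- simulate_rank1(cfg, seed = 314)
  y <- round(sweep(sim$cm$counts, 2, sim$truth$delta, "/"))
  mu_true <- exp(4 + sim$truth$beta)          # v = 0 for every gene
  for (d in 1:3) {
    cols <- sim$cm$condition == paste0("cond", d)
    m <- rowMeans(y[, cols])
    s2 <- apply(y[, cols], 1, var)
    expect_lt(max(abs(m - mu_true) / mu_true), 0.02)
    v_true <- mu_true + sim$truth$phi * mu_true^2
    expect_lt(max(abs(s2 - v_true) / v_true), 0.15)
  }
})

test_that("pooled standardized residuals have mean 0 and variance 1", {
  cfg <- sim_config(D = 3, G = 2000, n_ee = 1600, n_up = 200, n_down = 200)
  sim <- simulate_rank1(cfg, seed = 11)
  y <- round(sweep(sim$cm$counts, 2, sim$truth$delta, "/"))
  mu <- exp(sim$truth$mu +
              matrix(sim$truth$beta, 3, 2000, byrow = TRUE) +
              sim$truth$gamma)
  phi <- sim$truth$phi
  z <- NULL
  for (d in 1:3) {
    cols <- sim$cm$condition == paste0("cond", d)
    sd_dg <- sqrt(mu[d, ] + phi * mu[d, ]^2)
    z <- c(z, (y[, cols] - mu[d, ]) / sd_dg)
  }
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(stats::var(z) - 1), 0.1)
})

test_that("the copula reproduces the target latent correlation", {
  cfg <- sim_config(D = 2, G = 300, n = 400, n_ee = 240, n_up = 30,
                    n_down = 30, rho = 0.3)
  sim <- simulate_rank1(cfg, seed = 2718, keep_latent = TRUE)
  z <- sim$truth$Z
  r <- vapply(seq_len(300), function(g) cor(z[, g, 1], z[, g, 2]),
              numeric(1))
  expect_lt(abs(mean(r) - 0.3), 0.05)
})

test_that("saturated interactions are full rank and degenerate at zero range", {
  cfg <- sim_config(D = 4, G = 500, n_ee = 250, n_up = 125, n_down = 125)
  sim <- simulate_saturated(cfg, seed = 13)
  g_de <- sim$truth$gamma[, sim$truth$de_label == "DE"]
  sv <- svd(g_de)$d
  expect_gt(sv[2] / sv[1], 0.1)  # decisively not rank 1
  expect_lt(max(abs(colSums(g_de * cfg$n_d))), 1e-10)
  expect_equal(levels(sim$truth$de_label), c("EE", "DE"))

  deg <- simulate_saturated(cfg, gamma_range = c(0, 0), seed = 13)
  expect_equal(max(abs(deg$truth$gamma)), 0)
})

test_that("the rank-1 test still ranks DE genes first under misspecification", {
  cfg <- sim_config(D = 3, G = 2000, n_ee = 1600, n_up = 200, n_down = 200,
                    design = "unmatched")
  sim <- simulate_saturated(cfg, seed = 29)
  res <- de_test(sim$cm, normalization = "median")
  expect_gt(roc_curve(res$table$p, sim$truth$de_label)$auc, 0.5)
})

test_that("spike-in perturbation scales, rounds, and labels correctly", {
  set.seed(47)
  counts <- matrix(rnbinom(6526 * 9, mu = 100, size = 2), 6526, 9)
  sp <- spike_in_perturbation(counts, D = 3, de_count = 600, seed = 7)
  expect_equal(sum(sp$truth$de_label == "DE"), 600)
  n_d <- samples_per_condition(sp$cm)   # level order follows the permutation
  expect_equal(unname(n_d[paste0("cond", 1:3)]), rep(3L, 3))
  # count 10 under factor 1.1 becomes 11
  g <- sp$truth$de_genes[1]
  cols2 <- sp$truth$assignment == 2
  expect_equal(unname(sp$cm$counts[g, cols2]),
               unname(round(counts[g, cols2] * 1.1)))
  cols3 <- sp$truth$assignment == 3
  expect_equal(unname(sp$cm$counts[g, cols3]),
               unname(round(counts[g, cols3] * 0.9)))
  # EE genes and condition-1 columns are untouched
  ee <- which(sp$truth$de_label == "EE")
  expect_equal(unname(sp$cm$counts[ee, ]), unname(counts[ee, ]))

  # unit factors leave all counts identical
  sp1 <- spike_in_perturbation(counts, D = 3, de_count = 600,
                               factors = c(1, 1, 1), seed = 7)
  expect_equal(unname(sp1$cm$counts), unname(counts))

  expect_error(spike_in_perturbation(counts[, 1:8], D = 3, de_count = 5),
               "divisible")
  expect_error(spike_in_perturbation(counts, D = 3, de_count = 10^6),
               "exceeds")
})
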