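#' Simulation configuration for multi-condition RNA-seq counts
#'
#' Bundles the generative parameters of the count simulator. The
#' defaults are the study conditions of the package's validation
#' simulations: grand mean `mu = 4` (natural-log scale), no condition
#' main effects, gene effects `beta_g ~ N(0, 0.25^2)`, dispersions
#' `phi_g ~ Gamma(shape 5, rate 20)`, size factors
#' `delta_id ~ LogNormal(0, 0.25^2)`, 90% equally expressed genes and
#' 5% up- / 5% down-regulated genes with half-normal interaction scores
#' of variance 0.32, condition scores `u_d` from fixed reference tables
#' (below), `n = 4` subjects per condition in the matched design and
#' `n_d = D + d - 1` samples in the unmatched design, and latent
#' between-condition correlations `rho ~ U(0.2, 0.4)` for matched
#' samples (0 for unmatched).
#'
#' Default `u` tables (satisfying `u_1 = 1`, `sum_d n_d u_d = 0`):
#' matched `(1,-1)`, `(1,0.2,-1.2)`, `(1,0.4,-0.6,-0.8)`,
#' `(1,0.5,0,-0.5,-1)` for `D = 2..5`; unmatched `(1,-2/3)`,
#' `(1,3/4,-6/5)`, `(1,4/5,-3/6,-5/7)`, `(1,5/6,3/7,-5/8,-8/9)`.
#'
#' @param D number of conditions (2-5 have default `u` tables; other
#'   `D` require `u`).
#' @param design `"matched"` or `"unmatched"`.
#' @param G number of genes.
#' @param n samples per condition: a scalar (matched) or a length-`D`
#'   vector (unmatched); defaults as above.
#' @param mu grand mean of log expression.
#' @param u per-condition interaction scores (`u[1] = 1`,
#'   `sum(n_d * u) = 0`); defaults from the reference tables.
#' @param n_ee,n_up,n_down numbers of equally expressed, up- and
#'   down-regulated genes (`n_ee + n_up + n_down = G`); default 90/5/5
#'   percent of `G`.
#' @param v_scale scale of the half-normal draw of `|v_g|` for DE
#'   genes; interpreted as a *variance* unless `v_scale_is_sd = TRUE`.
#' @param v_scale_is_sd interpret `v_scale` as a standard deviation.
#' @param beta_sd standard deviation of the gene main effects.
#' @param delta_log_sd log-scale standard deviation of the size
#'   factors.
#' @param phi_shape,phi_rate gamma parameters of the dispersion draw.
#' @param rho fixed latent correlation: a scalar or `D x D` matrix
#'   (matched only); overrides `rho_range`.
#' @param rho_range interval the pairwise latent correlations are drawn
#'   from (matched only), default `c(0.2, 0.4)`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(D = 3, design = c("matched", "unmatched"),
                       G = 10000, n = NULL, mu = 4, u = NULL,
                       n_ee = NULL, n_up = NULL, n_down = NULL,
                       v_scale = 0.32, v_scale_is_sd = FALSE,
                       beta_sd = 0.25, delta_log_sd = 0.25,
                       phi_shape = 5, phi_rate = 20,
                       rho = NULL, rho_range = c(0.2, 0.4)) {
  design <- match.arg(design)
  stopifnot(D >= 2, G >= 2)
  if (is.null(n)) {
    n <- if (design == "matched") 4L else D + seq_len(D) - 1L
  }
  n_d <- if (design == "matched") {
    stopifnot(length(n) == 1L)
    rep(as.integer(n), D)
  } else {
    if (length(n) == 1L) rep(as.integer(n), D) else as.integer(n)
  }
  stopifnot(length(n_d) == D, all(n_d >= 2))

  if (is.null(u)) u <- .default_u(D, design)
  if (length(u) != D) stop("'u' must have length D")
  if (abs(u[1] - 1) > 1e-8) stop("'u' must be anchored at u[1] = 1")
  if (abs(sum(n_d * u)) > 1e-8) {
    stop("'u' violates the constraint sum(n_d * u) = 0 for these ",
         "sample sizes")
  }

  if (is.null(n_ee)) n_ee <- round(0.90 * G)
  if (is.null(n_up)) n_up <- round(0.05 * G)
  if (is.null(n_down)) n_down <- G - n_ee - n_up
  if (n_ee + n_up + n_down != G || min(n_ee, n_up, n_down) < 0) {
    stop("'n_ee' + 'n_up' + 'n_down' must equal G (all non-negative)")
  }

  if (!is.null(rho)) {
    rho <- if (is.matrix(rho)) rho else matrix(rho, D, D) + diag(1 - rho, D)
    stopifnot(nrow(rho) == D, ncol(rho) == D, all(diag(rho) == 1))
  }

  structure(list(D = D, design = design, G = G, n_d = n_d, mu = mu, u = u,
                 n_ee = n_ee, n_up = n_up, n_down = n_down,
                 v_scale = v_scale, v_scale_is_sd = v_scale_is_sd,
                 beta_sd = beta_sd, delta_log_sd = delta_log_sd,
                 phi_shape = phi_shape, phi_rate = phi_rate,
                 rho = rho, rho_range = rho_range),
            class = "sim_config")
}

.default_u <- function(D, design) {
  tabs <- if (design == "matched") {
    list(`2` = c(1, -1), `3` = c(1, 0.2, -1.2), `4` = c(1, 0.4, -0.6, -0.8),
         `5` = c(1, 0.5, 0, -0.5, -1))
  } else {
    list(`2` = c(1, -2/3), `3` = c(1, 3/4, -6/5),
         `4` = c(1, 4/5, -3/6, -5/7), `5` = c(1, 5/6, 3/7, -5/8, -8/9))
  }
  u <- tabs[[as.character(D)]]
  if (is.null(u)) stop("no default 'u' table for D = ", D, "; supply 'u'")
  u
}

#' Simulate counts under the rank-1 interaction model
#'
#' Draws, in this order: the DE gene scores `v_g` (0 for equally
#' expressed genes, `-|N(0, s)|` for up-regulated, `+|N(0, s)|` for
#' down-regulated — the signs follow the convention that a negative
#' score in a positive-`u` condition lowers expression there), the gene
#' effects `beta_g`, the dispersions `phi_g`, the size factors
#' `delta_id`, the pairwise latent correlations (matched designs), the
#' latent expressions `Z_idg` from gamma marginals with mean `mu_dg =
#' exp(mu + beta_g + u_d v_g)` and variance `phi_g mu_dg^2` coupled
#' across conditions by a Gaussian copula, and finally the read counts
#' `X_idg ~ Poisson(Z_idg * delta_id)`. Identical seeds give
#' bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param keep_latent also return the latent expressions `Z` in the
#'   truth (as a `samples x genes x conditions`-shaped matrix per
#'   condition block), for calibration checks.
#' @return list with `cm` (a [count_matrix()] of the raw counts `X`)
#'   and `truth`: the generative parameters (`mu`, `alpha`, `beta`,
#'   `gamma`, `u`, `v`, `phi`, `delta`, `rho`) and the per-gene
#'   `de_label` (`"EE"`, `"up"`, `"down"`).
#' @export
simulate_rank1 <- function(cfg, seed = NULL, keep_latent = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  v_sd <- if (cfg$v_scale_is_sd) cfg$v_scale else sqrt(cfg$v_scale)
  v <- c(rep(0, cfg$n_ee),
         -abs(stats::rnorm(cfg$n_up, 0, v_sd)),
         abs(stats::rnorm(cfg$n_down, 0, v_sd)))
  de_label <- rep(c("EE", "up", "down"),
                  c(cfg$n_ee, cfg$n_up, cfg$n_down))
  gamma <- outer(cfg$u, v)
  .simulate_counts(cfg, gamma, v = v, de_label = de_label,
                   keep_latent = keep_latent)
}

#' Simulate counts under a saturated (full-rank) interaction model
#'
#' Sensitivity-analysis design: identical to [simulate_rank1()] except
#' that the DE genes' interactions `gamma_dg` are drawn i.i.d. uniform
#' on `gamma_range` — not expressible as a rank-1 product for
#' `D >= 3` — and then re-centered (sample-size weighted) so each gene
#' satisfies `sum_d n_d gamma_dg = 0`, keeping the fitted interaction a
#' well-defined target. Equally expressed genes get `gamma = 0`.
#'
#' @param cfg a [sim_config()]; `n_up + n_down` genes are DE.
#' @param gamma_range interval of the uniform draw, default
#'   `c(-0.75, 0.75)`.
#' @param seed integer seed.
#' @return as [simulate_rank1()], with `truth$gamma` the full matrix,
#'   `truth$v = NULL`, and `de_label` in `{"EE", "DE"}`.
#' @export
simulate_saturated <- function(cfg, gamma_range = c(-0.75, 0.75),
                               seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(gamma_range) == 2)
  if (!is.null(seed)) set.seed(seed)
  n_de <- cfg$n_up + cfg$n_down
  gamma <- matrix(0, cfg$D, cfg$G)
  if (n_de > 0) {
    g_de <- matrix(stats::runif(cfg$D * n_de, gamma_range[1],
                                gamma_range[2]), cfg$D, n_de)
    ## weighted re-centering: sum_d n_d gamma_dg = 0 per gene
    g_de <- g_de - matrix(colSums(g_de * cfg$n_d) / sum(cfg$n_d),
                          cfg$D, n_de, byrow = TRUE)
    gamma[, cfg$n_ee + seq_len(n_de)] <- g_de
  }
  de_label <- rep(c("EE", "DE"), c(cfg$n_ee, n_de))
  .simulate_counts(cfg, gamma, v = NULL, de_label = de_label)
}

## shared generative core: beta, phi, delta, rho, copula-coupled gamma
## latents, Poisson counts
.simulate_counts <- function(cfg, gamma, v, de_label, keep_latent = FALSE) {
  D <- cfg$D; G <- cfg$G; n_d <- cfg$n_d
  beta <- stats::rnorm(G, 0, cfg$beta_sd)
  phi <- stats::rgamma(G, shape = cfg$phi_shape, rate = cfg$phi_rate)
  delta <- stats::rlnorm(sum(n_d), 0, cfg$delta_log_sd)
  mu_dg <- exp(cfg$mu + matrix(beta, D, G, byrow = TRUE) + gamma)

  matched <- cfg$design == "matched"
  rho <- NULL
  if (matched) {
    rho <- cfg$rho
    if (is.null(rho)) {
      rho <- diag(1, D)
      for (d1 in seq_len(D - 1)) {
        for (d2 in (d1 + 1):D) {
          rho[d1, d2] <- rho[d2, d1] <-
            stats::runif(1, cfg$rho_range[1], cfg$rho_range[2])
        }
      }
    }
    L <- tryCatch(chol(rho), error = function(e)
      stop("latent correlation matrix is not positive definite"))
  }

  cond_labels <- paste0("cond", seq_len(D))
  condition <- rep(cond_labels, n_d)

  X <- matrix(0, G, sum(n_d))
  Zkeep <- if (keep_latent) array(NA_real_, c(if (matched) n_d[1] else 0,
                                              G, D)) else NULL
  if (matched) {
    n <- n_d[1]
    shape <- rep(1 / phi, each = n)
    ## rows index (subject within gene); copula couples the D columns
    E <- matrix(stats::rnorm(n * G * D), n * G, D) %*% L
    U <- stats::pnorm(E)
    for (d in seq_len(D)) {
      col0 <- (d - 1) * n
      scale_d <- rep(mu_dg[d, ] * phi, each = n)
      Z <- stats::qgamma(U[, d], shape = shape, scale = scale_d)
      if (keep_latent) Zkeep[, , d] <- matrix(Z, n, G)
      lam <- Z * rep(delta[col0 + seq_len(n)], times = G)
      X[, col0 + seq_len(n)] <- t(matrix(stats::rpois(n * G, lam), n, G))
    }
    subject <- rep(paste0("subj", seq_len(n)), D)
    sample_ids <- paste0(condition, "_", subject)
  } else {
    col0 <- 0
    for (d in seq_len(D)) {
      nd <- n_d[d]
      U <- stats::pnorm(stats::rnorm(nd * G))
      Z <- stats::qgamma(U, shape = rep(1 / phi, each = nd),
                         scale = rep(mu_dg[d, ] * phi, each = nd))
      lam <- Z * rep(delta[col0 + seq_len(nd)], times = G)
      X[, col0 + seq_len(nd)] <- t(matrix(stats::rpois(nd * G, lam), nd, G))
      col0 <- col0 + nd
    }
    subject <- NULL
    sample_ids <- paste0(condition, "_rep",
                         unlist(lapply(n_d, seq_len)))
  }

  gene_ids <- paste0("gene", seq_len(G))
  dimnames(X) <- list(gene_ids, sample_ids)
  names(delta) <- sample_ids
  cm <- count_matrix(X, condition, subject)
  truth <- list(mu = cfg$mu, alpha = rep(0, D), beta = beta, gamma = gamma,
                u = if (is.null(v)) NULL else cfg$u, v = v, phi = phi,
                delta = delta, rho = rho,
                de_label = factor(de_label, levels = unique(de_label)),
                Z = Zkeep)
  list(cm = cm, truth = truth)
}

#' Spike-in perturbation of a real count matrix
#'
#' Builds a semi-synthetic benchmark from any count matrix: samples are
#' randomly reassigned to `D` equal-sized condition groups (breaking
#' any real condition structure), a random subset of genes is declared
#' DE, and those genes' counts are multiplied by a per-condition factor
#' (default `(1, 1.1, 0.9)` for `D = 3`) and rounded to the nearest
#' integer. All remaining genes are equally expressed by construction.
#'
#' @param cm a [count_matrix()] (or a bare count matrix) whose number
#'   of samples is divisible by `D`.
#' @param D number of condition groups.
#' @param de_count number of DE genes (alternatively `de_fraction`).
#' @param de_fraction fraction of DE genes.
#' @param factors per-condition multiplicative perturbations (length
#'   `D`); default `c(1, 1.1, 0.9)` when `D = 3`.
#' @param seed integer seed.
#' @return list with `cm` (perturbed counts, new condition labels,
#'   unmatched) and `truth` (with `de_label` in `{"EE", "DE"}`,
#'   `factors`, and the permuted assignment).
#' @export
spike_in_perturbation <- function(cm, D = 3, de_count = NULL,
                                  de_fraction = NULL, factors = NULL,
                                  seed = NULL) {
  if (inherits(cm, "count_matrix")) cm <- cm$counts
  cm <- as.matrix(cm)
  N <- ncol(cm); G <- nrow(cm)
  if (N %% D != 0) {
    stop("number of samples (", N, ") is not divisible into ", D,
         " equal condition groups")
  }
  if (is.null(factors)) {
    if (D != 3) stop("default perturbation factors exist only for D = 3")
    factors <- c(1, 1.1, 0.9)
  }
  stopifnot(length(factors) == D, all(factors > 0))
  if (is.null(de_count)) {
    if (is.null(de_fraction)) stop("supply 'de_count' or 'de_fraction'")
    de_count <- round(de_fraction * G)
  }
  if (de_count > G) stop("'de_count' exceeds the number of genes")
  if (!is.null(seed)) set.seed(seed)

  assignment <- sample(rep(seq_len(D), each = N %/% D))
  de_genes <- sort(sample(G, de_count))
  out <- cm
  for (d in seq_len(D)) {
    cols <- assignment == d
    out[de_genes, cols] <- round(out[de_genes, cols] * factors[d])
  }
  de_label <- factor(ifelse(seq_len(G) %in% de_genes, "DE", "EE"),
                     levels = c("EE", "DE"))
  cm_out <- count_matrix(out, paste0("cond", assignment))
  list(cm = cm_out,
       truth = list(de_label = de_label, de_genes = de_genes,
                    factors = factors, assignment = assignment))
}
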