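#' Condition-by-gene mean log expression
#'
#' Estimates `mu_dg` by the within-condition sample mean of the
#' normalized counts and `eta_dg = log(mu_dg)` (natural log).
#'
#' @param nc a [normalized_counts()] object.
#' @return list with `eta` and `mu_dg`, both `D x G` matrices (rows =
#'   conditions in level order, columns = genes).
#' @export
estimate_eta <- function(nc) {
  stopifnot(inherits(nc, "normalized_counts"))
  y <- nc$values
  cond <- nc$condition
  mu_dg <- t(vapply(levels(cond), function(lev) {
    rowMeans(y[, cond == lev, drop = FALSE])
  }, numeric(nrow(y))))
  if (any(mu_dg == 0)) {
    bad <- which(mu_dg == 0, arr.ind = TRUE)[1, ]
    stop("zero mean count for gene '", colnames(mu_dg)[bad[2]],
         "' in condition '", rownames(mu_dg)[bad[1]],
         "'; apply filter_genes() first")
  }
  list(eta = log(mu_dg), mu_dg = mu_dg)
}

#' Moment estimators of the main and interaction effects
#'
#' Decomposes the condition-by-gene log-mean matrix into a grand mean,
#' condition and gene main effects, and an interaction matrix, under
#' the sample-size-weighted identifiability constraints
#' `sum_d n_d alpha_d = 0`, `sum_g beta_g = 0`,
#' `sum_d n_d gamma_dg = 0` (each gene) and `sum_g gamma_dg = 0`
#' (each condition). The constraints hold exactly by construction.
#'
#' @param eta `D x G` matrix of log mean expressions (from
#'   [estimate_eta()]).
#' @param n_d integer vector of samples per condition (length `D`).
#' @return list with `mu` (scalar), `alpha` (length `D`), `beta`
#'   (length `G`), `gamma` (`D x G`).
#' @export
moment_effects <- function(eta, n_d) {
  stopifnot(is.matrix(eta), length(n_d) == nrow(eta), all(is.finite(eta)))
  D <- nrow(eta); G <- ncol(eta); N <- sum(n_d)
  mu <- sum(n_d * rowSums(eta)) / (G * N)
  alpha <- rowMeans(eta) - mu
  beta <- colSums(eta * n_d) / N - mu
  gamma <- eta - mu - matrix(alpha, D, G) - matrix(beta, D, G, byrow = TRUE)
  list(mu = mu, alpha = alpha, beta = beta, gamma = gamma)
}

#' Constrained rank-1 decomposition of the interaction matrix
#'
#' Minimizes the weighted least-squares objective
#' `l(u, v) = sum_dg n_d (gamma_dg - u_d v_g)^2` by alternating the two
#' closed-form updates (`u` given `v`, then `v` given `u`), anchoring
#' `u[reference] = 1` after each `u` update. The constraints
#' `sum_d n_d u_d = 0` and `sum_g v_g = 0` hold automatically because
#' `gamma` satisfies the corresponding zero-sum identities. The
#' objective is non-increasing across iterations.
#'
#' `v` is initialized from the leading right singular vector of the
#' `sqrt(n_d)`-row-scaled `gamma` (`init = "svd"`, fast and
#' deterministic) or from the column means (`init = "means"`).
#'
#' @param gamma `D x G` interaction matrix satisfying the model's
#'   zero-sum constraints (not identically zero).
#' @param n_d samples per condition.
#' @param max_iter maximum number of alternating updates (default 500).
#' @param tol relative objective-change convergence threshold (default
#'   `1e-10`).
#' @param reference index of the condition anchored at `u = 1`
#'   (default 1).
#' @param de_set optional integer/logical index of genes used in the
#'   `u` update (see [refine_u()]); all genes are always used in the
#'   `v` update.
#' @param init initialization of `v`: `"svd"` or `"means"`.
#' @return list with `u`, `v`, `iterations`, `converged`,
#'   `objective_trace`.
#' @export
wls_rank1 <- function(gamma, n_d, max_iter = 500, tol = 1e-10,
                      reference = 1, de_set = NULL,
                      init = c("svd", "means")) {
  stopifnot(is.matrix(gamma), length(n_d) == nrow(gamma))
  init <- match.arg(init)
  if (all(abs(gamma) < 1e-12)) {
    stop("interaction matrix is identically zero; ",
         "no rank-1 structure to estimate")
  }
  if (!is.null(de_set)) {
    de_set <- .resolve_gene_set(de_set, colnames(gamma), ncol(gamma))
  }
  v <- if (init == "svd") {
    sv <- svd(sqrt(n_d) * gamma, nu = 0, nv = 1)
    sv$d[1] * sv$v[, 1]
  } else {
    colMeans(gamma)
  }
  ## column means vanish under equal group sizes; fall back to the row
  ## of gamma with the largest norm
  if (all(abs(v) < 1e-12)) v <- gamma[which.max(rowSums(gamma^2)), ]

  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    u <- .update_u(gamma, v, de_set, reference)
    v <- colSums(gamma * (n_d * u)) / sum(n_d * u^2)
    obj <- sum(n_d * (gamma - outer(u, v))^2)
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(prev - obj) < tol * max(abs(prev), 1)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  names(u) <- rownames(gamma)
  names(v) <- colnames(gamma)
  list(u = u, v = v, iterations = it, converged = converged,
       objective_trace = trace)
}

## Eq for u given v, restricted to a gene set when supplied, rescaled so
## u[reference] = 1
.update_u <- function(gamma, v, de_set, reference) {
  idx <- if (is.null(de_set)) seq_len(ncol(gamma)) else de_set
  denom <- sum(v[idx]^2)
  if (denom == 0) stop("'v' is identically zero on the gene set")
  ut <- as.vector(gamma[, idx, drop = FALSE] %*% v[idx]) / denom
  if (abs(ut[reference]) < 1e-8 * max(abs(ut))) {
    stop("unstable reference: u for the reference condition is ",
         "numerically zero; re-anchor with a different 'reference'")
  }
  ut / ut[reference]
}

.resolve_gene_set <- function(de_set, genes, G) {
  if (is.logical(de_set)) de_set <- which(de_set)
  if (is.character(de_set)) {
    idx <- match(de_set, genes)
    if (anyNA(idx)) stop("unknown gene(s) in 'de_set'")
    de_set <- idx
  }
  de_set <- unique(as.integer(de_set))
  if (length(de_set) == 0) {
    warning("empty DE gene set; falling back to all genes")
    return(NULL)
  }
  if (any(de_set < 1 | de_set > G)) stop("'de_set' indices out of range")
  de_set
}

#' Re-estimate u over a restricted DE gene set
#'
#' For data dominated by equally expressed genes (true `v_g = 0`), the
#' unrestricted `u` update averages over pure noise. Restricting the
#' sums to a DE gene set `S` removes that noise and reduces the
#' variance of the estimate. An empty `S` falls back to all genes with
#' a warning.
#'
#' @param gamma `D x G` interaction matrix.
#' @param v current per-gene interaction scores.
#' @param de_set gene subset (indices, logical mask, or gene names).
#' @param reference condition anchored at `u = 1`.
#' @return rescaled `u` (length `D`, `u[reference] = 1`).
#' @export
refine_u <- function(gamma, v, de_set, reference = 1) {
  de_set <- .resolve_gene_set(de_set, colnames(gamma), ncol(gamma))
  u <- .update_u(gamma, v, de_set, reference)
  names(u) <- rownames(gamma)
  u
}

#' Fit the rank-1 interaction model
#'
#' Composes [estimate_eta()], [moment_effects()] and [wls_rank1()] into
#' a complete fit of the two-factor log-linear model with rank-1
#' interaction `log mu_dg = mu + alpha_d + beta_g + u_d v_g`.
#'
#' @param nc a [normalized_counts()] object.
#' @param de_set optional gene subset used to refine the `u` update
#'   (see [refine_u()]).
#' @param max_iter,tol,reference,init passed to [wls_rank1()].
#' @return an object of class `rank1_fit`: the moment estimates (`mu`,
#'   `alpha`, `beta`, `gamma`, `eta`, `mu_dg`), the rank-1 factors
#'   (`u`, `v`), the design (`n_d`, `conditions`, `matched`), and
#'   convergence diagnostics (`iterations`, `converged`,
#'   `objective_trace`).
#' @export
fit_rank1 <- function(nc, de_set = NULL, max_iter = 500, tol = 1e-10,
                      reference = 1, init = "svd") {
  stopifnot(inherits(nc, "normalized_counts"))
  if (nlevels(nc$condition) < 2) {
    stop("model fitting requires at least two conditions")
  }
  n_d <- samples_per_condition(nc)
  ee <- estimate_eta(nc)
  me <- moment_effects(ee$eta, n_d)
  w <- wls_rank1(me$gamma, n_d, max_iter = max_iter, tol = tol,
                 reference = reference, de_set = de_set, init = init)
  structure(
    list(mu = me$mu, alpha = me$alpha, beta = me$beta, gamma = me$gamma,
         u = w$u, v = w$v, eta = ee$eta, mu_dg = ee$mu_dg,
         n_d = n_d, conditions = levels(nc$condition),
         matched = !is.null(nc$subject), reference = reference,
         iterations = w$iterations, converged = w$converged,
         objective_trace = w$objective_trace),
    class = "rank1_fit"
  )
}

#' @export
print.rank1_fit <- function(x, ...) {
  cat(sprintf("rank1_fit: %d conditions x %d genes (%s design)\n",
              length(x$u), length(x$v),
              if (x$matched) "matched" else "unmatched"))
  cat(sprintf("  grand mean mu = %.4f; converged in %d iteration(s)\n",
              x$mu, x$iterations))
  cat("  u:", paste(sprintf("%s=%.3f", x$conditions, x$u), collapse = ", "),
      "\n")
  invisible(x)
}
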