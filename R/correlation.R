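#' Between-condition correlation of latent expressions (matched designs)
#'
#' In a matched design the latent expressions of the same subject are
#' correlated across conditions with a coefficient `rho_{d1d2}` shared
#' by all genes. For each condition pair the estimator computes, per
#' gene, the subject-paired sample correlation of the normalized counts,
#' applies a small-sample (continuity) correction, rescales it by the
#' negative-binomial factor
#' `sqrt((mu1 + mu1^2 phi)(mu2 + mu2^2 phi)) / (mu1 mu2 phi)` that maps
#' the count-scale correlation back to the latent scale, averages over
#' genes, and clamps to `[-1, 1]`.
#'
#' Genes with zero within-pair variance, a non-finite correlation, or a
#' dispersion at the numerical floor (`phi < phi_min`, where the
#' rescaling factor diverges) are excluded; the exclusion counts are
#' recorded per pair.
#'
#' The default correction is an Olkin-Pratt-type expansion
#' `r * (1 + (1 - r^2) / (2 (n - 3)))`, applied for `n >= 4` subjects
#' and skipped for `n = 3`; `correction = "none"` disables it.
#'
#' @param nc a matched [normalized_counts()] object with at least 3
#'   subjects.
#' @param fit a [fit_rank1()] fit on `nc` (provides `mu_dg`).
#' @param phi a `dispersion_set` for the genes of `nc`.
#' @param correction `"olkin-pratt"` (default) or `"none"`.
#' @param phi_min genes with `phi` below this are excluded from the
#'   average (default `1e-3`): for effectively Poisson genes the
#'   latent-scale rescaling factor diverges as `1/phi` while the count
#'   correlation carries almost no information about `rho`, so such
#'   genes contribute unbounded noise.
#' @return an object of class `rho_estimate`: list with `rho` (symmetric
#'   `D x D` matrix, unit diagonal), `per_gene_r` (pairs x genes matrix
#'   of corrected count-scale correlations), `n_subjects`, `genes_used`
#'   and `genes_skipped` per pair, `correction`.
#' @export
estimate_rho <- function(nc, fit, phi, correction = c("olkin-pratt", "none"),
                         phi_min = 1e-3) {
  stopifnot(inherits(nc, "normalized_counts"), inherits(fit, "rank1_fit"),
            inherits(phi, "dispersion_set"))
  correction <- match.arg(correction)
  if (is.null(nc$subject)) {
    stop("correlation estimation requires a matched design ",
         "(subject annotations)")
  }
  cond <- nc$condition
  subj <- nc$subject
  D <- nlevels(cond)
  n <- nlevels(subj)
  if (n < 3) stop("at least 3 subjects are required to estimate rho")
  G <- nrow(nc$values)
  phi_g <- phi$phi[rownames(nc$values)]

  ## G x n x D array, subjects aligned across conditions
  y <- array(NA_real_, dim = c(G, n, D))
  for (d in seq_len(D)) {
    cols <- which(cond == levels(cond)[d])
    cols <- cols[match(levels(subj), subj[cols])]
    y[, , d] <- nc$values[, cols]
  }

  pairs <- utils::combn(D, 2)
  rho <- diag(1, D)
  dimnames(rho) <- list(levels(cond), levels(cond))
  per_gene_r <- matrix(NA_real_, ncol(pairs), G,
                       dimnames = list(apply(pairs, 2, function(p)
                         paste(levels(cond)[p], collapse = ":")),
                         rownames(nc$values)))
  genes_used <- genes_skipped <- integer(ncol(pairs))

  for (k in seq_len(ncol(pairs))) {
    d1 <- pairs[1, k]; d2 <- pairs[2, k]
    r <- .row_cor(y[, , d1], y[, , d2])
    if (correction == "olkin-pratt" && n >= 4) {
      r <- pmin(pmax(r * (1 + (1 - r^2) / (2 * (n - 3))), -1), 1)
    }
    per_gene_r[k, ] <- r
    scale <- .rho_scale(fit$mu_dg[d1, ], fit$mu_dg[d2, ], phi_g)
    use <- is.finite(r) & phi_g >= phi_min
    genes_used[k] <- sum(use)
    genes_skipped[k] <- G - sum(use)
    if (!any(use)) stop("no usable genes for condition pair ",
                        rownames(per_gene_r)[k])
    est <- mean(r[use] * scale[use])
    rho[d1, d2] <- rho[d2, d1] <- min(max(est, -1), 1)
  }
  if (any(genes_skipped > 0)) {
    message("estimate_rho: skipped ", max(genes_skipped),
            " gene(s) per pair (zero variance or dispersion at floor)")
  }
  structure(list(rho = rho, per_gene_r = per_gene_r, n_subjects = n,
                 genes_used = genes_used, genes_skipped = genes_skipped,
                 correction = correction),
            class = "rho_estimate")
}

## NB rescaling from the count-scale correlation back to the latent
## scale: corr(Y1, Y2) = rho * mu1 mu2 phi / sqrt((mu1 + mu1^2 phi)
## (mu2 + mu2^2 phi)), inverted here
.rho_scale <- function(mu1, mu2, phi) {
  sqrt((mu1 + mu1^2 * phi) * (mu2 + mu2^2 * phi)) / (mu1 * mu2 * phi)
}

## row-wise Pearson correlation of two G x n matrices; NA where either
## row is constant
.row_cor <- function(a, b) {
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  r <- rowSums(ca * cb) / den
  r[den == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("rho_estimate (%s correction, %d subjects):\n",
              x$correction, x$n_subjects))
  print(round(x$rho, 3))
  invisible(x)
}
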