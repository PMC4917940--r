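#' Variance of the per-gene interaction score (unmatched design)
#'
#' Plug-in variance of `v_g` treating the grand mean, main effects and
#' `u` as known (they pool information across all genes, so their
#' variances are negligible relative to the per-gene quantities):
#' `var(v_g) = sum_d n_d u_d^2 (1/mu_dg + phi_g) / (sum_d n_d u_d^2)^2`.
#'
#' @param fit a [fit_rank1()] object.
#' @param phi a `dispersion_set`.
#' @return named numeric vector of per-gene variances.
#' @export
var_v_unmatched <- function(fit, phi) {
  stopifnot(inherits(fit, "rank1_fit"), inherits(phi, "dispersion_set"))
  u <- fit$u; n_d <- fit$n_d
  su <- sum(n_d * u^2)
  if (su <= 0) stop("degenerate u: sum(n_d * u^2) must be positive")
  phi_g <- phi$phi[colnames(fit$mu_dg)]
  m <- 1 / fit$mu_dg + matrix(phi_g, nrow(fit$mu_dg), ncol(fit$mu_dg),
                              byrow = TRUE)
  colSums((n_d * u^2) * m) / su^2
}

#' Variance of the per-gene interaction score (matched design)
#'
#' As [var_v_unmatched()] but with `n_d = n` and the covariance induced
#' by the between-condition correlation of latent expressions:
#' `var(v_g) = {sum_d u_d^2 (1/mu_dg + phi_g) +
#' 2 sum_{d1<d2} u_d1 u_d2 phi_g rho_{d1d2}} / (n (sum_d u_d^2)^2)`.
#' Values driven non-positive by the cross term (possible with noisy
#' correlation estimates) are clamped at `floor` with a warning.
#'
#' @param fit a [fit_rank1()] object from a matched design.
#' @param phi a `dispersion_set`.
#' @param rho a [estimate_rho()] result (or a `D x D` correlation
#'   matrix).
#' @param floor positive lower clamp (default `1e-12`).
#' @return named numeric vector of per-gene variances.
#' @export
var_v_matched <- function(fit, phi, rho, floor = 1e-12) {
  stopifnot(inherits(fit, "rank1_fit"), inherits(phi, "dispersion_set"))
  if (inherits(rho, "rho_estimate")) rho <- rho$rho
  n_d <- fit$n_d
  if (length(unique(n_d)) != 1L) {
    stop("matched variance requires equal samples per condition")
  }
  n <- n_d[1]
  u <- fit$u
  D <- length(u)
  su2 <- sum(u^2)
  if (su2 <= 0) stop("degenerate u: sum(u^2) must be positive")
  phi_g <- phi$phi[colnames(fit$mu_dg)]
  m <- 1 / fit$mu_dg + matrix(phi_g, D, ncol(fit$mu_dg), byrow = TRUE)
  base <- colSums(u^2 * m)
  cross_u <- 0
  for (d1 in seq_len(D - 1)) {
    for (d2 in (d1 + 1):D) cross_u <- cross_u + u[d1] * u[d2] * rho[d1, d2]
  }
  v <- (base + 2 * phi_g * cross_u) / (n * su2^2)
  nonpos <- sum(v < floor)
  if (nonpos > 0) {
    warning(nonpos, " gene(s) with non-positive matched variance; ",
            "clamped at ", floor)
  }
  pmax(v, floor)
}

#' One-degree-of-freedom Wald test of differential expression
#'
#' Tests `H_g: v_g = 0` per gene with `T_g = v_g^2 / var(v_g)`,
#' referred to the chi-squared distribution with one degree of freedom.
#'
#' @param fit a [fit_rank1()] object.
#' @param var_v per-gene variance of `v` (from [var_v_unmatched()] or
#'   [var_v_matched()]).
#' @return data frame with columns `gene`, `v`, `se`, `statistic`, `p`.
#' @export
wald_test <- function(fit, var_v) {
  stopifnot(inherits(fit, "rank1_fit"), all(var_v > 0),
            length(var_v) == length(fit$v))
  T_g <- fit$v^2 / var_v
  data.frame(gene = names(fit$v), v = unname(fit$v),
             se = unname(sqrt(var_v)), statistic = unname(T_g),
             p = stats::pchisq(unname(T_g), df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multiple-testing adjustment of per-gene p-values
#'
#' Benjamini-Hochberg step-up FDR (default), Bonferroni, or none; thin
#' wrapper around [stats::p.adjust()] with input validation.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"BH"`, `"bonferroni"`, or `"none"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}
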