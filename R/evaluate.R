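#' ROC curve and AUC of a DE ranking against simulation truth
#'
#' Genes are ranked by ascending p-value (ties broken by gene order, so
#' curves are deterministic); the standard ROC is traced over the
#' ranking and the AUC computed by the trapezoid rule. The AUC is
#' invariant to any strictly increasing transform of the scores.
#'
#' @param p per-gene p-values (or any score where smaller = more
#'   significant).
#' @param is_de logical vector of true DE status, or a factor/character
#'   `de_label` where `"EE"` marks equally expressed genes.
#' @return list with `points` (data frame `fpr`, `tpr`, starting at
#'   (0, 0)) and `auc`.
#' @export
roc_curve <- function(p, is_de) {
  is_de <- .as_de_logical(is_de)
  stopifnot(length(p) == length(is_de))
  if (!any(is_de) || all(is_de)) {
    stop("truth must contain at least one DE and one EE gene")
  }
  ord <- order(p, seq_along(p))
  lab <- is_de[ord]
  tpr <- c(0, cumsum(lab) / sum(is_de))
  fpr <- c(0, cumsum(!lab) / sum(!is_de))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Empirical FDR among the top-N ranked genes
#'
#' For each `N` in `1..n_max`, the fraction of truly equally expressed
#' genes among the `N` smallest p-values (ties broken by gene order).
#'
#' @param p per-gene p-values.
#' @param is_de true DE status (see [roc_curve()]).
#' @param n_max largest list size (default all genes).
#' @return numeric vector of length `n_max`; element `N` is the
#'   empirical FDR of the top-`N` list.
#' @export
empirical_fdr <- function(p, is_de, n_max = length(p)) {
  is_de <- .as_de_logical(is_de)
  stopifnot(length(p) == length(is_de), n_max <= length(p), n_max >= 1)
  ord <- order(p, seq_along(p))
  fdr <- cumsum(!is_de[ord]) / seq_along(ord)
  fdr[seq_len(n_max)]
}

.as_de_logical <- function(is_de) {
  if (is.logical(is_de)) return(is_de)
  as.character(is_de) != "EE"
}

#' (D-1)-degrees-of-freedom ANOVA-type comparator test
#'
#' A minimal Wald-type chi-squared test of the unreduced per-gene null
#' `H_g: gamma_1g = ... = gamma_Dg = 0`, used as an internal benchmark
#' for the power gain of the one-degree-of-freedom rank-1 test. The
#' statistic sums `gamma_dg^2` over conditions, each standardized by
#' the delta-method variance `n_d^{-1} (1/mu_dg + phi_g)` of the log
#' condition mean, and is referred to chi-squared with `D - 1` degrees
#' of freedom.
#'
#' @param nc a [normalized_counts()] object.
#' @param phi a `dispersion_set`.
#' @return data frame with columns `gene`, `statistic`, `df`, `p`.
#' @export
anova_comparator_test <- function(nc, phi) {
  stopifnot(inherits(nc, "normalized_counts"),
            inherits(phi, "dispersion_set"))
  n_d <- samples_per_condition(nc)
  ee <- estimate_eta(nc)
  me <- moment_effects(ee$eta, n_d)
  phi_g <- phi$phi[rownames(nc$values)]
  D <- length(n_d)
  var_eta <- (1 / ee$mu_dg +
                matrix(phi_g, D, ncol(ee$mu_dg), byrow = TRUE)) / n_d
  T_g <- colSums(me$gamma^2 / var_eta)
  data.frame(gene = rownames(nc$values), statistic = unname(T_g),
             df = D - 1,
             p = stats::pchisq(unname(T_g), df = D - 1, lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}
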