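#' End-to-end differential expression test across multiple conditions
#'
#' Runs the complete pipeline: size factors, normalized counts,
#' dispersion estimation, the rank-1 interaction fit, the
#' between-condition correlation for matched designs, and the
#' one-degree-of-freedom Wald test with multiplicity adjustment.
#'
#' With `two_pass = TRUE` the model is fitted once, the genes with
#' adjusted p-value below `alpha` are taken as the DE set, and `u` is
#' re-estimated restricted to that set (see [refine_u()]) in a second
#' fit; this removes the noise that equally expressed genes contribute
#' to the `u` update.
#'
#' @param cm a [count_matrix()].
#' @param normalization size-factor method (see [size_factors()]),
#'   default `"tmm"`.
#' @param prior_df dispersion shrinkage strength (default 5; 0 for raw
#'   moment estimates).
#' @param phi optional user-supplied per-gene dispersions (named
#'   vector), bypassing estimation.
#' @param matched `NULL` (decide from the presence of subject
#'   annotations), or logical. `matched = FALSE` on subject-annotated
#'   data proceeds unmatched with a warning.
#' @param adjust multiplicity adjustment: `"BH"` (default),
#'   `"bonferroni"`, `"none"`.
#' @param alpha significance level for the DE flag (and the two-pass DE
#'   set), default 0.05.
#' @param two_pass re-estimate `u` on the first-pass DE set.
#' @param trim_fraction TMM trim fraction (default 0.30).
#' @param ... further arguments to [fit_rank1()].
#' @return an object of class `de_result`: list with `table` (data
#'   frame: `gene`, `v`, `se`, `statistic`, `p`, `p_adj`, `de`), `fit`,
#'   `phi`, `rho` (matched designs), `size_factors`, `adjust_method`,
#'   `alpha`, `matched`.
#' @examples
#' sim <- simulate_rank1(sim_config(D = 3, G = 300, n_ee = 240,
#'                                  n_up = 30, n_down = 30), seed = 1)
#' res <- de_test(sim$cm, normalization = "median")
#' head(res$table)
#' @export
de_test <- function(cm, normalization = "tmm", prior_df = 5, phi = NULL,
                    matched = NULL, adjust = c("BH", "bonferroni", "none"),
                    alpha = 0.05, two_pass = FALSE, trim_fraction = 0.30,
                    ...) {
  stopifnot(inherits(cm, "count_matrix"))
  adjust <- match.arg(adjust)
  has_subjects <- !is.null(cm$subject)
  if (is.null(matched)) matched <- has_subjects
  if (matched && !has_subjects) {
    stop("matched analysis requested but the data carry no subject ",
         "annotations")
  }
  if (!matched && has_subjects) {
    warning("subject annotations present but matched = FALSE; ",
            "proceeding with the unmatched analysis")
  }

  sf <- size_factors(cm, method = normalization,
                     trim_fraction = trim_fraction)
  nc <- normalize_counts(cm, sf)
  if (!matched) nc$subject <- NULL
  disp <- estimate_dispersion(nc, prior_df = prior_df, phi = phi)
  fit <- fit_rank1(nc, ...)

  rho <- NULL
  result_of <- function(fit) {
    if (matched) {
      rho <<- estimate_rho(nc, fit, disp)
      var_v <- var_v_matched(fit, disp, rho)
    } else {
      var_v <- var_v_unmatched(fit, disp)
    }
    wald_test(fit, var_v)
  }
  tab <- result_of(fit)

  if (two_pass) {
    de_set <- which(adjust_pvalues(tab$p, "BH") < alpha)
    if (length(de_set) == 0) {
      warning("two-pass requested but no genes pass BH < ", alpha,
              " in the first pass; keeping the single-pass fit")
    } else {
      fit <- fit_rank1(nc, de_set = de_set, ...)
      tab <- result_of(fit)
    }
  }

  tab$p_adj <- adjust_pvalues(tab$p, adjust)
  tab$de <- tab$p_adj < alpha
  structure(list(table = tab, fit = fit, phi = disp, rho = rho,
                 size_factors = sf, adjust_method = adjust, alpha = alpha,
                 matched = matched),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d genes, %d conditions (%s design)\n",
              nrow(x$table), length(x$fit$u),
              if (x$matched) "matched" else "unmatched"))
  cat(sprintf("  %d DE genes at %s-adjusted p < %g\n",
              sum(x$table$de), x$adjust_method, x$alpha))
  cat("  u:", paste(sprintf("%s=%.3f", x$fit$conditions, x$fit$u),
                    collapse = ", "), "\n")
  invisible(x)
}
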