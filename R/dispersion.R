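#' Moment estimator of the per-gene NB dispersion
#'
#' Under the negative-binomial model `Var(Y) = mu + phi * mu^2`, so
#' within each condition `phi = (s^2 - ybar) / ybar^2`. The estimate is
#' pooled across conditions with precision weights `n_d - 1` (conditions
#' whose sample mean is zero contribute nothing) and clamped below at
#' `floor`.
#'
#' With `bias_correction = TRUE` the denominator `ybar^2` is replaced by
#' the unbiased estimate of `mu^2`, `ybar^2 - s^2/n` (falling back to
#' `ybar^2` where that is non-positive). Because
#' `E(ybar^2) = mu^2 + Var(Y)/n`, the uncorrected ratio systematically
#' underestimates `phi` at small `n`; the correction removes most of
#' that bias and is what the testing pipeline uses, since the plug-in
#' Wald variances are only calibrated with an (approximately) unbiased
#' dispersion.
#'
#' @param nc a [normalized_counts()] object; each condition must have at
#'   least two samples.
#' @param floor lower clamp for the dispersion (default `1e-8`),
#'   numerically negligible but keeps downstream variance formulas
#'   finite.
#' @param bias_correction use the unbiased `mu^2` denominator (default
#'   `FALSE`: the plain moment ratio).
#' @return an object of class `dispersion_set`: list with `phi` (named
#'   non-negative numeric per gene), `method`, `prior_df`, `floor`.
#' @export
moment_dispersion <- function(nc, floor = 1e-8, bias_correction = FALSE) {
  stopifnot(inherits(nc, "normalized_counts"), floor > 0)
  y <- nc$values
  cond <- nc$condition
  G <- nrow(y)
  num <- den <- numeric(G)
  for (lev in levels(cond)) {
    sub <- y[, cond == lev, drop = FALSE]
    n <- ncol(sub)
    ybar <- rowMeans(sub)
    s2 <- rowSums((sub - ybar)^2) / (n - 1)
    msq <- ybar^2
    if (bias_correction) {
      corrected <- msq - s2 / n
      msq <- ifelse(corrected > 0, corrected, msq)
    }
    use <- ybar > 0
    w <- n - 1
    num[use] <- num[use] + w * ((s2[use] - ybar[use]) / msq[use])
    den[use] <- den[use] + w
  }
  if (any(den == 0)) {
    stop("gene(s) with zero mean in every condition (dispersion undefined): ",
         paste(utils::head(rownames(y)[den == 0], 5), collapse = ", "),
         "; apply filter_genes() first")
  }
  phi <- pmax(num / den, floor)
  names(phi) <- rownames(y)
  structure(list(phi = phi, method = "moments", prior_df = 0, floor = floor),
            class = "dispersion_set")
}

#' Shrink per-gene dispersions toward a common value
#'
#' Empirical-Bayes-style stabilization for small designs: each
#' dispersion is pulled, on the arithmetic scale, toward the mean of
#' all dispersions with weight `prior_df / (prior_df + df_resid)`,
#' where `df_resid = sum(n_d - 1)` is the residual degrees of freedom
#' of the design. `prior_df = 0` returns the input unchanged;
#' `prior_df = Inf` sets every gene to the common value.
#'
#' Shrinkage is linear rather than geometric (log-scale) on purpose:
#' averaging noisy log-dispersions is systematically downward-biased
#' (Jensen), which propagates into anti-conservative Wald variances.
#'
#' @param raw a `dispersion_set` (typically from [moment_dispersion()]).
#' @param nc the [normalized_counts()] the dispersions were estimated
#'   from (provides the design's residual degrees of freedom).
#' @param prior_df non-negative shrinkage strength (default 5).
#' @return a `dispersion_set` with `method = "shrunk"`.
#' @export
shrink_dispersion <- function(raw, nc, prior_df = 5) {
  stopifnot(inherits(raw, "dispersion_set"),
            inherits(nc, "normalized_counts"), prior_df >= 0)
  if (prior_df == 0) return(raw)
  common <- mean(raw$phi)
  df_resid <- sum(samples_per_condition(nc) - 1L)
  w <- if (is.infinite(prior_df)) 1 else prior_df / (prior_df + df_resid)
  phi <- pmax((1 - w) * raw$phi + w * common, raw$floor)
  structure(list(phi = phi, method = "shrunk", prior_df = prior_df,
                 floor = raw$floor),
            class = "dispersion_set")
}

#' Estimate (or accept) per-gene dispersions
#'
#' The estimation route used by [de_test()]: bias-corrected moment
#' estimation (see [moment_dispersion()]) followed by arithmetic
#' shrinkage (see [shrink_dispersion()]). Alternatively a pass-through
#' for dispersions computed elsewhere (e.g. by an external
#' empirical-Bayes estimator), supplied as a named vector.
#'
#' @param nc a [normalized_counts()] object.
#' @param prior_df shrinkage strength (default 5; 0 disables
#'   shrinkage).
#' @param phi optional user-supplied per-gene dispersions (named by
#'   gene, covering every gene in `nc`); bypasses estimation.
#' @param floor lower clamp for the dispersion.
#' @param bias_correction use the unbiased `mu^2` denominator in the
#'   moment step (default `TRUE`).
#' @return a `dispersion_set`.
#' @export
estimate_dispersion <- function(nc, prior_df = 5, phi = NULL, floor = 1e-8,
                                bias_correction = TRUE) {
  stopifnot(inherits(nc, "normalized_counts"))
  if (!is.null(phi)) {
    genes <- rownames(nc$values)
    if (is.null(names(phi))) {
      if (length(phi) != length(genes)) {
        stop("unnamed 'phi' must have one value per gene")
      }
      names(phi) <- genes
    }
    missing <- setdiff(genes, names(phi))
    if (length(missing)) {
      stop("supplied dispersions missing for gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    phi <- pmax(phi[genes], floor)
    return(structure(list(phi = phi, method = "supplied", prior_df = 0,
                          floor = floor),
                     class = "dispersion_set"))
  }
  raw <- moment_dispersion(nc, floor = floor,
                           bias_correction = bias_correction)
  shrink_dispersion(raw, nc, prior_df = prior_df)
}

#' @export
print.dispersion_set <- function(x, ...) {
  cat(sprintf("dispersion_set (%s%s): %d genes, median phi = %.4g\n",
              x$method,
              if (x$method == "shrunk") paste0(", prior_df = ", x$prior_df)
              else "",
              length(x$phi), stats::median(x$phi)))
  invisible(x)
}
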