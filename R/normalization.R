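#' Between-lane size factors
#'
#' Computes a per-sample library size factor `delta_id` by one of four
#' between-lane normalization methods:
#'
#' * `median` — sample median count divided by the geometric mean of all
#'   samples' medians (geometric mean of the factors is 1);
#' * `total` — sample total count divided by the arithmetic mean of all
#'   totals (arithmetic mean of the factors is 1);
#' * `quantile` — sample 75th percentile divided by the arithmetic mean
#'   of all 75th percentiles (linear-interpolation quantile, R type 7);
#' * `tmm` — weighted trimmed mean of M-values against a reference
#'   sample: gene-wise log2 relative expression `M =
#'   log2((x/N)/(x_ref/N_ref))` with genes of zero count in either
#'   sample dropped, the upper and lower `trim_fraction` of M-values
#'   removed, and the remainder averaged with precision weights
#'   (inverse of the binomial delta-method variance
#'   `(N-x)/(Nx) + (N_ref-x_ref)/(N_ref x_ref)`). The factor is
#'   `2^(weighted mean)`, and all TMM factors are rescaled to geometric
#'   mean 1. The reference defaults to the sample whose upper quartile
#'   of scaled counts is closest to the mean upper quartile.
#'
#' @param cm a [count_matrix()].
#' @param method one of `"median"`, `"total"`, `"quantile"`, `"tmm"`.
#' @param trim_fraction fraction of M-values trimmed from each tail
#'   (TMM only, default 0.30).
#' @param reference sample identifier used as TMM reference, or `NULL`
#'   for automatic selection.
#' @param min_genes minimum number of usable genes after trimming (TMM
#'   only, default 10).
#' @return an object of class `size_factors`: list with `delta` (named
#'   positive numeric, one per sample), `method`, and `reference`
#'   (TMM only).
#' @export
size_factors <- function(cm, method = c("median", "total", "quantile", "tmm"),
                         trim_fraction = 0.30, reference = NULL,
                         min_genes = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  x <- cm$counts
  delta <- switch(method,
    median = {
      m <- apply(x, 2, stats::median)
      if (any(m == 0)) {
        stop("sample(s) with zero median count: ",
             paste(colnames(x)[m == 0], collapse = ", "),
             "; filter low-count genes first")
      }
      m / exp(mean(log(m)))
    },
    total = {
      s <- colSums(x)
      if (any(s == 0)) stop("sample(s) with zero total count")
      s / mean(s)
    },
    quantile = {
      q <- apply(x, 2, stats::quantile, probs = 0.75, names = FALSE)
      if (any(q == 0)) {
        stop("sample(s) with zero 75th percentile; filter low-count genes first")
      }
      q / mean(q)
    },
    tmm = .tmm_factors(x, trim_fraction, reference, min_genes)
  )
  reference <- attr(delta, "reference")
  attributes(delta) <- NULL
  names(delta) <- colnames(x)
  structure(list(delta = delta, method = method, reference = reference),
            class = "size_factors")
}

.tmm_factors <- function(x, trim_fraction, reference, min_genes) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("'trim_fraction' must be in [0, 0.5)")
  }
  N <- colSums(x)
  if (is.null(reference)) {
    ## edgeR convention: upper quartile of depth-scaled counts closest
    ## to the mean upper quartile
    f75 <- vapply(seq_len(ncol(x)),
                  function(j) stats::quantile(x[, j] / N[j], probs = 0.75,
                                              names = FALSE),
                  numeric(1))
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(reference, colnames(x))
    if (is.na(ref)) stop("reference sample '", reference, "' not found")
  }
  xr <- x[, ref]
  Nr <- N[ref]
  delta <- vapply(seq_len(ncol(x)), function(j) {
    .tmm_pair(x[, j], xr, N[j], Nr, trim_fraction, min_genes)
  }, numeric(1))
  delta <- delta / exp(mean(log(delta)))
  attr(delta, "reference") <- colnames(x)[ref]
  delta
}

## one sample against the reference: trimmed, precision-weighted mean of
## M-values, exponentiated back from log2 scale
.tmm_pair <- function(xs, xr, Ns, Nr, trim_fraction, min_genes) {
  ok <- xs > 0 & xr > 0
  xs <- xs[ok]; xr <- xr[ok]
  M <- log2((xs / Ns) / (xr / Nr))
  v <- (Ns - xs) / (Ns * xs) + (Nr - xr) / (Nr * xr)
  n <- length(M)
  lo <- floor(n * trim_fraction)
  if (n - 2 * lo < min_genes) {
    stop("fewer than ", min_genes, " usable genes after TMM trimming")
  }
  keep <- order(M)[(lo + 1):(n - lo)]
  w <- 1 / v[keep]
  2^(sum(w * M[keep]) / sum(w))
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("size_factors (%s%s):\n", x$method,
              if (!is.null(x$reference)) paste0(", reference = ", x$reference)
              else ""))
  print(round(x$delta, 4))
  invisible(x)
}

#' Normalized counts Y = [X / delta]
#'
#' Divides each sample's raw counts by its size factor and rounds to the
#' nearest integer (round-half-to-even, R's `round()`), producing the
#' normalized counts `Y_idg` that the negative-binomial model describes.
#'
#' @param cm a [count_matrix()].
#' @param sf a `size_factors` object, or a method name passed to
#'   [size_factors()] (default `"tmm"`).
#' @param ... further arguments to [size_factors()] when `sf` is a
#'   method name.
#' @return an object of class `normalized_counts`: list with `values`
#'   (integer matrix, genes x samples), `condition`, `subject`,
#'   `size_factors`.
#' @export
normalize_counts <- function(cm, sf = "tmm", ...) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.character(sf)) sf <- size_factors(cm, method = sf, ...)
  stopifnot(inherits(sf, "size_factors"))
  if (!identical(names(sf$delta), colnames(cm$counts))) {
    stop("size factors do not match the samples of 'cm'")
  }
  y <- round(sweep(cm$counts, 2, sf$delta, "/"))
  normalized_counts(y, cm$condition, cm$subject, sf)
}

#' Construct a normalized-counts object directly
#'
#' For users who normalized counts elsewhere. `values` must be
#' non-negative integers on the scale the model describes.
#'
#' @param values non-negative integer matrix, genes x samples.
#' @param condition condition label per sample (see [count_matrix()]).
#' @param subject optional subject label per sample (matched design).
#' @param size_factors optional `size_factors` object used to produce
#'   `values`.
#' @return an object of class `normalized_counts`.
#' @export
normalized_counts <- function(values, condition, subject = NULL,
                              size_factors = NULL) {
  cm <- count_matrix(values, condition, subject)  # reuse validation
  structure(list(values = cm$counts, condition = cm$condition,
                 subject = cm$subject, size_factors = size_factors),
            class = "normalized_counts")
}

#' @export
print.normalized_counts <- function(x, ...) {
  cat(sprintf("normalized_counts: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$size_factors)) "user-supplied"
              else x$size_factors$method))
  invisible(x)
}
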