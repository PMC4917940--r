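#' Construct a gene-by-sample count matrix with design annotations
#'
#' The basic data container of the package: a matrix of non-negative
#' integer read counts (genes in rows, samples in columns) together with
#' the mapping of each sample to a treatment condition and, for matched
#' (repeated-measures) designs, to a subject.
#'
#' Every condition must contain at least two biological replicates. In a
#' matched design every subject must contribute exactly one sample to
#' every condition, so all conditions share the same number of samples.
#'
#' @param counts numeric matrix (or data frame) of non-negative integer
#'   read counts, genes in rows, samples in columns. Row and column
#'   names are used as gene and sample identifiers (generated if absent).
#' @param condition vector of condition labels, one per sample. Arbitrary
#'   labels are allowed; they are mapped to conditions `1..D` in order of
#'   first appearance.
#' @param subject optional vector of subject labels, one per sample;
#'   supplying it declares a matched design.
#' @return an object of class `count_matrix`: a list with elements
#'   `counts`, `condition` (factor), `subject` (factor or `NULL`).
#' @seealso [read_counts()], [filter_genes()], [size_factors()]
#' @export
count_matrix <- function(counts, condition, subject = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix (genes x samples)")
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts contain missing or non-finite entries")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers (raw read counts)")
  }
  counts <- round(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample identifiers must be unique")

  if (length(condition) != ncol(counts)) {
    stop("'condition' must give one label per sample")
  }
  ## a single condition is allowed in the container (normalization and
  ## dispersion work per sample/condition); DE fitting requires D >= 2
  condition <- .as_ordered_factor(condition)
  n_d <- table(condition)
  if (any(n_d < 2)) {
    stop("each condition needs at least two biological replicates; offending: ",
         paste(names(n_d)[n_d < 2], collapse = ", "))
  }

  if (!is.null(subject)) {
    if (length(subject) != ncol(counts)) {
      stop("'subject' must give one label per sample")
    }
    if (anyNA(subject)) stop("'subject' contains missing labels")
    subject <- .as_ordered_factor(subject)
    grid <- table(subject, condition)
    if (any(grid != 1L)) {
      stop("matched design requires every subject to appear exactly once ",
           "in every condition")
    }
  }

  structure(
    list(counts = counts, condition = condition, subject = subject),
    class = "count_matrix"
  )
}

## factor with levels in order of first appearance (deterministic mapping
## of arbitrary labels to condition indices 1..D)
.as_ordered_factor <- function(x) {
  x <- as.character(x)
  factor(x, levels = unique(x))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, %d conditions (%s design)\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$condition),
              if (is.null(x$subject)) "unmatched" else "matched"))
  n_d <- table(x$condition)
  cat("  samples per condition:",
      paste(sprintf("%s=%d", names(n_d), n_d), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Samples per condition
#'
#' @param x a `count_matrix` or `normalized_counts` object.
#' @return named integer vector `n_d`, in condition order.
#' @export
samples_per_condition <- function(x) {
  tab <- table(x$condition)
  structure(as.integer(tab), names = names(tab))
}

#' Read a count matrix and its sample metadata from delimited text
#'
#' The counts file must have a header row of sample identifiers and a
#' leading gene-identifier column. The metadata table must contain
#' columns `sample_id` and `condition`, and optionally `subject` (whose
#' presence declares a matched design). Sample order is taken from the
#' counts file.
#'
#' @param path path to the counts file (tab-delimited by default; comma
#'   if the extension is `.csv` or `sep = ","` is given).
#' @param metadata a data frame, or path to a delimited file, with
#'   columns `sample_id`, `condition`, optional `subject`.
#' @param sep field separator for `path`; inferred from the extension if
#'   `NULL`.
#' @return a validated [count_matrix()].
#' @export
read_counts <- function(path, metadata, sep = NULL) {
  if (is.null(sep)) sep <- .infer_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("counts file contains non-numeric entries")
  if (anyNA(m)) stop("counts file contains missing entries")
  if (any(m < 0)) stop("counts file contains negative entries")
  if (any(abs(m - round(m)) > 1e-8)) {
    stop("counts file contains non-integer entries")
  }

  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- utils::read.table(metadata, header = TRUE,
                                  sep = .infer_sep(metadata),
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "condition") %in% names(metadata))) {
    stop("metadata must have columns 'sample_id' and 'condition'")
  }
  missing <- setdiff(colnames(m), as.character(metadata$sample_id))
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  }
  md <- metadata[match(colnames(m), as.character(metadata$sample_id)), ]
  subject <- NULL
  if ("subject" %in% names(md) && !all(is.na(md$subject))) {
    subject <- md$subject
  }
  count_matrix(m, md$condition, subject)
}

.infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Write a count matrix (and metadata) to delimited text
#'
#' Inverse of [read_counts()]: writing then reading reproduces the
#' counts and annotations exactly.
#'
#' @param cm a `count_matrix`.
#' @param path output path for the counts table.
#' @param metadata_path optional output path for the sample metadata
#'   table (`sample_id`, `condition`, `subject` when matched).
#' @param sep field separator (default tab).
#' @return invisibly, `cm`.
#' @export
write_counts <- function(cm, path, metadata_path = NULL, sep = "\t") {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    md <- data.frame(sample_id = colnames(cm$counts),
                     condition = as.character(cm$condition),
                     stringsAsFactors = FALSE)
    if (!is.null(cm$subject)) md$subject <- as.character(cm$subject)
    utils::write.table(md, metadata_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(cm)
}

#' Filter genes on per-condition maximum count
#'
#' Keeps exactly the genes whose maximum raw count is strictly greater
#' than `min_max_count` in *every* condition — the standard expression
#' filter applied before model fitting, which also guarantees the
#' positive condition means required by the log-linear fit.
#'
#' @param cm a `count_matrix`.
#' @param min_max_count non-negative integer threshold (default 50).
#' @return the filtered `count_matrix` (annotations preserved).
#' @export
filter_genes <- function(cm, min_max_count = 50) {
  stopifnot(inherits(cm, "count_matrix"), min_max_count >= 0)
  keep <- rep(TRUE, nrow(cm$counts))
  for (lev in levels(cm$condition)) {
    sub <- cm$counts[, cm$condition == lev, drop = FALSE]
    keep <- keep & (apply(sub, 1, max) > min_max_count)
  }
  if (!any(keep)) {
    stop("no genes pass the expression filter (min_max_count = ",
         min_max_count, ")")
  }
  count_matrix(cm$counts[keep, , drop = FALSE], cm$condition, cm$subject)
}
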