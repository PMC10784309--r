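#' Construct a validated expression matrix
#'
#' The expression matrix is the single substrate of the pipeline: a numeric
#' genes-by-samples matrix with unique gene symbols as row names, sample IDs
#' as column names and an explicit scale tag, either `"tpm"`
#' (transcripts-per-million, non-negative) or `"log2p1"` (`log2(TPM + 1)`).
#' All downstream functions check the tag so that rank-based scoring and
#' clustering always run on the intended scale.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param scale Either `"tpm"` or `"log2p1"`.
#' @return The matrix with an `expr_scale` attribute set.
#' @export
expr_matrix <- function(values, scale = c("tpm", "log2p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene symbols as rownames and sample IDs as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    abort(paste0("duplicate gene symbol after collapse: '", dup, "'."))
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample IDs in expression matrix.")
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(paste0(
      "missing value in expression matrix at gene '", rownames(values)[idx[1]],
      "', sample '", colnames(values)[idx[2]], "'."
    ))
  }
  if (scale == "tpm" && any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(paste0(
      "negative TPM at gene '", rownames(values)[idx[1]],
      "', sample '", colnames(values)[idx[2]], "'."
    ))
  }
  attr(values, "expr_scale") <- scale
  values
}

#' Scale tag of an expression matrix
#'
#' @param m An expression matrix created by [expr_matrix()], [read_expression()]
#'   or [log_transform()].
#' @return `"tpm"` or `"log2p1"`.
#' @export
expr_scale <- function(m) {
  sc <- attr(m, "expr_scale")
  if (is.null(sc)) abort("matrix carries no `expr_scale` attribute; build it with expr_matrix().")
  sc
}

check_scale <- function(m, expected, what) {
  if (!identical(expr_scale(m), expected)) {
    abort(paste0(what, " requires a ", expected, " matrix, got ", expr_scale(m), "."))
  }
  invisible(m)
}

#' Read a gene-by-sample expression table
#'
#' Reads a TSV or CSV file (by extension) with gene symbols in the first
#' column and sample IDs in the header. Duplicate gene rows are collapsed:
#' `"max_mean"` keeps the row with the highest mean expression (deterministic,
#' ties broken by file order), `"first"` keeps the first occurrence.
#'
#' @param path File path; `.csv` is read as comma-separated, anything else as
#'   tab-separated.
#' @param collapse Duplicate-gene policy, `"max_mean"` (default) or `"first"`.
#' @param scale Scale tag to stamp on the result (files are expected to hold
#'   TPM values; pass `"log2p1"` only for already-transformed tables).
#' @return A validated expression matrix (see [expr_matrix()]).
#' @export
read_expression <- function(path, collapse = c("max_mean", "first"),
                            scale = c("tpm", "log2p1")) {
  collapse <- match.arg(collapse)
  scale <- match.arg(scale)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(tbl) < 2) abort("expression file needs a gene column plus >= 1 sample column.")
  genes <- as.character(tbl[[1]])
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  colnames(vals) <- names(tbl)[-1]
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(paste0("missing value at gene '", genes[idx[1]], "', sample '",
                 colnames(vals)[idx[2]], "' in ", path, "."))
  }
  if (anyDuplicated(genes)) {
    keep <- switch(collapse,
      first = !duplicated(genes),
      max_mean = {
        mu <- rowMeans(vals)
        # highest-mean row per symbol; ties keep the earlier row
        ord <- order(genes, -mu, seq_along(genes))
        first_of_run <- !duplicated(genes[ord])
        sel <- logical(length(genes))
        sel[ord[first_of_run]] <- TRUE
        sel
      }
    )
    n_drop <- sum(!keep)
    inform(paste0("collapsed ", n_drop, " duplicate gene row(s) with policy '",
                  collapse, "'."))
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(vals) <- genes
  expr_matrix(vals, scale = scale)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: genes as rows, a `gene` first column and
#' one column per sample. Round-trips unchanged for valid matrices.
#'
#' @param m Expression matrix.
#' @param path Output path; `.csv` writes comma-separated, else tab-separated.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  expr_scale(m) # validates tag presence
  tbl <- tibble::as_tibble(m, rownames = "gene")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(tbl, path)
  } else {
    readr::write_tsv(tbl, path)
  }
  invisible(path)
}

#' Log-transform a TPM matrix
#'
#' Applies `log2(TPM + 1)`, the working scale for clustering, scoring and
#' classifier construction. Refuses to run twice: re-applying to a `log2p1`
#' matrix is an error rather than a silent double transform.
#'
#' @param m TPM expression matrix.
#' @return Expression matrix on the `log2p1` scale.
#' @export
log_transform <- function(m) {
  check_scale(m, "tpm", "log_transform()")
  out <- log2(m + 1)
  attr(out, "expr_scale") <- NULL
  expr_matrix(out, scale = "log2p1")
}

# subset an expression matrix while keeping the scale tag
expr_subset <- function(m, genes = NULL, samples = NULL) {
  sc <- expr_scale(m)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  attr(m, "expr_scale") <- sc
  m
}
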