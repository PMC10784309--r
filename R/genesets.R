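#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name<TAB>description<TAB>`
#' followed by gene symbols. Within-set duplicates are removed keeping the
#' first occurrence; empty sets and malformed lines are rejected with the
#' offending line number.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (one element per set), with a
#'   `description` attribute (named character) and, when descriptions are
#'   `"up"`/`"down"`, a `direction` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("no gene sets in ", path, "."))
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      abort(paste0("malformed GMT line ", i, " in ", path,
                   ": need name, description and >= 1 gene."))
    }
    nm <- fields[1]
    genes <- unique(fields[-(1:2)])
    if (nm %in% names(sets)) abort(paste0("duplicate set name '", nm, "' at line ", i, "."))
    sets[[nm]] <- genes
    descs[nm] <- fields[2]
  }
  attr(sets, "description") <- descs
  if (all(descs %in% c("up", "down"))) attr(sets, "direction") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors. An optional `direction`
#'   attribute (or `description` attribute) supplies the second GMT field;
#'   otherwise `"na"` is written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every gene set must be named.")
  }
  desc <- attr(sets, "direction") %||% attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    if (length(genes) == 0) abort(paste0("gene set '", nm, "' is empty."))
    paste(c(nm, desc[[nm]] %||% "na", genes), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# intersect a gene set with the matrix universe, with a logged drop count
match_set <- function(set, genes, set_name, min_genes = 1L) {
  present <- set[set %in% genes]
  if (length(present) < min_genes) {
    missing <- setdiff(set, genes)
    abort(paste0(
      "gene set '", set_name, "' has ", length(present),
      " gene(s) in the matrix (minimum ", min_genes, "); missing: ",
      paste(head(missing, 10), collapse = ", "),
      if (length(missing) > 10) ", ..." else "", "."
    ))
  }
  if (length(present) < length(set)) {
    inform(paste0("set '", set_name, "': ", length(set) - length(present),
                  " gene(s) not in matrix, ", length(present), " used."))
  }
  present
}
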