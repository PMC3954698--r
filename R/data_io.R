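#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated table whose first column holds gene identifiers and
#' whose header row holds sample identifiers, and validates it as an
#' expression table of the stated kind.  Row (gene) and column (sample)
#' order are preserved exactly as found in the file.
#'
#' @param path Path to a TSV file.
#' @param value_kind One of `"tag_count"` (integer SAGE tag counts),
#'   `"tpm"` (tags per million) or `"intensity"` (continuous microarray
#'   signal).  Tag counts must be non-negative integers; the other kinds
#'   must be non-negative reals.
#' @return A numeric matrix (genes x samples) with `rownames` = gene ids,
#'   `colnames` = sample ids and a `value_kind` attribute.
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path,
                                  value_kind = c("intensity", "tag_count", "tpm")) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expression table must have a gene-id column and >= 1 sample column")
  }
  gene_ids <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  validate_expression_table(values, value_kind)
}

#' Validate an expression matrix
#'
#' Checks the invariants shared by all expression tables: unique gene and
#' sample identifiers, no missing values, all values non-negative, and
#' integer values when `value_kind = "tag_count"`.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param value_kind See [read_expression_table()].
#' @return The validated matrix, with the `value_kind` attribute set.
#' @export
validate_expression_table <- function(values,
                                      value_kind = c("intensity", "tag_count", "tpm")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(values)) stop("missing values are not permitted in expression tables")
  if (any(values < 0)) stop("negative expression value found")
  if (value_kind == "tag_count" && any(values != round(values))) {
    stop("non-integer value in a tag-count table")
  }
  attr(values, "value_kind") <- value_kind
  values
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_table()]: integer counts are written exactly,
#' reals with 6 significant digits.
#'
#' @param values Expression matrix (genes x samples, dimnames required).
#' @param path Output file path.
#' @param gene_col Name for the gene-id column (first column) in the header.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(values, path, gene_col = "gene_id") {
  kind <- attr(values, "value_kind")
  fmt <- if (identical(kind, "tag_count")) {
    format(values, trim = TRUE, scientific = FALSE)
  } else {
    formatC(values, digits = 6, format = "g")
  }
  df <- data.frame(rownames(values), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(gene_col, colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT-style gene-set collection
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`.  Duplicate
#' members within a set are dropped with a warning; duplicate set names are
#' an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member gene ids, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("gene-set line %d has fewer than 3 tab-separated fields", i))
    }
    nms[i] <- f[1L]
    descs[i] <- f[2L]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate members dropped", f[1L]))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("gene set '%s' is empty", f[1L]))
    sets[[i]] <- members
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  names(descs) <- nms
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors; optional `descriptions`
#'   attribute as produced by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  if (is.null(descs)) descs <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CLS-like phenotype label file
#'
#' Format: line 1 `n_samples n_classes 1`; line 2 `# class1 class2 ...`;
#' line 3 space-separated per-sample labels (class names or 0-based indices
#' into line 2).
#'
#' @param path Path to the label file.
#' @return A factor of per-sample labels, in file order, with levels in
#'   the declared class order.
#' @export
read_phenotype_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("phenotype file must have 3 lines")
  hdr <- as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]])
  n_samples <- hdr[1L]
  classes <- strsplit(trimws(sub("^#\\s*", "", lines[[2L]])), "\\s+")[[1L]]
  labels <- strsplit(trimws(lines[[3L]]), "\\s+")[[1L]]
  if (length(labels) != n_samples) {
    stop(sprintf("header declares %d samples but %d labels follow",
                 n_samples, length(labels)))
  }
  if (all(grepl("^[0-9]+$", labels))) {
    labels <- classes[as.integer(labels) + 1L]
  }
  if (!all(labels %in% classes)) {
    stop("label not among declared classes: ",
         paste(setdiff(labels, classes), collapse = ", "))
  }
  factor(labels, levels = classes)
}

#' Write phenotype labels in the CLS-like format
#'
#' @param labels Factor (or character) of per-sample labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_labels <- function(labels, path) {
  labels <- as.factor(labels)
  writeLines(c(
    paste(length(labels), nlevels(labels), 1),
    paste("#", paste(levels(labels), collapse = " ")),
    paste(as.character(labels), collapse = " ")
  ), path)
  invisible(path)
}

#' Require at least two phenotype classes
#'
#' Contract check used by every two-class consumer of phenotype labels.
#' @param labels Factor of labels.
#' @return `labels` invisibly; errors when fewer than 2 classes are present.
#' @export
require_two_classes <- function(labels) {
  if (length(unique(as.character(labels))) < 2L) {
    stop("at least 2 distinct phenotype classes are required")
  }
  invisible(labels)
}
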