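#' Validate a log2 expression matrix
#'
#' An expression matrix is an ordinary numeric matrix of log2 expression
#' values with unique, non-empty gene identifiers as row names and unique,
#' non-empty sample identifiers as column names.  All values must be finite:
#' missing values are not permitted once a matrix has been loaded.
#'
#' @param x numeric matrix with gene row names and sample column names.
#' @param allow_duplicate_genes allow duplicated row (gene/probe) names.
#'   Only sensible for probe-level matrices that will immediately be passed
#'   through [collapse_probes()].
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x, allow_duplicate_genes = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  gid <- rownames(x)
  sid <- colnames(x)
  if (is.null(gid) || any(!nzchar(gid))) {
    stop("expression matrix must have non-empty gene row names", call. = FALSE)
  }
  if (is.null(sid) || any(!nzchar(sid))) {
    stop("expression matrix must have non-empty sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (!allow_duplicate_genes && anyDuplicated(gid)) {
    stop("duplicate gene ids: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "),
         "; collapse probes to genes first", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  invisible(x)
}

#' Read a tab-delimited expression table
#'
#' Reads a plain-text expression table in the level-3-like layout: a header
#' row of sample identifiers, one row per gene (or probe), the first column
#' holding the gene/probe identifier and all remaining columns numeric.
#'
#' @param path path to the file.
#' @param has_header logical; whether the first line holds sample ids.  When
#'   `FALSE`, samples are named `S1`, `S2`, ...
#' @param delimiter field delimiter, tab by default.
#' @param allow_duplicate_genes passed to [validate_expression_matrix()];
#'   set `TRUE` for probe-level tables that will be collapsed.
#' @return a validated expression matrix (genes x samples).
#' @seealso [write_expression_table()], [collapse_probes()]
#' @export
read_expression_table <- function(path, has_header = TRUE, delimiter = "\t",
                                  allow_duplicate_genes = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = has_header, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs an id column plus at least one sample column",
                         call. = FALSE)
  ids <- df[[1]]
  # take the header before subsetting: [.data.frame would dedup names
  sid <- if (has_header) colnames(df)[-1] else paste0("S", seq_len(ncol(df) - 1L))
  val <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(val, as.numeric, numeric(nrow(val))))
  if (nrow(val) == 1L) num <- matrix(num, nrow = 1L)
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 val[bad[1], bad[2]], ids[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, sid)
  validate_expression_matrix(num, allow_duplicate_genes = allow_duplicate_genes)
  num
}

#' Write an expression matrix as a tab-delimited table
#'
#' Inverse of [read_expression_table()]: UTF-8, tab-delimited, header row of
#' sample ids, first column `gene_id`.  Values are written at full double
#' precision so that a written matrix re-reads exactly.
#'
#' @param x expression matrix.
#' @param path output path.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, delimiter = "\t") {
  validate_expression_matrix(x, allow_duplicate_genes = TRUE)
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Where multiple probes represent one gene, the gene's expression is the
#' unweighted arithmetic mean of its probe rows (means of log2 values).
#' Probes absent from the map are dropped with a message reporting the count.
#' Output genes are ordered lexicographically.
#'
#' @param x probe-level expression matrix (probe ids as row names; duplicates
#'   permitted).
#' @param probe_map data frame with columns `probe_id` and `gene_id`, mapping
#'   each probe to exactly one gene (many probes per gene allowed).
#' @return gene-level expression matrix.
#' @export
collapse_probes <- function(x, probe_map) {
  validate_expression_matrix(x, allow_duplicate_genes = TRUE)
  if (!is.data.frame(probe_map) ||
      !all(c("probe_id", "gene_id") %in% names(probe_map))) {
    stop("probe_map must be a data frame with columns probe_id and gene_id",
         call. = FALSE)
  }
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probe_map maps some probe to more than one gene", call. = FALSE)
  }
  gene_of <- stats::setNames(as.character(probe_map$gene_id),
                             as.character(probe_map$probe_id))
  probes <- rownames(x)
  mapped <- probes %in% names(gene_of)
  if (!any(mapped)) stop("no probe in the matrix is present in the probe map",
                         call. = FALSE)
  if (any(!mapped)) {
    message(sum(!mapped), " unmapped probe(s) dropped")
  }
  xm <- x[mapped, , drop = FALSE]
  genes <- gene_of[rownames(xm)]
  sums <- rowsum(xm, group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out)), , drop = FALSE]
  validate_expression_matrix(out)
  out
}

#' Intersect gene universes across datasets
#'
#' Signature comparisons are restricted to genes measured in every dataset
#' involved; this intersection is the background (sampling frame) of the
#' two-sided Fisher exact test.  The result is sorted so that it is
#' deterministic and independent of input order.
#'
#' @param ... two or more character vectors of gene ids, or a single list of
#'   them.
#' @param quiet suppress the message reporting the harmonized size.
#' @return sorted character vector, the intersection of all inputs.
#' @export
harmonize_universe <- function(..., quiet = FALSE) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2L) stop("need at least two gene universes", call. = FALSE)
  if (any(vapply(sets, length, 1L) == 0L)) {
    stop("empty gene universe supplied", call. = FALSE)
  }
  bg <- Reduce(intersect, lapply(sets, unique))
  if (length(bg) == 0L) stop("gene universes have an empty intersection",
                             call. = FALSE)
  bg <- sort(bg)
  if (!quiet) message("harmonized universe: ", length(bg), " genes")
  bg
}

#' Read / write sample manifests
#'
#' A manifest is a two-column tab-delimited table (`sample_id`, `group`)
#' assigning each sample to a group: normal, GBM, a subtype name, or a
#' sorted-pair label.
#'
#' @param path file path.
#' @return named character vector of group labels, named by sample id.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("manifest needs columns sample_id and group", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in manifest",
                                        call. = FALSE)
  stats::setNames(df$group, df$sample_id)
}

#' @rdname read_sample_manifest
#' @param groups named character vector (names = sample ids, values = group
#'   labels).
#' @export
write_sample_manifest <- function(groups, path) {
  df <- data.frame(sample_id = names(groups), group = unname(groups),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
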