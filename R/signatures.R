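#' Construct a gene signature
#'
#' A gene signature is a named pair of disjoint up- and down-regulated gene
#' sets together with the universe of genes it was derived from and the
#' log2 fold-change threshold used.  The pipeline presets are tau = 1
#' (two-fold) and the relaxed tau = 0.5 used for the three-way
#' reconciliation; any positive threshold is accepted.
#'
#' @param name signature name.
#' @param up,down character vectors of gene ids.
#' @param universe character vector of all genes the signature was derived
#'   from; must contain `up` and `down`.
#' @param threshold_log2 positive log2 fold-change threshold.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, up, down, universe, threshold_log2 = 1) {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  universe <- sort(unique(as.character(universe)))
  if (length(intersect(up, down)) > 0L) {
    stop("up and down sets must be disjoint", call. = FALSE)
  }
  if (!all(up %in% universe) || !all(down %in% universe)) {
    stop("up/down sets must be contained in the universe", call. = FALSE)
  }
  if (!is.numeric(threshold_log2) || threshold_log2 <= 0) {
    stop("threshold_log2 must be positive", call. = FALSE)
  }
  structure(list(name = as.character(name), up = up, down = down,
                 universe = universe, threshold_log2 = threshold_log2),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up, %d down, universe %d, tau = %g\n",
              x$name, length(x$up), length(x$down), length(x$universe),
              x$threshold_log2))
  invisible(x)
}

.mean_rows <- function(expr, samples) {
  rowMeans(expr[, samples, drop = FALSE])
}

.check_samples <- function(expr, samples, what) {
  missing <- setdiff(samples, colnames(expr))
  if (length(missing) > 0L) {
    stop(what, " sample(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(samples) == 0L) stop(what, " group is empty", call. = FALSE)
}

#' Derive a signature from group-vs-reference mean fold change
#'
#' A gene enters the up set when the difference of mean log2 expression,
#' group minus reference, is at least `tau`, and the down set when it is at
#' most `-tau` (boundaries inclusive: "at least" a 2^tau-fold change).
#' Fold change is the difference of mean log2 values, i.e. the log2 ratio
#' of geometric means.
#'
#' @param expr log2 expression matrix.
#' @param group_samples,reference_samples disjoint, non-empty sample id
#'   vectors, all present in `expr`.
#' @param tau positive log2 fold-change threshold.
#' @param name signature name.
#' @return a [gene_signature()] whose universe is the gene set of `expr`.
#' @export
derive_group_signature <- function(expr, group_samples, reference_samples,
                                   tau = 1, name = "group_vs_reference") {
  validate_expression_matrix(expr)
  .check_samples(expr, group_samples, "group")
  .check_samples(expr, reference_samples, "reference")
  if (length(intersect(group_samples, reference_samples)) > 0L) {
    stop("group and reference samples overlap", call. = FALSE)
  }
  fc <- .mean_rows(expr, group_samples) - .mean_rows(expr, reference_samples)
  gene_signature(name,
                 up = rownames(expr)[fc >= tau],
                 down = rownames(expr)[fc <= -tau],
                 universe = rownames(expr), threshold_log2 = tau)
}

#' Derive a subtype marker signature against the mean of the other subtypes
#'
#' For a chosen subtype, genes are called up (down) when the subtype's mean
#' log2 expression exceeds (falls below) the mean over samples of all other
#' subtypes by at least `tau`.
#'
#' @param expr log2 expression matrix.
#' @param labels named character vector assigning each of its samples
#'   (names) a subtype; all named samples must be columns of `expr`.  At
#'   least two distinct subtypes are required.
#' @param subtype the subtype whose signature is derived.
#' @param tau positive log2 fold-change threshold.
#' @return a [gene_signature()] named after the subtype.
#' @export
derive_subtype_vs_rest_signature <- function(expr, labels, subtype, tau = 1) {
  validate_expression_matrix(expr)
  .check_samples(expr, names(labels), "labeled")
  if (length(unique(labels)) < 2L) {
    stop("need at least two subtype labels", call. = FALSE)
  }
  if (!subtype %in% labels) stop("subtype '", subtype, "' absent from labels",
                                 call. = FALSE)
  inside <- names(labels)[labels == subtype]
  outside <- names(labels)[labels != subtype]
  fc <- .mean_rows(expr, inside) - .mean_rows(expr, outside)
  gene_signature(subtype,
                 up = rownames(expr)[fc >= tau],
                 down = rownames(expr)[fc <= -tau],
                 universe = rownames(expr), threshold_log2 = tau)
}

#' Derive per-pair signatures from sorted +/- sample pairs, with consensus
#'
#' Each pair contributes a signature from the single-sample log2 difference
#' (positive minus negative fraction) thresholded at `tau`.  The consensus
#' signature collects genes up-regulated in at least `min_support` pairs
#' (likewise down).  A gene reaching both consensus sets is removed from
#' both and reported in `conflicts`.
#'
#' @param expr log2 expression matrix containing all pair samples.
#' @param pairs data frame with columns `pos` and `neg` (sample ids), one
#'   row per sorted pair.
#' @param tau positive log2 fold-change threshold.
#' @param min_support minimum number of supporting pairs for the consensus,
#'   between 1 and the number of pairs.
#' @param name consensus signature name.
#' @return list with elements `per_pair` (list of [gene_signature()]),
#'   `consensus` ([gene_signature()]) and `conflicts` (character vector of
#'   genes dropped from the consensus for conflicting directions).
#' @export
derive_paired_signature <- function(expr, pairs, tau = 1, min_support = 2,
                                    name = "paired_consensus") {
  validate_expression_matrix(expr)
  if (!is.data.frame(pairs) || !all(c("pos", "neg") %in% names(pairs))) {
    stop("pairs must be a data frame with columns pos and neg", call. = FALSE)
  }
  n_pairs <- nrow(pairs)
  if (n_pairs < 1L) stop("no pairs supplied", call. = FALSE)
  if (min_support < 1 || min_support > n_pairs) {
    stop("min_support must lie between 1 and the number of pairs",
         call. = FALSE)
  }
  per_pair <- vector("list", n_pairs)
  pair_ids <- if (!is.null(rownames(pairs)) &&
                  !identical(rownames(pairs), as.character(seq_len(n_pairs)))) {
    rownames(pairs)
  } else {
    paste0("pair", seq_len(n_pairs))
  }
  up_count <- down_count <- stats::setNames(integer(nrow(expr)), rownames(expr))
  for (i in seq_len(n_pairs)) {
    pos <- as.character(pairs$pos[i]); neg <- as.character(pairs$neg[i])
    if (identical(pos, neg)) {
      stop("pair ", pair_ids[i], " uses the same sample twice", call. = FALSE)
    }
    .check_samples(expr, c(pos, neg), paste0("pair ", pair_ids[i]))
    fc <- expr[, pos] - expr[, neg]
    sig <- gene_signature(pair_ids[i],
                          up = rownames(expr)[fc >= tau],
                          down = rownames(expr)[fc <= -tau],
                          universe = rownames(expr), threshold_log2 = tau)
    per_pair[[i]] <- sig
    up_count[sig$up] <- up_count[sig$up] + 1L
    down_count[sig$down] <- down_count[sig$down] + 1L
  }
  names(per_pair) <- pair_ids
  up <- names(up_count)[up_count >= min_support]
  down <- names(down_count)[down_count >= min_support]
  conflicts <- intersect(up, down)
  if (length(conflicts) > 0L) {
    message(length(conflicts),
            " gene(s) supported in both directions removed from consensus")
    up <- setdiff(up, conflicts)
    down <- setdiff(down, conflicts)
  }
  consensus <- gene_signature(name, up = up, down = down,
                              universe = rownames(expr), threshold_log2 = tau)
  list(per_pair = per_pair, consensus = consensus,
       conflicts = sort(conflicts))
}

#' Per-sample log2 fold changes against a reference mean
#'
#' Returns a matrix of the same shape rules as an expression matrix whose
#' entry (g, s) is `expr[g, s]` minus the mean log2 expression of gene g
#' over the reference samples.
#'
#' @param expr log2 expression matrix.
#' @param reference_samples non-empty sample id vector, all in `expr`.
#' @param samples samples to report (default: all non-reference columns).
#' @return fold-change matrix (genes x samples), log2 FC units.
#' @export
per_sample_log2fc <- function(expr, reference_samples, samples = NULL) {
  validate_expression_matrix(expr)
  .check_samples(expr, reference_samples, "reference")
  if (is.null(samples)) samples <- setdiff(colnames(expr), reference_samples)
  .check_samples(expr, samples, "query")
  ref <- .mean_rows(expr, reference_samples)
  expr[, samples, drop = FALSE] - ref
}

#' Read / write signature files
#'
#' Plain-text format with `#up` / `#down` section markers (and an optional
#' `#universe` section), one gene id per line.  Metadata lines `#name:` and
#' `#tau:` carry the signature name and threshold.
#'
#' @param sig a [gene_signature()].
#' @param path file path.
#' @return `write_signature()` returns `path` invisibly;
#'   `read_signature()` returns a [gene_signature()].  When the file has no
#'   `#universe` section the universe defaults to the union of up and down.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  lines <- c(paste0("#name: ", sig$name),
             paste0("#tau: ", format(sig$threshold_log2, digits = 17)),
             "#up", sig$up, "#down", sig$down, "#universe", sig$universe)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  name <- sub("^#name: *", "", grep("^#name:", lines, value = TRUE)[1])
  tau <- as.numeric(sub("^#tau: *", "", grep("^#tau:", lines, value = TRUE)[1]))
  if (is.na(name)) name <- "signature"
  if (is.na(tau)) tau <- 1
  section <- NA_character_
  sets <- list(up = character(), down = character(), universe = character())
  for (ln in lines) {
    if (grepl("^#(name|tau):", ln)) next
    if (ln %in% c("#up", "#down", "#universe")) {
      section <- sub("^#", "", ln)
    } else if (nzchar(ln)) {
      if (is.na(section)) stop("gene line before any section marker in ", path,
                               call. = FALSE)
      sets[[section]] <- c(sets[[section]], ln)
    }
  }
  universe <- if (length(sets$universe) > 0L) sets$universe else
    union(sets$up, sets$down)
  gene_signature(name, sets$up, sets$down, universe, threshold_log2 = tau)
}

#' Serialize a signature to JSON
#'
#' @param sig a [gene_signature()].
#' @param path optional output path; when given the JSON is written there.
#' @return JSON string, invisibly when `path` is given.
#' @export
signature_to_json <- function(sig, path = NULL) {
  stopifnot(inherits(sig, "gene_signature"))
  obj <- list(name = sig$name, tau = sig$threshold_log2,
              n_up = length(sig$up), n_down = length(sig$down),
              n_universe = length(sig$universe),
              up = sig$up, down = sig$down)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
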