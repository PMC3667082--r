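#' Pearson correlation of sample fold-change profiles against inducer
#' profiles
#'
#' Each sample's expression signature is its per-sample log2 fold-change
#' vector (versus a reference mean, see [per_sample_log2fc()]); each
#' inducer's profile is its induced-versus-control mean log2 fold change.
#' Correlations are computed over the genes shared by the two fold-change
#' matrices.
#'
#' @param fc_samples fold-change matrix, genes x samples.
#' @param fc_inducers fold-change matrix, genes x inducers.
#' @return object of class `correlation_grid`: `r` (samples x inducers
#'   Pearson matrix), `genes` (shared gene universe used).
#' @export
correlate_profiles <- function(fc_samples, fc_inducers) {
  validate_expression_matrix(fc_samples)
  validate_expression_matrix(fc_inducers)
  shared <- intersect(rownames(fc_samples), rownames(fc_inducers))
  if (length(shared) < 3L) {
    stop("need at least 3 shared genes to correlate profiles", call. = FALSE)
  }
  a <- fc_samples[shared, , drop = FALSE]
  b <- fc_inducers[shared, , drop = FALSE]
  flat <- function(m) {
    v <- apply(m, 2L, stats::var)
    colnames(m)[v == 0]
  }
  bad <- c(flat(a), flat(b))
  if (length(bad) > 0L) {
    stop("zero-variance profile(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(r = stats::cor(a, b), genes = sort(shared)),
            class = "correlation_grid")
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat(sprintf("correlation_grid: %d samples x %d profiles over %d genes\n",
              nrow(x$r), ncol(x$r), length(x$genes)))
  invisible(x)
}

#' Group-wise averages of a correlation grid
#'
#' Averages the Pearson grid over sample groups (e.g. tumor subtypes)
#' and/or inducer groups, producing the per-(group, inducer) cell means,
#' the per-sample-group means across all inducers, and the per-inducer
#' means across all samples.
#'
#' @param grid a `correlation_grid` from [correlate_profiles()].
#' @param sample_groups named character vector partitioning the grid's
#'   samples into groups.
#' @param inducer_groups optional named character vector partitioning the
#'   inducers; by default every inducer is its own group.
#' @return list with `cell_means` (sample group x inducer group),
#'   `sample_group_means` and `inducer_group_means` (named vectors).
#' @export
group_average <- function(grid, sample_groups, inducer_groups = NULL) {
  stopifnot(inherits(grid, "correlation_grid"))
  r <- grid$r
  if (!setequal(names(sample_groups), rownames(r))) {
    stop("sample_groups must cover exactly the grid's samples", call. = FALSE)
  }
  if (is.null(inducer_groups)) {
    inducer_groups <- stats::setNames(colnames(r), colnames(r))
  }
  if (!setequal(names(inducer_groups), colnames(r))) {
    stop("inducer_groups must cover exactly the grid's profiles",
         call. = FALSE)
  }
  sg <- sample_groups[rownames(r)]
  ig <- inducer_groups[colnames(r)]
  if (any(table(sg) == 0L) || any(table(ig) == 0L)) {
    stop("empty group", call. = FALSE)
  }
  sgs <- sort(unique(sg)); igs <- sort(unique(ig))
  cells <- matrix(NA_real_, length(sgs), length(igs),
                  dimnames = list(sgs, igs))
  for (g in sgs) {
    for (h in igs) {
      cells[g, h] <- mean(r[sg == g, ig == h, drop = FALSE])
    }
  }
  list(cell_means = cells,
       sample_group_means = vapply(sgs, function(g)
         mean(r[sg == g, , drop = FALSE]), numeric(1)),
       inducer_group_means = vapply(igs, function(h)
         mean(r[, ig == h, drop = FALSE]), numeric(1)))
}

#' Mean log2 fold change of a gene set per sample group
#'
#' Averages the signed log2 fold change over all (gene, sample) cells of a
#' gene set within each sample group, and reports the absolute value
#' alongside (the display convention for down-regulated sets, whose
#' summaries are shown as magnitudes).
#'
#' @param fc fold-change matrix, genes x samples.
#' @param gene_set character vector of genes; its intersection with the
#'   matrix rows must be non-empty.
#' @param sample_groups named character vector assigning each of its
#'   samples to a group; all named samples must be columns of `fc`.
#' @return data frame with columns `group`, `n_genes`, `n_samples`,
#'   `mean_log2fc` (signed) and `mean_abs` (absolute value of the mean).
#' @export
mean_absfc_summary <- function(fc, gene_set, sample_groups) {
  validate_expression_matrix(fc)
  genes <- intersect(gene_set, rownames(fc))
  if (length(genes) == 0L) {
    stop("gene set does not intersect the fold-change matrix", call. = FALSE)
  }
  .check_samples(fc, names(sample_groups), "grouped")
  groups <- sort(unique(sample_groups))
  rows <- lapply(groups, function(g) {
    samp <- names(sample_groups)[sample_groups == g]
    m <- mean(fc[genes, samp, drop = FALSE])
    data.frame(group = g, n_genes = length(genes), n_samples = length(samp),
               mean_log2fc = m, mean_abs = abs(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
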