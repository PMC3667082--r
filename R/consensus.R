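# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Filter genes by median absolute deviation
#'
#' Keeps genes whose unscaled MAD, `median(|x - median(x)|)` over the
#' selected samples, is at least `min_mad`.  Low-MAD genes carry no
#' grouping information and are removed before clustering.
#'
#' @param expr log2 expression matrix.
#' @param min_mad non-negative MAD threshold (0.5 in the clustering preset).
#' @param samples samples over which the MAD is evaluated (default all).
#' @return the filtered expression matrix (all samples retained).
#' @export
mad_filter <- function(expr, min_mad = 0.5, samples = NULL) {
  validate_expression_matrix(expr)
  if (!is.numeric(min_mad) || min_mad < 0) {
    stop("min_mad must be non-negative", call. = FALSE)
  }
  if (is.null(samples)) samples <- colnames(expr)
  .check_samples(expr, samples, "MAD")
  mads <- apply(expr[, samples, drop = FALSE], 1L,
                function(r) stats::mad(r, constant = 1))
  keep <- mads >= min_mad
  if (!any(keep)) stop("all genes fall below the MAD threshold", call. = FALSE)
  expr[keep, , drop = FALSE]
}

#' Standardize each gene row to zero mean and unit variance
#'
#' Uses the population (divide-by-n) variance.  Constant rows cannot be
#' standardized and raise an error naming the first offending gene; they
#' are expected to have been removed by [mad_filter()].
#'
#' @param expr log2 expression matrix.
#' @return matrix of the same shape with row means 0 and row variances 1.
#' @export
zscore_rows <- function(expr) {
  validate_expression_matrix(expr)
  ctr <- expr - rowMeans(expr)
  sd_pop <- sqrt(rowMeans(ctr^2))
  if (any(sd_pop == 0)) {
    stop("constant row cannot be standardized: gene '",
         rownames(expr)[which(sd_pop == 0)[1]], "'", call. = FALSE)
  }
  ctr / sd_pop
}

#' Consensus k-means clustering of samples
#'
#' Repeatedly subsamples the columns (samples) without replacement, runs
#' k-means (Euclidean, with `kmeans_restarts` random initializations
#' keeping the best within-cluster sum of squares), and records for every
#' sample pair how often it was clustered together.  The consensus entry
#' m_ij is the co-clustering count divided by the number of resamples in
#' which i and j were co-drawn.  Final labels are extracted by
#' average-linkage hierarchical clustering of the dissimilarity
#' 1 - consensus, cut at k.
#'
#' @param expr expression matrix (typically MAD-filtered and row
#'   standardized); columns are clustered.
#' @param k number of clusters, `1 <= k <=` number of samples.
#' @param n_resamples number of subsampling iterations.
#' @param subsample_fraction fraction of samples drawn each iteration,
#'   in (0, 1].
#' @param seed integer seed making the whole resample/restart stream
#'   reproducible; the caller's RNG state is left untouched.
#' @param kmeans_restarts random restarts per resample.
#' @param iter_max maximum k-means iterations.
#' @return object of class `consensus_result`: `k`, `consensus` (sample x
#'   sample matrix in \[0, 1\]), `labels` (named integer vector),
#'   `quality_factor`, and `run_params`.
#' @export
consensus_kmeans <- function(expr, k, n_resamples = 500,
                             subsample_fraction = 0.8, seed = NULL,
                             kmeans_restarts = 10, iter_max = 50) {
  validate_expression_matrix(expr)
  n <- ncol(expr)
  if (k < 1 || k > n) stop("k must lie between 1 and the number of samples",
                           call. = FALSE)
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (n_resamples < 1) stop("need at least one resample", call. = FALSE)
  m <- ceiling(subsample_fraction * n)
  if (k > m) stop("subsample smaller than k; raise subsample_fraction",
                  call. = FALSE)
  dat <- t(expr)  # samples x genes for kmeans
  co_cluster <- matrix(0, n, n)
  co_drawn <- matrix(0, n, n)
  .with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, m))
      cl <- if (k == 1L) rep(1L, m) else {
        stats::kmeans(dat[idx, , drop = FALSE], centers = k,
                      nstart = kmeans_restarts, iter.max = iter_max)$cluster
      }
      same <- outer(cl, cl, "==")
      co_cluster[idx, idx] <- co_cluster[idx, idx] + same
      co_drawn[idx, idx] <- co_drawn[idx, idx] + 1
    }
  })
  never <- co_drawn == 0
  diag(never) <- FALSE
  if (any(never)) {
    stop("some sample pairs were never co-drawn; increase n_resamples",
         call. = FALSE)
  }
  consensus <- co_cluster / pmax(co_drawn, 1)
  diag(consensus)[diag(co_drawn) == 0] <- 1  # samples never drawn at all
  dimnames(consensus) <- list(colnames(expr), colnames(expr))
  labels <- if (k == 1L) {
    stats::setNames(rep(1L, n), colnames(expr))
  } else {
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    stats::cutree(hc, k = k)
  }
  if (length(unique(labels)) < k) {
    warning("consensus labels use fewer than k clusters", call. = FALSE)
  }
  structure(list(k = as.integer(k), consensus = consensus, labels = labels,
                 quality_factor = quality_factor(consensus),
                 run_params = list(n_resamples = n_resamples,
                                   subsample_fraction = subsample_fraction,
                                   seed = seed,
                                   kmeans_restarts = kmeans_restarts)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k = %d, %d samples, quality factor %.3f\n",
              x$k, ncol(x$consensus), x$quality_factor))
  invisible(x)
}

#' Consensus-matrix quality factor
#'
#' Cleanness score of a consensus matrix: the mean over off-diagonal
#' entries of `2 * |m_ij - 0.5|`.  It equals 1 exactly when every entry is
#' 0 or 1 (perfectly stable clustering) and 0 when every entry is 0.5
#' (coin-flip co-clustering), and increases as the matrix becomes cleaner.
#'
#' @param consensus square symmetric matrix with entries in \[0, 1\].
#' @return quality factor in \[0, 1\].
#' @export
quality_factor <- function(consensus) {
  if (!is.matrix(consensus) || nrow(consensus) != ncol(consensus)) {
    stop("consensus must be a square matrix", call. = FALSE)
  }
  if (any(consensus < 0 | consensus > 1)) {
    stop("consensus entries must lie in [0, 1]", call. = FALSE)
  }
  off <- consensus[row(consensus) != col(consensus)]
  if (length(off) == 0L) return(1)
  mean(2 * abs(off - 0.5))
}

#' Quality-factor curve over k with largest-drop model selection
#'
#' Runs [consensus_kmeans()] for each k in `k_range` and selects the k
#' preceding the largest drop in the quality factor, formalizing the
#' "sharp drop" rule for choosing the number of clusters: a clean
#' consensus at the true k degrades abruptly once k exceeds it.
#'
#' @param expr expression matrix (columns clustered).
#' @param k_range ascending integer vector of candidate k.
#' @param n_resamples,subsample_fraction,kmeans_restarts,iter_max passed to
#'   [consensus_kmeans()].
#' @param seed integer seed; each k uses the sub-seed `seed + 1000 * k` so
#'   adding or removing candidates never perturbs the other runs.
#' @return object of class `qf_curve`: data frame `curve` (k, quality
#'   factor), `selected_k`, and the per-k `results` list.
#' @export
select_k <- function(expr, k_range = 2:7, n_resamples = 500,
                     subsample_fraction = 0.8, seed = NULL,
                     kmeans_restarts = 10, iter_max = 50) {
  if (length(k_range) == 0L || is.unsorted(k_range, strictly = TRUE)) {
    stop("k_range must be non-empty and strictly ascending", call. = FALSE)
  }
  results <- lapply(k_range, function(k) {
    consensus_kmeans(expr, k, n_resamples = n_resamples,
                     subsample_fraction = subsample_fraction,
                     seed = if (is.null(seed)) NULL else seed + 1000L * k,
                     kmeans_restarts = kmeans_restarts, iter_max = iter_max)
  })
  names(results) <- paste0("k", k_range)
  qf <- vapply(results, function(r) r$quality_factor, numeric(1))
  selected <- if (length(k_range) == 1L) {
    k_range[1]
  } else {
    drops <- qf[-length(qf)] - qf[-1]
    k_range[which.max(drops)]
  }
  structure(list(curve = data.frame(k = k_range, quality_factor = unname(qf)),
                 selected_k = selected, results = results),
            class = "qf_curve")
}

#' @export
print.qf_curve <- function(x, ...) {
  cat("quality-factor curve:\n")
  print(x$curve, row.names = FALSE)
  cat("selected k (largest drop):", x$selected_k, "\n")
  invisible(x)
}

#' Permutation-invariant agreement between two labelings
#'
#' Fraction of samples on which two cluster labelings agree under the best
#' one-to-one relabeling.  For up to 8 clusters the optimum is found by
#' exhaustive permutation; beyond that a greedy matching is used.
#'
#' @param labels,reference vectors of cluster labels over the same samples
#'   (matched by name when both are named, else by position).
#' @return agreement in \[0, 1\].
#' @export
label_agreement <- function(labels, reference) {
  if (!is.null(names(labels)) && !is.null(names(reference))) {
    if (!setequal(names(labels), names(reference))) {
      stop("labelings cover different samples", call. = FALSE)
    }
    reference <- reference[names(labels)]
  }
  if (length(labels) != length(reference)) {
    stop("labelings must have equal length", call. = FALSE)
  }
  tab <- table(as.character(labels), as.character(reference))
  k1 <- nrow(tab); k2 <- ncol(tab)
  n <- length(labels)
  if (k1 <= 8L && k1 <= k2) {
    perms <- .permutations(k2, k1)
    best <- 0
    for (i in seq_len(nrow(perms))) {
      hit <- sum(tab[cbind(seq_len(k1), perms[i, ])])
      if (hit > best) best <- hit
    }
    return(best / n)
  }
  # greedy fallback: repeatedly take the largest remaining cell
  tab2 <- tab
  total <- 0
  for (step in seq_len(min(k1, k2))) {
    ij <- which(tab2 == max(tab2), arr.ind = TRUE)[1, ]
    total <- total + tab2[ij[1], ij[2]]
    tab2[ij[1], ] <- -1
    tab2[, ij[2]] <- -1
  }
  total / n
}

# All injections of 1..r into 1..m, as rows.
.permutations <- function(m, r = m) {
  if (r == 0L) return(matrix(integer(0), nrow = 1L))
  out <- matrix(seq_len(m), ncol = 1L)
  if (r == 1L) return(out)
  for (pos in 2:r) {
    blocks <- lapply(seq_len(nrow(out)), function(i) {
      rest <- setdiff(seq_len(m), out[i, ])
      cbind(matrix(out[i, ], nrow = length(rest), ncol = pos - 1L,
                   byrow = TRUE), rest)
    })
    out <- do.call(rbind, blocks)
  }
  unname(out)
}

#' Match cluster signatures to reference signatures by up-set overlap
#'
#' Builds the cluster x reference grid of up-regulated gene overlap counts
#' and assigns each cluster to at most one reference by greedy maximum
#' count; ties break lexicographically on the reference name, then on the
#' cluster name.  Used to identify de novo clusters with previously
#' published subtype signatures.
#'
#' @param cluster_signatures,reference_signatures lists of
#'   [gene_signature()]s with non-empty up sets.
#' @return object of class `confusion_table`: `counts` (matrix), `matching`
#'   (data frame cluster/reference/overlap), and `uninformative` (`TRUE`
#'   when the grid is all zero).
#' @export
confusion_match <- function(cluster_signatures, reference_signatures) {
  .sig_names <- function(sigs) vapply(sigs, function(s) s$name, character(1))
  if (length(cluster_signatures) == 0L || length(reference_signatures) == 0L) {
    stop("signature lists must be non-empty", call. = FALSE)
  }
  for (s in c(cluster_signatures, reference_signatures)) {
    if (length(s$up) == 0L) stop("signature '", s$name, "' has an empty up set",
                                 call. = FALSE)
  }
  cn <- .sig_names(cluster_signatures); rn <- .sig_names(reference_signatures)
  counts <- matrix(0L, length(cn), length(rn), dimnames = list(cn, rn))
  for (i in seq_along(cn)) {
    for (j in seq_along(rn)) {
      counts[i, j] <- length(intersect(cluster_signatures[[i]]$up,
                                       reference_signatures[[j]]$up))
    }
  }
  uninformative <- all(counts == 0L)
  remaining <- counts
  matching <- data.frame(cluster = character(), reference = character(),
                         overlap = integer(), stringsAsFactors = FALSE)
  if (!uninformative) {
    for (step in seq_len(min(dim(counts)))) {
      mx <- max(remaining)
      if (mx < 0) break
      hits <- which(remaining == mx, arr.ind = TRUE)
      hits <- hits[order(colnames(remaining)[hits[, 2]],
                         rownames(remaining)[hits[, 1]]), , drop = FALSE]
      i <- hits[1, 1]; j <- hits[1, 2]
      matching <- rbind(matching,
                        data.frame(cluster = rownames(remaining)[i],
                                   reference = colnames(remaining)[j],
                                   overlap = counts[i, j],
                                   stringsAsFactors = FALSE))
      remaining[i, ] <- -1L
      remaining[, j] <- -1L
    }
  }
  structure(list(counts = counts, matching = matching,
                 uninformative = uninformative),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("confusion table (up-set overlap counts):\n")
  print(x$counts)
  if (x$uninformative) {
    cat("matching uninformative: all overlaps are zero\n")
  } else {
    print(x$matching, row.names = FALSE)
  }
  invisible(x)
}
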