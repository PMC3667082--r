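#' Two-sided Fisher exact p-value for a gene-list overlap
#'
#' Exact two-sided p-value of observing `overlap` genes in common between
#' lists of sizes `n_a` and `n_b` drawn from a background of `n_background`
#' genes, by the point-probability (minimum-likelihood) rule: the sum of
#' hypergeometric probabilities P(k), over all achievable overlaps k, whose
#' P(k) does not exceed P(overlap).  A relative tolerance of 1e-7 on the
#' comparison absorbs floating-point ties, matching the convention of
#' standard two-sided Fisher implementations.  Probabilities are evaluated
#' on the log scale internally, so backgrounds of ten thousand genes or
#' more pose no overflow risk.
#'
#' @param overlap observed overlap(s) a; may be a vector.
#' @param n_a,n_b list sizes after restriction to the background.
#' @param n_background background (universe) size N.
#' @return p-value(s) in (0, 1], one per element of `overlap`.
#' @export
fisher_overlap_p <- function(overlap, n_a, n_b, n_background) {
  N <- as.integer(n_background)
  n_a <- as.integer(n_a); n_b <- as.integer(n_b)
  if (N < 1L) stop("background must be non-empty", call. = FALSE)
  if (n_a > N || n_b > N || n_a < 0L || n_b < 0L) {
    stop("list sizes must lie in [0, n_background]", call. = FALSE)
  }
  k_min <- max(0L, n_a + n_b - N)
  k_max <- min(n_a, n_b)
  a <- as.integer(overlap)
  if (any(a < k_min | a > k_max)) {
    stop("overlap outside the achievable range [", k_min, ", ", k_max, "]",
         call. = FALSE)
  }
  k <- k_min:k_max
  pk <- stats::dhyper(k, n_a, N - n_a, n_b)
  ord <- order(pk)
  cum <- cumsum(pk[ord])
  # p(a) = total probability of outcomes no more likely than a (1e-7 slack)
  idx <- findInterval(pk[match(a, k)] * (1 + 1e-7), pk[ord])
  pmin(1, cum[idx])
}

#' Background-harmonized two-sided Fisher exact overlap test
#'
#' Restricts both gene lists to the background universe, builds the 2x2
#' membership table, and tests the overlap in both directions (enrichment
#' and depletion) with the exact hypergeometric point-probability rule of
#' [fisher_overlap_p()].  The expected overlap under chance is
#' `n_a * n_b / N`.
#'
#' @param list_a,list_b character vectors of gene ids.
#' @param background character vector, the gene universe (sampling frame).
#' @param alpha significance level in (0, 1).
#' @param name_a,name_b labels used in reports.
#' @return an object of class `overlap_result` with fields `n_background`,
#'   `n_a`, `n_b`, `overlap`, `counts_2x2` (a, b, c, d), `expected`,
#'   `p_value`, `direction` (`"enriched"`, `"depleted"` or `"none"`),
#'   `significant` and `alpha`.
#' @export
tsfet <- function(list_a, list_b, background, alpha = 0.05,
                  name_a = "A", name_b = "B") {
  if (length(background) == 0L) stop("background must be non-empty",
                                     call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  bg <- unique(as.character(background))
  ga <- intersect(unique(as.character(list_a)), bg)
  gb <- intersect(unique(as.character(list_b)), bg)
  N <- length(bg); n_a <- length(ga); n_b <- length(gb)
  a <- length(intersect(ga, gb))
  expected <- n_a * n_b / N
  p <- fisher_overlap_p(a, n_a, n_b, N)
  direction <- if (a > expected) "enriched" else if (a < expected) "depleted" else "none"
  structure(list(name_a = name_a, name_b = name_b,
                 n_background = N, n_a = n_a, n_b = n_b, overlap = a,
                 counts_2x2 = c(a = a, b = n_a - a, c = n_b - a,
                                d = N - n_a - n_b + a),
                 expected = expected, p_value = p, direction = direction,
                 significant = p < alpha, alpha = alpha),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, digits = 2, ...) {
  cat(sprintf("%s(%d) vs %s(%d) on background %d: overlap %d (expected %s), p = %.3g [%s%s]\n",
              x$name_a, x$n_a, x$name_b, x$n_b, x$n_background, x$overlap,
              format(round(x$expected, digits), nsmall = digits), x$p_value,
              x$direction, if (x$significant) ", significant" else ""))
  invisible(x)
}

#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(pair = paste0(x$name_a, "-", x$name_b),
             n_a = x$n_a, n_b = x$n_b, n_background = x$n_background,
             overlap = x$overlap, expected = x$expected,
             p_value = x$p_value, direction = x$direction,
             significant = x$significant, stringsAsFactors = FALSE)
}

#' Compare two signatures in all four direction pairings
#'
#' Harmonizes the two signatures' universes into a shared background and
#' runs [tsfet()] for (up, up), (down, down), (up, down) and (down, up).
#'
#' @param sig_a,sig_b [gene_signature()] objects carrying universes.
#' @param alpha significance level.
#' @return object of class `signature_comparison`: a list with the four
#'   `overlap_result`s (`up_up`, `down_down`, `up_down`, `down_up`), the
#'   signature names, `alpha` and the shared background size.
#' @export
compare_signatures <- function(sig_a, sig_b, alpha = 0.05) {
  stopifnot(inherits(sig_a, "gene_signature"), inherits(sig_b, "gene_signature"))
  bg <- harmonize_universe(sig_a$universe, sig_b$universe, quiet = TRUE)
  cell <- function(side_a, side_b) {
    tsfet(sig_a[[side_a]], sig_b[[side_b]], bg, alpha = alpha,
          name_a = paste0(sig_a$name, "_", side_a),
          name_b = paste0(sig_b$name, "_", side_b))
  }
  structure(list(up_up = cell("up", "up"),
                 down_down = cell("down", "down"),
                 up_down = cell("up", "down"),
                 down_up = cell("down", "up"),
                 name_a = sig_a$name, name_b = sig_b$name,
                 alpha = alpha, n_background = length(bg)),
            class = "signature_comparison")
}

#' @export
as.data.frame.signature_comparison <- function(x, ...) {
  cells <- c("up_up", "down_down", "up_down", "down_up")
  out <- do.call(rbind, lapply(x[cells], as.data.frame))
  out <- cbind(sig_a = x$name_a, sig_b = x$name_b, pairing = cells,
               out[, -1], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf("signature comparison %s vs %s (background %d, alpha %g)\n",
              x$name_a, x$name_b, x$n_background, x$alpha))
  for (cell in c("up_up", "down_down", "up_down", "down_up")) print(x[[cell]])
  invisible(x)
}

#' Grid of overlap tests between two lists of signatures
#'
#' Runs [compare_signatures()] for every pair (row-major over
#' `signatures_a` x `signatures_b`); each cell's background is the
#' harmonized universe of that pair.  Returned as a long data frame in the
#' "overlap (expected) / p-value" report layout, one row per direction
#' pairing per cell.
#'
#' @param signatures_a,signatures_b non-empty lists of [gene_signature()]s.
#' @param alpha significance level.
#' @param pairings which direction pairings to report (default all four).
#' @return data frame with columns `sig_a`, `sig_b`, `pairing`, `n_a`,
#'   `n_b`, `n_background`, `overlap`, `expected`, `p_value`, `direction`,
#'   `significant`.
#' @export
batch_overlap_table <- function(signatures_a, signatures_b, alpha = 0.05,
                                pairings = c("up_up", "down_down",
                                             "up_down", "down_up")) {
  if (length(signatures_a) == 0L || length(signatures_b) == 0L) {
    stop("signature lists must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (sa in signatures_a) {
    for (sb in signatures_b) {
      cmp <- as.data.frame(compare_signatures(sa, sb, alpha = alpha))
      rows[[length(rows) + 1L]] <- cmp[cmp$pairing %in% pairings, , drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an overlap report
#'
#' @param report data frame as returned by [batch_overlap_table()] or
#'   `as.data.frame()` on a comparison.
#' @param path output path; `.json` extension selects JSON, anything else
#'   TSV.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    writeLines(jsonlite::toJSON(report, dataframe = "rows", digits = NA,
                                auto_unbox = TRUE), path)
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
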