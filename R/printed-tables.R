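#' Published overlap-table rows bundled with the package
#'
#' The published analysis reports its signature comparisons as tables of
#' list sizes, overlap lengths, expected overlaps and two-sided Fisher
#' p-values on stated background universes.  Those printed list sizes and
#' overlaps are sufficient input to recompute every expected overlap and
#' p-value from scratch, which makes them a strong end-to-end check of the
#' overlap machinery.  This function returns the bundled rows (the
#' comparisons of the EMT core signature against the overall GBM
#' signature and the four subtype signatures, the opposite-direction EMT
#' versus CD133 comparisons, and the full subtype-versus-sorted-GBM
#' grid).  A handful of published same-direction EMT-versus-CD133 rows
#' whose printed expected overlaps are inconsistent with their own stated
#' list sizes are not included.
#'
#' @return data frame with columns `table`, `pair`, `side_a`, `side_b`,
#'   `n_background`, `n_a`, `n_b`, `overlap`, `expected_printed` and
#'   `p_printed` (the last two as printed, i.e. character).
#' @export
printed_overlap_rows <- function() {
  path <- system.file("extdata", "printed_overlaps.tsv", package = "gbmsig",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = c(rep("character", 4), rep("integer", 4),
                                   "character", "character"),
                    stringsAsFactors = FALSE)
}

#' Recompute the published overlap statistics from the printed sizes
#'
#' Runs the two-sided Fisher machinery on every bundled row of
#' [printed_overlap_rows()] and returns the recomputed expected overlap
#' and p-value next to the printed values, together with agreement flags:
#' `expected_match` is `TRUE` when the recomputed expectation rounds to
#' the printed decimals, `p_match` when the recomputed p-value agrees with
#' the printed one to its printed significant figures (at most 3).
#'
#' @param rows data frame in the layout of [printed_overlap_rows()].
#' @return the input with columns `expected`, `p_value`,
#'   `expected_match`, `p_match` and `p_rel_err` appended.
#' @export
recompute_printed_tables <- function(rows = printed_overlap_rows()) {
  dec <- function(s) {
    frac <- sub("^[^.]*", "", s)
    if (nchar(frac) == 0L) 0L else nchar(frac) - 1L
  }
  sigfigs <- function(s) {
    mant <- sub("[eE].*$", "", s)
    nchar(gsub("[^0-9]", "", sub("^0*\\.?0*", "", mant)))
  }
  rows$expected <- rows$n_a * rows$n_b / rows$n_background
  rows$p_value <- mapply(fisher_overlap_p, rows$overlap, rows$n_a, rows$n_b,
                         rows$n_background)
  rows$expected_match <- mapply(function(e, printed) {
    isTRUE(all.equal(round(e, dec(printed)), as.numeric(printed),
                     tolerance = 1e-9))
  }, rows$expected, rows$expected_printed)
  rows$p_match <- mapply(function(p, printed) {
    d <- min(3L, sigfigs(printed))
    isTRUE(all.equal(signif(p, d), as.numeric(printed),
                     tolerance = 1e-9))
  }, rows$p_value, rows$p_printed)
  rows$p_rel_err <- abs(rows$p_value / as.numeric(rows$p_printed) - 1)
  rows
}
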