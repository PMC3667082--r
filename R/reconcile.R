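#' Discordant gene sets between two signatures
#'
#' Genes regulated in opposite directions by two signatures, restricted to
#' a shared background: `a_down_b_up` holds genes down in `sig_a` and up
#' in `sig_b`; `a_up_b_down` the reverse.  These discordant sets are the
#' unit of the three-way reconciliation analysis.
#'
#' @param sig_a,sig_b [gene_signature()] objects.
#' @param background character vector, the shared gene universe.
#' @return object of class `discordant_sets` with fields `a_down_b_up`,
#'   `a_up_b_down`, `name_a`, `name_b`, `background`.
#' @export
discordant_sets <- function(sig_a, sig_b, background) {
  stopifnot(inherits(sig_a, "gene_signature"), inherits(sig_b, "gene_signature"))
  if (length(background) == 0L) stop("background must be non-empty",
                                     call. = FALSE)
  bg <- unique(as.character(background))
  structure(list(
    a_down_b_up = sort(intersect(intersect(sig_a$down, sig_b$up), bg)),
    a_up_b_down = sort(intersect(intersect(sig_a$up, sig_b$down), bg)),
    name_a = sig_a$name, name_b = sig_b$name, background = sort(bg)),
    class = "discordant_sets")
}

#' @export
print.discordant_sets <- function(x, ...) {
  cat(sprintf("discordant sets %s vs %s (background %d): %s_down-%s_up %d genes, %s_up-%s_down %d genes\n",
              x$name_a, x$name_b, length(x$background),
              x$name_a, x$name_b, length(x$a_down_b_up),
              x$name_a, x$name_b, length(x$a_up_b_down)))
  invisible(x)
}

#' Test a discordant set against one side of a third signature
#'
#' Delegates to [tsfet()] on the triple-harmonized background: do the
#' genes discordant between two signatures coincide with the up (or down)
#' set of a third signature more than chance predicts?
#'
#' @param discordant_set character vector of genes (one side of a
#'   [discordant_sets()] result).
#' @param third_sig_side character vector, one side (up or down) of the
#'   third signature.
#' @param background shared background of all three universes.
#' @param alpha significance level.
#' @param name_a,name_b labels for the report.
#' @return an `overlap_result`.
#' @export
reconcile <- function(discordant_set, third_sig_side, background,
                      alpha = 0.05, name_a = "discordant", name_b = "third") {
  tsfet(discordant_set, third_sig_side, background, alpha = alpha,
        name_a = name_a, name_b = name_b)
}

#' Three-way reconciliation of a subtype signature with two opposing
#' signatures
#'
#' Re-derives the subtype's signature from expression data at the relaxed
#' threshold, harmonizes the three universes into a triple background, and
#' runs the four discordance tests: genes down in the first signature but
#' up in the subtype against the second signature's up set, and the three
#' analogous pairings.  The relaxed threshold (0.5 on the log2 scale
#' instead of 1) keeps the discordant lists large enough for a three-way
#' intersection to be informative.
#'
#' @param expr log2 expression matrix for the subtype dataset.
#' @param groups named character vector of group labels for `expr` samples.
#' @param subtype label of the subtype of interest (e.g. the
#'   mesenchymal-like group).
#' @param reference_group label of the reference (normal) group.
#' @param sig_emt EMT-like [gene_signature()] (derived at the same relaxed
#'   threshold).
#' @param sig_cd133 CD133-like [gene_signature()] (same threshold).
#' @param tau relaxed log2 threshold for the subtype signature.
#' @param alpha significance level.
#' @return object of class `reconciliation`: `tests` (named list of four
#'   `overlap_result`s, `NULL` where a discordant set was empty, with a
#'   logged notice), `sets` (the two [discordant_sets()] objects),
#'   `sig_subtype`, and `n_background`.
#' @export
table7_pipeline <- function(expr, groups, subtype, reference_group,
                            sig_emt, sig_cd133, tau = 0.5, alpha = 0.05) {
  .check_samples(expr, names(groups), "grouped")
  sub_samples <- names(groups)[groups == subtype]
  ref_samples <- names(groups)[groups == reference_group]
  if (length(sub_samples) == 0L) stop("subtype '", subtype, "' has no samples",
                                      call. = FALSE)
  if (length(ref_samples) == 0L) stop("reference group '", reference_group,
                                      "' has no samples", call. = FALSE)
  sig_sub <- derive_group_signature(expr, sub_samples, ref_samples,
                                    tau = tau, name = subtype)
  bg <- harmonize_universe(sig_sub$universe, sig_emt$universe,
                           sig_cd133$universe, quiet = TRUE)
  ds_emt <- discordant_sets(sig_emt, sig_sub, bg)
  ds_cd <- discordant_sets(sig_cd133, sig_sub, bg)
  run <- function(set, side_genes, name_a, name_b) {
    if (length(set) == 0L) {
      message("discordant set ", name_a, " is empty; test skipped")
      return(NULL)
    }
    reconcile(set, side_genes, bg, alpha = alpha,
              name_a = name_a, name_b = name_b)
  }
  emt <- sig_emt$name; cd <- sig_cd133$name; sub <- sig_sub$name
  tests <- list(
    emt_down_sub_up_vs_cd_up =
      run(ds_emt$a_down_b_up, sig_cd133$up,
          paste0(emt, "_down-", sub, "_up"), paste0(cd, "_up")),
    emt_up_sub_down_vs_cd_down =
      run(ds_emt$a_up_b_down, sig_cd133$down,
          paste0(emt, "_up-", sub, "_down"), paste0(cd, "_down")),
    cd_down_sub_up_vs_emt_up =
      run(ds_cd$a_down_b_up, sig_emt$up,
          paste0(cd, "_down-", sub, "_up"), paste0(emt, "_up")),
    cd_up_sub_down_vs_emt_down =
      run(ds_cd$a_up_b_down, sig_emt$down,
          paste0(cd, "_up-", sub, "_down"), paste0(emt, "_down")))
  structure(list(tests = tests, sets = list(emt = ds_emt, cd133 = ds_cd),
                 sig_subtype = sig_sub, n_background = length(bg)),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("three-way reconciliation (background %d genes)\n",
              x$n_background))
  for (nm in names(x$tests)) {
    if (is.null(x$tests[[nm]])) cat(nm, ": skipped (empty discordant set)\n")
    else print(x$tests[[nm]])
  }
  invisible(x)
}

#' @export
as.data.frame.reconciliation <- function(x, ...) {
  rows <- lapply(x$tests, function(t) if (is.null(t)) NULL else
    as.data.frame(t))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
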