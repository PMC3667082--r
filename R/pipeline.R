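#' Run the full signature-concordance analysis on a synthetic study
#'
#' Orchestrates every stage on a generated study: signature derivation
#' (overall tumor-vs-normal, per-subtype vs normal, subtype vs rest, EMT
#' from the pooled induced samples, per-pair sorted signatures with
#' consensus), the four overlap-table analogues, consensus k-means
#' clustering with quality-factor model selection and confusion matching
#' against the planted subtype signatures, correlation profiling against
#' the inducer profiles, and the relaxed-threshold three-way
#' reconciliation.  When `out_dir` is given, every table is written as
#' TSV/JSON together with a run log recording parameters and seed.
#'
#' @param config a [synthetic_config()]; its `seed` governs the study and,
#'   offset by fixed amounts, the clustering resamples.
#' @param out_dir optional output directory.
#' @param tau main log2 threshold (two-fold).
#' @param tau_relaxed relaxed threshold for the reconciliation stage.
#' @param alpha significance level for all overlap tests.
#' @param mad_min MAD filter threshold applied before clustering.  The
#'   preset for real tumor compendia is 0.5; the default `NULL` scales the
#'   threshold to the data instead, 25% above the MAD of pure noise
#'   (`0.6745 * noise_sd`), which plays the same role at the synthetic
#'   noise scale.
#' @param k_range candidate cluster numbers.
#' @param n_resamples,subsample_fraction,kmeans_restarts consensus
#'   clustering parameters (see [consensus_kmeans()]).
#' @param min_support consensus support for the paired signature.
#' @return invisible list with all stage results: `study`, `signatures`,
#'   `overlap_tables`, `clustering`, `correlation`, `reconciliation`.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         tau = 1, tau_relaxed = 0.5, alpha = 0.05,
                         mad_min = NULL, k_range = 2:7,
                         n_resamples = 100, subsample_fraction = 0.8,
                         kmeans_restarts = 5, min_support = 2) {
  study <- generate_study(config)
  man <- study$manifests
  normal <- names(man$tumor)[man$tumor == "normal"]
  tumor <- names(man$tumor)[man$tumor != "normal"]
  labels <- man$tumor[tumor]
  subtypes <- names(config$samples_per_subtype)
  mes <- subtypes[1]

  ## signatures -----------------------------------------------------------
  sig_gbm <- derive_group_signature(study$expr_tumor, tumor, normal,
                                    tau = tau, name = "GBM")
  sig_subtype_vs_normal <- stats::setNames(lapply(subtypes, function(s) {
    derive_group_signature(study$expr_tumor, names(labels)[labels == s],
                           normal, tau = tau, name = s)
  }), subtypes)
  sig_subtype_vs_rest <- stats::setNames(lapply(subtypes, function(s) {
    derive_subtype_vs_rest_signature(study$expr_tumor, labels, s, tau = tau)
  }), subtypes)
  induced <- names(man$inducers)[man$inducers != "control"]
  controls <- names(man$inducers)[man$inducers == "control"]
  sig_emt <- derive_group_signature(study$expr_inducers, induced, controls,
                                    tau = tau, name = "EMT")
  paired <- derive_paired_signature(study$expr_pairs, man$pairs, tau = tau,
                                    min_support = min_support,
                                    name = "CD133")
  signatures <- list(gbm = sig_gbm, subtype_vs_normal = sig_subtype_vs_normal,
                     subtype_vs_rest = sig_subtype_vs_rest, emt = sig_emt,
                     cd133 = paired)

  ## overlap tables --------------------------------------------------------
  overlap_tables <- list(
    emt_vs_gbm = as.data.frame(compare_signatures(sig_emt, sig_gbm,
                                                  alpha = alpha)),
    emt_vs_subtypes = batch_overlap_table(list(sig_emt),
                                          sig_subtype_vs_normal,
                                          alpha = alpha),
    emt_vs_pairs = batch_overlap_table(list(sig_emt), paired$per_pair,
                                       alpha = alpha),
    subtypes_vs_cd133 = batch_overlap_table(sig_subtype_vs_normal,
                                            c(paired$per_pair,
                                              list(paired$consensus)),
                                            alpha = alpha))

  ## clustering ------------------------------------------------------------
  # pure-noise rows have MAD ~= 0.6745 * sigma; a 25% margin separates them
  # from rows carrying a planted subtype shift
  if (is.null(mad_min)) mad_min <- 1.25 * 0.6745 * config$noise_sd
  tumor_expr <- study$expr_tumor[, tumor, drop = FALSE]
  filtered <- mad_filter(tumor_expr, min_mad = mad_min)
  standardized <- zscore_rows(filtered)
  kcurve <- select_k(standardized, k_range = k_range,
                     n_resamples = n_resamples,
                     subsample_fraction = subsample_fraction,
                     seed = config$seed + 100L,
                     kmeans_restarts = kmeans_restarts)
  chosen <- kcurve$results[[paste0("k", kcurve$selected_k)]]
  cluster_labels <- stats::setNames(
    paste0("cluster", chosen$labels), names(chosen$labels))
  cluster_sigs <- lapply(sort(unique(cluster_labels)), function(cl) {
    derive_subtype_vs_rest_signature(tumor_expr, cluster_labels, cl,
                                     tau = tau)
  })
  confusion <- confusion_match(cluster_sigs,
                               study$truth$subtype_signatures)
  clustering <- list(mad_min = mad_min, n_genes_kept = nrow(filtered),
                     qf_curve = kcurve, selected = chosen,
                     cluster_labels = cluster_labels, confusion = confusion)

  ## correlation -----------------------------------------------------------
  fc_samples <- per_sample_log2fc(study$expr_tumor, normal, tumor)
  inducer_names <- setdiff(unique(man$inducers), "control")
  fc_inducers <- do.call(cbind, lapply(inducer_names, function(i) {
    cols <- names(man$inducers)[man$inducers == i]
    rowMeans(study$expr_inducers[, cols, drop = FALSE]) -
      rowMeans(study$expr_inducers[, controls, drop = FALSE])
  }))
  colnames(fc_inducers) <- inducer_names
  grid <- correlate_profiles(fc_samples, fc_inducers)
  averages <- group_average(grid, labels)
  emt_up_shared <- intersect(sig_emt$up,
                             unique(unlist(lapply(sig_subtype_vs_normal,
                                                  function(s) s$up))))
  absfc <- if (length(intersect(emt_up_shared, rownames(fc_samples))) > 0L) {
    mean_absfc_summary(fc_samples, emt_up_shared, labels)
  } else NULL
  correlation <- list(grid = grid, averages = averages,
                      mean_absfc_up = absfc)

  ## reconciliation ---------------------------------------------------------
  sig_emt_rel <- derive_group_signature(study$expr_inducers, induced,
                                        controls, tau = tau_relaxed,
                                        name = "EMT")
  paired_rel <- derive_paired_signature(study$expr_pairs, man$pairs,
                                        tau = tau_relaxed,
                                        min_support = min_support,
                                        name = "CD133")
  reconciliation <- table7_pipeline(study$expr_tumor, man$tumor, mes,
                                    "normal", sig_emt_rel,
                                    paired_rel$consensus,
                                    tau = tau_relaxed, alpha = alpha)

  out <- list(study = study, signatures = signatures,
              overlap_tables = overlap_tables, clustering = clustering,
              correlation = correlation, reconciliation = reconciliation)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir, config,
                                                 tau, tau_relaxed, alpha)
  invisible(out)
}

.write_pipeline_outputs <- function(out, out_dir, config, tau, tau_relaxed,
                                    alpha) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(out$overlap_tables)) {
    write_overlap_report(out$overlap_tables[[nm]],
                         file.path(out_dir, paste0("overlap_", nm, ".tsv")))
  }
  utils::write.table(out$clustering$qf_curve$curve,
                     file.path(out_dir, "qf_curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cons <- out$clustering$selected$consensus
  utils::write.table(data.frame(sample_id = rownames(cons), cons,
                                check.names = FALSE),
                     file.path(out_dir, "consensus_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(out$clustering$cluster_labels),
                                cluster = unname(out$clustering$cluster_labels)),
                     file.path(out_dir, "cluster_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  r <- out$correlation$grid$r
  utils::write.table(data.frame(sample_id = rownames(r), r,
                                check.names = FALSE),
                     file.path(out_dir, "correlation_grid.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rec <- as.data.frame(out$reconciliation)
  if (!is.null(rec)) {
    write_overlap_report(rec, file.path(out_dir, "reconciliation.tsv"))
  }
  log_lines <- c(
    paste0("gbmsig ", as.character(utils::packageVersion("gbmsig"))),
    paste0("R ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("tau: ", tau, "  tau_relaxed: ", tau_relaxed, "  alpha: ", alpha),
    paste0("config: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
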