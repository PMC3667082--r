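#!/usr/bin/env Rscript
# Correlation profiling: Pearson correlation of every tumor sample's
# fold-change profile (vs the normal-group mean) against each inducer's
# induced-vs-control fold-change profile, averaged per subtype and per
# inducer; plus the mean |log2 FC| summary of the shared up-regulated
# genes per subtype.

library(gbmsig)

dir.create("results", showWarnings = FALSE)

st <- generate_study(synthetic_config(seed = 1))
man <- st$manifests
normal <- names(man$tumor)[man$tumor == "normal"]
labels <- man$tumor[man$tumor != "normal"]
induced_controls <- names(man$inducers)[man$inducers == "control"]

fc_samples <- per_sample_log2fc(st$expr_tumor, normal, names(labels))
inducer_names <- setdiff(unique(man$inducers), "control")
fc_inducers <- vapply(inducer_names, function(nm) {
  cols <- names(man$inducers)[man$inducers == nm]
  rowMeans(st$expr_inducers[, cols, drop = FALSE]) -
    rowMeans(st$expr_inducers[, induced_controls, drop = FALSE])
}, numeric(nrow(st$expr_inducers)))

grid <- correlate_profiles(fc_samples, fc_inducers)
av <- group_average(grid, labels)

cat("mean Pearson r per (subtype, inducer):\n")
print(round(av$cell_means, 3))
cat("\nper-subtype means over all inducers:\n")
print(round(av$sample_group_means, 3))
top <- rownames(av$cell_means)[apply(av$cell_means, 2, which.max)]
cat(sprintf("\nsubtype with the highest mean r for every inducer: %s\n",
            paste(unique(top), collapse = ", ")))

utils::write.table(data.frame(sample_id = rownames(grid$r), grid$r,
                              check.names = FALSE),
                   "results/correlation_grid.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(data.frame(subtype = rownames(av$cell_means),
                              av$cell_means, check.names = FALSE),
                   "results/correlation_subtype_means.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# mean |log2 FC| of EMT-up genes shared with any subtype signature
induced <- names(man$inducers)[man$inducers != "control"]
sig_emt <- derive_group_signature(st$expr_inducers, induced,
                                  induced_controls, tau = 1, name = "EMT")
sub_up <- unique(unlist(lapply(unique(labels), function(s)
  derive_group_signature(st$expr_tumor, names(labels)[labels == s], normal,
                         tau = 1, name = s)$up)))
shared_up <- intersect(sig_emt$up, sub_up)
if (length(shared_up) > 0) {
  summ <- mean_absfc_summary(fc_samples, shared_up, labels)
  cat(sprintf("\nmean log2 FC of the %d EMT-up genes shared with subtype signatures:\n",
              length(shared_up)))
  print(summ, row.names = FALSE, digits = 3)
  utils::write.table(summ, "results/mean_absfc_up.tsv", sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
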