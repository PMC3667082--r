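#!/usr/bin/env Rscript
# Build the four overlap-table analogues on the default synthetic study:
# EMT vs overall tumor signature, EMT vs per-subtype signatures, EMT vs
# the per-pair sorted signatures, and the subtype x sorted-signature grid.
# All tests run on the harmonized gene universe of each signature pair.

library(gbmsig)

dir.create("results", showWarnings = FALSE)

st <- generate_study(synthetic_config(seed = 1))
man <- st$manifests
normal <- names(man$tumor)[man$tumor == "normal"]
tumor <- names(man$tumor)[man$tumor != "normal"]
labels <- man$tumor[tumor]
induced <- names(man$inducers)[man$inducers != "control"]
controls <- names(man$inducers)[man$inducers == "control"]

sig_gbm <- derive_group_signature(st$expr_tumor, tumor, normal, tau = 1,
                                  name = "GBM")
sub_sigs <- lapply(unique(labels), function(s)
  derive_group_signature(st$expr_tumor, names(labels)[labels == s], normal,
                         tau = 1, name = s))
sig_emt <- derive_group_signature(st$expr_inducers, induced, controls,
                                  tau = 1, name = "EMT")
paired <- derive_paired_signature(st$expr_pairs, man$pairs, tau = 1,
                                  min_support = 2, name = "CD133")

tables <- list(
  emt_vs_gbm = as.data.frame(compare_signatures(sig_emt, sig_gbm)),
  emt_vs_subtypes = batch_overlap_table(list(sig_emt), sub_sigs),
  emt_vs_pairs = batch_overlap_table(list(sig_emt), paired$per_pair),
  subtypes_vs_cd133 = batch_overlap_table(sub_sigs,
                                          c(paired$per_pair,
                                            list(paired$consensus))))

for (nm in names(tables)) {
  write_overlap_report(tables[[nm]],
                       file.path("results", paste0("overlap_", nm, ".tsv")))
}

cat("EMT vs overall tumor signature:\n")
print(tables$emt_vs_gbm[, c("pairing", "n_a", "n_b", "overlap", "expected",
                            "p_value", "direction", "significant")],
      row.names = FALSE, digits = 3)
if (all(tables$emt_vs_gbm$n_b == 0)) {
  cat(strwrap(paste("note: the pooled tumor-vs-normal signature is empty at",
                    "the two-fold threshold because planted effects are",
                    "subtype-private (each shift is diluted 4:1 in the",
                    "pooled mean); the per-subtype tables below carry the",
                    "signal"), width = 78), sep = "\n")
}

cat("\nEMT vs per-subtype signatures (same-direction rows):\n")
sub_tab <- tables$emt_vs_subtypes
print(sub_tab[sub_tab$pairing %in% c("up_up", "down_down"),
              c("sig_b", "pairing", "n_a", "n_b", "overlap", "expected",
                "p_value", "direction")],
      row.names = FALSE, digits = 3)

cat("\nmesenchymal-like subtype vs sorted consensus (direction structure):\n")
cons <- tables$subtypes_vs_cd133
cons <- cons[cons$sig_b == "CD133" & cons$sig_a == "mesenchymal", ]
print(cons[, c("pairing", "overlap", "expected", "p_value", "direction")],
      row.names = FALSE, digits = 3)
cat("\nfour tables written under results/\n")
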