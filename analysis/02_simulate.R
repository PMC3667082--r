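#!/usr/bin/env Rscript
# Generate the default synthetic study and write it out in the package's
# text formats.  All downstream analysis scripts regenerate the same study
# from the same seed, so they can be run independently of this one; the
# files written here are for inspection and external reuse.

library(gbmsig)

cfg <- synthetic_config(seed = 1)
study <- generate_study(cfg)
print(study)

write_study(study, "results/study")
cat("study written to results/study/ (matrices, manifests, truth.json)\n")

tr <- study$truth
cat(sprintf("planted core signature: %d up / %d down of %d genes\n",
            length(tr$core_signature$up), length(tr$core_signature$down),
            cfg$n_genes))
cat(sprintf("planted sorted signature: %d up / %d down (anti-core fraction %.2f)\n",
            length(tr$sorted_signature$up), length(tr$sorted_signature$down),
            cfg$anti_fraction))
for (s in names(tr$subtype_signatures)) {
  sig <- tr$subtype_signatures[[s]]
  cat(sprintf("subtype %-12s: %d up / %d down markers\n",
              s, length(sig$up), length(sig$down)))
}
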