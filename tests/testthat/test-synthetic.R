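test_that("study generation is deterministic in the seed", {
  s1 <- generate_study(small_config(seed = 31))
  s2 <- generate_study(small_config(seed = 31))
  expect_identical(s1$expr_tumor, s2$expr_tumor)
  expect_identical(s1$expr_inducers, s2$expr_inducers)
  expect_identical(s1$expr_pairs, s2$expr_pairs)
  expect_identical(s1$truth$plan, s2$truth$plan)
  s3 <- generate_study(small_config(seed = 32))
  expect_false(identical(s1$expr_tumor, s3$expr_tumor))
})

test_that("planted set sizes follow the configuration", {
  cfg <- small_config(seed = 2)
  st <- generate_study(cfg)
  tr <- st$truth
  expect_length(c(tr$core_signature$up, tr$core_signature$down),
                cfg$core_signature_size)
  for (s in names(cfg$samples_per_subtype)) {
    sig <- tr$subtype_signatures[[s]]
    expect_length(c(sig$up, sig$down), cfg$markers_per_subtype)
  }
  expect_equal(sum(st$manifests$tumor == "normal"), cfg$n_normal)
  expect_equal(ncol(st$expr_pairs), 2 * cfg$n_pairs)
  # marker sets are disjoint across subtypes apart from the planted
  # core overlap routed to the first subtype
  other <- unlist(lapply(tr$subtype_signatures[-1],
                         function(s) c(s$up, s$down)))
  expect_length(intersect(c(tr$subtype_signatures[[1]]$up,
                            tr$subtype_signatures[[1]]$down), other), 0)
  expect_error(generate_study(small_config(seed = 1, n_genes = 150)),
               "exceed n_genes")
})

test_that("no planted effect plus tiny noise yields empty signatures", {
  st <- generate_study(small_config(seed = 3, effect_size = 1e-9,
                                    noise_sd = 1e-6))
  man <- st$manifests
  normal <- names(man$tumor)[man$tumor == "normal"]
  tumor <- names(man$tumor)[man$tumor != "normal"]
  sig <- derive_group_signature(st$expr_tumor, tumor, normal, tau = 1)
  expect_length(sig$up, 0)
  expect_length(sig$down, 0)
})

test_that("planted anti-correlation surfaces in profiles and overlap tests", {
  st <- generate_study(small_config(seed = 13))
  man <- st$manifests
  controls <- names(man$inducers)[man$inducers == "control"]
  # inducer-core FC profile vs positive-pair FC profile: negative r
  ind1 <- names(man$inducers)[man$inducers == "inducer1"]
  fc_ind <- rowMeans(st$expr_inducers[, ind1]) -
    rowMeans(st$expr_inducers[, controls])
  fc_pair <- st$expr_pairs[, man$pairs$pos[1]] -
    st$expr_pairs[, man$pairs$neg[1]]
  expect_lt(cor(fc_ind, fc_pair), 0)

  # planted core vs sorted signature: opposite-direction enrichment
  tr <- st$truth
  cmp <- compare_signatures(tr$core_signature, tr$sorted_signature)
  expect_equal(cmp$up_down$direction, "enriched")
  expect_equal(cmp$down_up$direction, "enriched")
  expect_true(cmp$up_down$significant)
  expect_equal(cmp$up_up$overlap, 0)
  expect_equal(cmp$down_down$overlap, 0)
})

test_that("marker recovery improves with the planted effect size", {
  sens_at <- function(delta) {
    st <- generate_study(small_config(seed = 41, effect_size = delta,
                                      noise_sd = 0.5))
    labels <- st$manifests$tumor[st$manifests$tumor != "normal"]
    expr <- st$expr_tumor[, names(labels)]
    mean(vapply(names(st$truth$subtype_signatures), function(s) {
      sig <- derive_subtype_vs_rest_signature(expr, labels, s, tau = 1)
      tr <- st$truth$subtype_signatures[[s]]
      (length(intersect(sig$up, tr$up)) +
         length(intersect(sig$down, tr$down))) /
        (length(tr$up) + length(tr$down))
    }, numeric(1)))
  }
  sens <- vapply(c(0.5, 1, 2), sens_at, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], 0.95)
})

test_that("ground truth serializes to JSON and round-trips", {
  st <- generate_study(small_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  truth_report(st, path)
  back <- jsonlite::fromJSON(readLines(path))
  expect_setequal(back$core_signature$up, st$truth$core_signature$up)
  expect_equal(back$config$n_genes, 800)
  expect_equal(length(back$subtype_labels),
               length(st$truth$subtype_labels))
})

test_that("a study writes and re-reads through the text formats", {
  st <- generate_study(small_config(seed = 19))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_expression_table(file.path(dir, "expr_tumor.tsv"))
  expect_equal(back, st$expr_tumor, tolerance = 1e-12)
  man <- read_sample_manifest(file.path(dir, "manifest_tumor.tsv"))
  expect_identical(man, st$manifests$tumor)
})
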