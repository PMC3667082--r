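test_that("gene_signature enforces disjointness and containment", {
  u <- letters[1:10]
  s <- gene_signature("s", up = c("a", "b"), down = c("c"), universe = u)
  expect_s3_class(s, "gene_signature")
  expect_error(gene_signature("s", up = "a", down = "a", universe = u),
               "disjoint")
  expect_error(gene_signature("s", up = "z", down = "c", universe = u),
               "universe")
  expect_error(gene_signature("s", up = "a", down = "c", universe = u,
                              threshold_log2 = 0), "positive")
})

test_that("derive_group_signature thresholds mean log2 differences inclusively", {
  m <- matrix(c(6, 6, 5, 5,    # gUp: group mean 6, ref mean 5 -> boundary up
                4, 4, 5.5, 5.5,  # gDn: -1.5 -> down
                5, 5, 5, 5),   # gNull
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gUp", "gDn", "gNull"),
                              c("t1", "t2", "n1", "n2")))
  sig <- derive_group_signature(m, c("t1", "t2"), c("n1", "n2"), tau = 1)
  expect_equal(sig$up, "gUp")     # boundary |FC| == tau is included
  expect_equal(sig$down, "gDn")
  expect_equal(sig$universe, sort(rownames(m)))

  # identical groups give an empty signature
  sig0 <- derive_group_signature(m, c("t1", "n1"), c("t2", "n2"), tau = 1)
  expect_length(sig0$up, 0)
  expect_length(sig0$down, 0)

  expect_error(derive_group_signature(m, c("t1", "t2"), c("t2", "n1")),
               "overlap")
  expect_error(derive_group_signature(m, character(), c("n1")), "empty")
})

test_that("group signatures recover planted effects and match a mean oracle", {
  set.seed(11)
  n_genes <- 400
  m <- random_expr(n_genes, 40, seed = 11, sd = 0)  # flat baseline
  noise <- matrix(rnorm(length(m), 0, 0.2), nrow = n_genes)
  planted_up <- rownames(m)[1:50]
  group <- colnames(m)[1:20]; ref <- colnames(m)[21:40]
  m[planted_up, group] <- m[planted_up, group] + 2
  m <- m + noise
  sig <- derive_group_signature(m, group, ref, tau = 1)
  expect_setequal(sig$up, planted_up)
  expect_length(sig$down, 0)

  # oracle: direct mean arithmetic
  fc <- rowMeans(m[, group]) - rowMeans(m[, ref])
  expect_setequal(sig$up, names(fc)[fc >= 1])
})

test_that("group signatures are antisymmetric and monotone in tau", {
  m <- random_expr(200, 12, seed = 3)
  a <- colnames(m)[1:6]; b <- colnames(m)[7:12]
  sab <- derive_group_signature(m, a, b, tau = 0.5)
  sba <- derive_group_signature(m, b, a, tau = 0.5)
  expect_equal(sab$up, sba$down)
  expect_equal(sab$down, sba$up)

  for (tau_hi in c(0.8, 1.2)) {
    hi <- derive_group_signature(m, a, b, tau = tau_hi)
    expect_true(all(hi$up %in% sab$up))
    expect_true(all(hi$down %in% sab$down))
  }

  # invariance to sample and gene order
  perm <- sample(ncol(m)); gperm <- sample(nrow(m))
  sp <- derive_group_signature(m[gperm, perm], a, b, tau = 0.5)
  expect_equal(sp$up, sab$up)
  expect_equal(sp$down, sab$down)
})

test_that("subtype-vs-rest signatures separate planted subtypes", {
  # one subtype shifted +2 on one gene: in its up set, in the other's down
  m <- matrix(5, nrow = 2, ncol = 6,
              dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:6)))
  labels <- setNames(rep(c("x", "y"), each = 3), colnames(m))
  m["gA", labels == "x"] <- 7
  sx <- derive_subtype_vs_rest_signature(m, labels, "x", tau = 1)
  sy <- derive_subtype_vs_rest_signature(m, labels, "y", tau = 1)
  expect_equal(sx$up, "gA")
  expect_equal(sy$down, "gA")
  expect_length(sx$down, 0)

  expect_error(derive_subtype_vs_rest_signature(m, labels, "z"), "absent")
  expect_error(derive_subtype_vs_rest_signature(
    m, setNames(rep("x", 6), colnames(m)), "x"), "two subtype")
})

test_that("subtype-vs-rest recovers planted markers on a synthetic study", {
  st <- generate_study(small_config(seed = 5))
  labels <- st$manifests$tumor[st$manifests$tumor != "normal"]
  expr <- st$expr_tumor[, names(labels)]
  for (s in names(st$truth$subtype_signatures)) {
    sig <- derive_subtype_vs_rest_signature(expr, labels, s, tau = 1)
    truth <- st$truth$subtype_signatures[[s]]
    # oracle: direct group-mean arithmetic on the generator's ground truth
    inside <- names(labels)[labels == s]
    outside <- names(labels)[labels != s]
    fc <- rowMeans(expr[, inside]) - rowMeans(expr[, outside])
    expect_setequal(sig$up, names(fc)[fc >= 1])
    expect_true(length(intersect(sig$up, truth$up)) / length(truth$up) > 0.9)
    expect_true(length(intersect(sig$down, truth$down)) /
                  length(truth$down) > 0.9)
  }
})

test_that("paired signatures apply the per-pair rule and consensus support", {
  genes <- c("gAll", "gOne", "gTwo", "gConflict", "gNone")
  n_pairs <- 4
  m <- matrix(8, nrow = 5, ncol = 2 * n_pairs,
              dimnames = list(genes,
                              paste0(rep(paste0("p", 1:4), each = 2),
                                     c("_pos", "_neg"))))
  pos <- grep("_pos$", colnames(m), value = TRUE)
  m["gAll", pos] <- 10                 # up in all 4 pairs
  m["gOne", pos[1]] <- 10              # up in 1 pair only
  m["gTwo", pos[1:2]] <- 10            # up in exactly 2 pairs
  m["gConflict", pos[1:2]] <- 10       # up in 2 ...
  m["gConflict", pos[3:4]] <- 6        # ... and down in 2
  pairs <- data.frame(pos = pos, neg = sub("_pos", "_neg", pos))
  res <- derive_paired_signature(m, pairs, tau = 1, min_support = 2)
  expect_length(res$per_pair, 4)
  expect_setequal(res$per_pair[[1]]$up, c("gAll", "gOne", "gTwo", "gConflict"))
  expect_true("gAll" %in% res$consensus$up)
  expect_true("gTwo" %in% res$consensus$up)     # at least two of four
  expect_false("gOne" %in% res$consensus$up)    # support 1 < 2
  expect_equal(res$conflicts, "gConflict")
  expect_false("gConflict" %in% c(res$consensus$up, res$consensus$down))

  expect_error(derive_paired_signature(
    m, data.frame(pos = pos[1], neg = pos[1]), min_support = 1),
    "same sample")
  expect_error(derive_paired_signature(m, pairs, min_support = 5),
               "min_support")
})

test_that("per_sample_log2fc equals the element-wise oracle", {
  m <- random_expr(20, 8, seed = 9)
  ref <- colnames(m)[1:3]
  fc <- per_sample_log2fc(m, ref)
  expect_equal(colnames(fc), colnames(m)[4:8])
  for (g in rownames(m)) {
    for (s in colnames(fc)) {
      expect_equal(fc[g, s], m[g, s] - mean(m[g, ref]))
    }
  }
  # a sample equal to the reference mean gives a zero column
  m2 <- cbind(m, probe = rowMeans(m[, ref]))
  colnames(m2)[ncol(m2)] <- "zcheck"
  fc2 <- per_sample_log2fc(m2, ref, samples = "zcheck")
  expect_true(all(abs(fc2) < 1e-12))
  # single reference sample: plain difference
  fc1 <- per_sample_log2fc(m, ref[1], samples = colnames(m)[4])
  expect_equal(fc1[, 1], m[, 4] - m[, ref[1]])
  expect_error(per_sample_log2fc(m, "nope"), "not in matrix")
})

test_that("signature files and JSON round-trip", {
  u <- sprintf("g%02d", 1:30)
  sig <- gene_signature("demo", up = u[1:5], down = u[6:12], universe = u,
                        threshold_log2 = 0.5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back[c("name", "up", "down", "universe", "threshold_log2")],
               sig[c("name", "up", "down", "universe", "threshold_log2")])

  js <- jsonlite::fromJSON(signature_to_json(sig))
  expect_equal(js$n_up, 5)
  expect_equal(js$n_universe, 30)
  expect_setequal(js$down, sig$down)
})
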