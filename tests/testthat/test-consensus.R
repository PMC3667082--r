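test_that("mad_filter keeps exactly the genes a direct MAD loop keeps", {
  m <- rbind(const = rep(5, 5), ramp = 1:5)
  colnames(m) <- paste0("s", 1:5)
  out <- mad_filter(m, 0.5)
  expect_equal(rownames(out), "ramp")   # MAD(1..5) = 1, constant row = 0

  m2 <- random_expr(80, 15, seed = 12, sd = 0.6)
  out2 <- mad_filter(m2, 0.4)
  keep_oracle <- apply(m2, 1, function(r) median(abs(r - median(r))) >= 0.4)
  expect_equal(rownames(out2), rownames(m2)[keep_oracle])
  expect_error(mad_filter(m2, 100), "below the MAD threshold")
})

test_that("zscore_rows standardizes to population moments and is idempotent", {
  m <- rbind(a = c(0, 2), b = c(1, 5))
  colnames(m) <- c("s1", "s2")
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 1))   # population sd of (0,2) is 1

  m2 <- random_expr(30, 12, seed = 2)
  z2 <- zscore_rows(m2)
  expect_true(all(abs(rowMeans(z2)) < 1e-12))
  expect_true(all(abs(rowMeans(z2^2) - 1) < 1e-12))
  expect_equal(zscore_rows(z2), z2, tolerance = 1e-12)

  m3 <- rbind(flat = rep(3, 4), ok = 1:4)
  colnames(m3) <- paste0("s", 1:4)
  expect_error(zscore_rows(m3), "flat")
})

test_that("quality_factor takes its analytic values on canonical matrices", {
  binary <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1))
  expect_equal(quality_factor(binary), 1)
  expect_equal(quality_factor(matrix(0.5, 4, 4)), 0)
  half <- matrix(0.75, 4, 4); diag(half) <- 1
  expect_equal(quality_factor(half), 0.5)
  expect_error(quality_factor(matrix(1.5, 2, 2)), "\\[0, 1\\]")
  # invariant under simultaneous row/column permutation
  set.seed(3)
  cm <- matrix(runif(49), 7, 7); cm <- (cm + t(cm)) / 2; diag(cm) <- 1
  perm <- sample(7)
  expect_equal(quality_factor(cm[perm, perm]), quality_factor(cm))
})

test_that("consensus k-means recovers two well-separated blobs exactly", {
  set.seed(10)
  n_per <- 20
  centers <- c(-5, 5)
  m <- vapply(seq_len(2 * n_per), function(i) {
    rnorm(30, centers[(i - 1) %/% n_per + 1], 0.5)
  }, numeric(30))
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:(2 * n_per)))
  truth <- rep(1:2, each = n_per)
  res <- consensus_kmeans(m, k = 2, n_resamples = 30, seed = 99,
                          kmeans_restarts = 3)
  expect_s3_class(res, "consensus_result")
  expect_equal(label_agreement(res$labels, truth), 1)
  expect_equal(res$quality_factor, 1)   # noiseless planted structure
  # consensus is symmetric with entries in [0, 1] and unit diagonal
  expect_equal(res$consensus, t(res$consensus))
  expect_true(all(res$consensus >= 0 & res$consensus <= 1))
  expect_true(all(diag(res$consensus) == 1))
})

test_that("consensus clustering is reproducible and degenerates sensibly", {
  m <- random_expr(40, 12, seed = 5)
  r1 <- consensus_kmeans(m, 3, n_resamples = 25, seed = 7, kmeans_restarts = 2)
  r2 <- consensus_kmeans(m, 3, n_resamples = 25, seed = 7, kmeans_restarts = 2)
  expect_identical(r1$consensus, r2$consensus)
  expect_identical(r1$labels, r2$labels)
  r3 <- consensus_kmeans(m, 3, n_resamples = 25, seed = 8, kmeans_restarts = 2)
  expect_false(identical(r1$consensus, r3$consensus))

  # k = 1: all-ones consensus, QF 1
  r4 <- consensus_kmeans(m, 1, n_resamples = 5, seed = 1)
  expect_true(all(r4$consensus == 1))
  expect_equal(r4$quality_factor, 1)
  expect_error(consensus_kmeans(m, 13, n_resamples = 5, seed = 1), "k must")
})

test_that("select_k picks the planted number of blobs by largest QF drop", {
  set.seed(14)
  n_per <- 15
  m <- vapply(seq_len(2 * n_per), function(i) {
    rnorm(25, c(-4, 4)[(i - 1) %/% n_per + 1], 0.5)
  }, numeric(25))
  dimnames(m) <- list(sprintf("g%02d", 1:25), sprintf("s%02d", 1:(2 * n_per)))
  sel <- select_k(m, k_range = 2:5, n_resamples = 30, seed = 42,
                  kmeans_restarts = 3)
  expect_equal(sel$selected_k, 2)
  expect_equal(sel$curve$quality_factor[1], 1)
  expect_error(select_k(m, integer()), "k_range")
})

test_that("label_agreement is permutation-invariant", {
  truth <- rep(1:3, each = 4)
  relabeled <- c(3, 1, 2)[truth]
  expect_equal(label_agreement(relabeled, truth), 1)
  flipped <- truth; flipped[1] <- 2
  expect_equal(label_agreement(c(3, 1, 2)[flipped], truth), 11 / 12)
  named <- setNames(truth, paste0("s", 1:12))
  shuffled <- sample(named)
  expect_equal(label_agreement(shuffled, named), 1)
})

test_that("confusion_match assigns clusters to references by up-set overlap", {
  u <- sprintf("g%03d", 1:300)
  mk <- function(nm, idx) gene_signature(nm, up = u[idx],
                                         down = character(), universe = u)
  refs <- list(mk("alpha", 1:50), mk("beta", 51:100), mk("gamma", 101:150))
  # clusters reuse the reference up sets with mild contamination
  clus <- list(mk("c1", c(51:95, 1:5)), mk("c2", c(101:140, 6:10)),
               mk("c3", c(1:45, 141:145)))
  cm <- confusion_match(clus, refs)
  expect_false(cm$uninformative)
  got <- setNames(cm$matching$reference, cm$matching$cluster)
  expect_equal(got[["c1"]], "beta")
  expect_equal(got[["c2"]], "gamma")
  expect_equal(got[["c3"]], "alpha")
  expect_equal(cm$counts["c1", "beta"], 45L)

  # identical lists give a diagonal-dominant grid with identity matching
  cm2 <- confusion_match(refs, refs)
  expect_true(all(diag(cm2$counts) == 50L))
  expect_equal(setNames(cm2$matching$reference, cm2$matching$cluster),
               c(alpha = "alpha", beta = "beta", gamma = "gamma"))

  # disjoint signatures: all-zero grid flagged uninformative
  other <- list(mk("d1", 201:250))
  cm3 <- confusion_match(other, refs)
  expect_true(cm3$uninformative)
  expect_equal(nrow(cm3$matching), 0)
})
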