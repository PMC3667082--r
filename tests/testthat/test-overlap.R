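test_that("tsfet reproduces published overlap rows from list sizes alone", {
  # EMT_up(78) vs GBM_up(1386) on the 11296-gene background
  bg <- sprintf("g%05d", 1:11296)
  a_genes <- c(bg[1:78], sprintf("x%03d", 1:5))   # 78 on background + 5 off
  b_genes <- bg[c(1:34, 2000:3351)]               # 1386, overlapping 34
  res <- tsfet(a_genes, b_genes, bg)
  expect_equal(res$n_a, 78)
  expect_equal(res$n_b, 1386)
  expect_equal(res$overlap, 34)
  expect_equal(round(res$expected, 2), 9.57)
  expect_equal(signif(res$p_value, 3), 4.53e-12)
  expect_equal(res$direction, "enriched")
  expect_true(res$significant)
  expect_equal(sum(res$counts_2x2), res$n_background)

  # EMT_down(129) vs GBM_up(1386): depleted
  a2 <- bg[c(1:8, 5000:5120)]                     # 129, overlapping 8
  res2 <- tsfet(a2, b_genes, bg)
  expect_equal(round(res2$expected, 2), 15.83)
  expect_equal(signif(res2$p_value, 3), 3.07e-2)
  expect_equal(res2$direction, "depleted")
})

test_that("tsfet handles the degenerate empty list", {
  bg <- letters[1:20]
  res <- tsfet(character(), bg[1:8], bg)
  expect_equal(res$overlap, 0)
  expect_equal(res$expected, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")
  expect_false(res$significant)
  expect_error(tsfet(letters[1:3], letters[1:3], character()), "non-empty")
})

test_that("two-sided p matches explicit enumeration on a small table", {
  # N=20, n_a=5, n_b=8, a=4
  p_pkg <- fisher_overlap_p(4, 5, 8, 20)
  p_ref <- enum_two_sided_p(4, 5, 8, 20)
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("overlap p-values are symmetric and complement-invariant", {
  set.seed(21)
  bg <- sprintf("g%03d", 1:120)
  for (i in 1:20) {
    la <- sample(bg, sample(0:60, 1))
    lb <- sample(bg, sample(0:60, 1))
    p_ab <- tsfet(la, lb, bg)$p_value
    expect_equal(tsfet(lb, la, bg)$p_value, p_ab, tolerance = 1e-12)
    expect_equal(tsfet(setdiff(bg, la), setdiff(bg, lb), bg)$p_value, p_ab,
                 tolerance = 1e-9)
  }
})

test_that("p never increases as the overlap moves away from its expectation", {
  for (N in c(17, 36, 55)) {
    for (n_a in c(3, 9, N %/% 2)) {
      for (n_b in c(5, 11, N %/% 3)) {
        k_min <- max(0, n_a + n_b - N); k_max <- min(n_a, n_b)
        ks <- k_min:k_max
        p <- fisher_overlap_p(ks, n_a, n_b, N)
        E <- n_a * n_b / N
        above <- ks >= E
        expect_true(all(diff(p[above]) <= 1e-12))      # further above E
        expect_true(all(diff(p[!above]) >= -1e-12))    # approaching E
      }
    }
  }
})

test_that("compare_signatures reports all four pairings on one background", {
  u <- sprintf("g%04d", 1:1000)
  s1 <- gene_signature("self", up = u[1:100], down = u[101:150], universe = u)
  cmp <- compare_signatures(s1, s1)
  expect_equal(cmp$n_background, 1000)
  expect_equal(cmp$up_up$overlap, 100)
  expect_equal(cmp$up_up$direction, "enriched")
  expect_true(cmp$up_up$significant)
  expect_equal(cmp$up_down$overlap, 0)

  # expected overlaps follow the product formula on random signatures
  set.seed(4)
  u2 <- sprintf("h%03d", 1:500)
  mk <- function(nm) {
    picks <- sample(u2, 120)
    gene_signature(nm, up = picks[1:60], down = picks[61:120], universe = u2)
  }
  a <- mk("a"); b <- mk("b")
  cmp2 <- compare_signatures(a, b)
  for (cell in c("up_up", "down_down", "up_down", "down_up")) {
    r <- cmp2[[cell]]
    expect_equal(r$expected, r$n_a * r$n_b / 500)
    expect_equal(r$n_background, 500)
  }
  df <- as.data.frame(cmp2)
  expect_equal(nrow(df), 4)
  expect_equal(df$pairing, c("up_up", "down_down", "up_down", "down_up"))
})

test_that("batch_overlap_table equals cell-by-cell comparisons", {
  set.seed(8)
  u <- sprintf("g%03d", 1:400)
  mk <- function(nm, n) {
    picks <- sample(u, n)
    gene_signature(nm, up = picks[seq_len(n %/% 2)],
                   down = picks[(n %/% 2 + 1):n], universe = u)
  }
  subs <- lapply(1:4, function(i) mk(paste0("sub", i), 60))
  cds <- lapply(1:2, function(i) mk(paste0("cd", i), 40))
  grid <- batch_overlap_table(subs, cds)
  expect_equal(nrow(grid), 4 * 2 * 4)
  for (r in sample(nrow(grid), 6)) {
    row <- grid[r, ]
    sa <- subs[[match(row$sig_a, vapply(subs, `[[`, "", "name"))]]
    sb <- cds[[match(row$sig_b, vapply(cds, `[[`, "", "name"))]]
    cell <- compare_signatures(sa, sb)[[row$pairing]]
    expect_equal(row$p_value, cell$p_value)
    expect_equal(row$overlap, cell$overlap)
  }
  one <- batch_overlap_table(subs[1], cds[1], pairings = "up_up")
  direct <- compare_signatures(subs[[1]], cds[[1]])$up_up
  expect_equal(nrow(one), 1)
  expect_equal(one$p_value, direct$p_value)
})

test_that("overlap reports export to TSV and JSON", {
  u <- sprintf("g%03d", 1:100)
  s <- gene_signature("s", up = u[1:10], down = u[11:20], universe = u)
  df <- as.data.frame(compare_signatures(s, s))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_overlap_report(df, tsv)
  write_overlap_report(df, jsn)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 4)
  expect_equal(jsonlite::fromJSON(readLines(jsn))$overlap, df$overlap)
})
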