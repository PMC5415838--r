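test_that("normalization to reads per million applies the 0.01 floor", {
  expect_equal(normalize_expression(5935963, 5935963), 1e6)
  expect_equal(normalize_expression(0, 5935963), 0.01)
  expect_equal(normalize_expression(7, 5935963), 1.1793, tolerance = 1e-4)
  expect_error(normalize_expression(5, 0), "clean_total")
  expect_error(normalize_expression(-1, 10), "negative")
})

test_that("log2 fold changes reproduce floored-NE arithmetic", {
  # a zero count against 7 reads recovers the published 6.88 via the floor
  expect_equal(log2_fold_change(0, 7, 5871055, 5935963), 6.88,
               tolerance = 0.005)
  expect_equal(log2_fold_change(16887, 38687, 5871055, 5922188), 1.18,
               tolerance = 0.005)
  # identity and antisymmetry
  expect_equal(log2_fold_change(10, 10, 1e6, 1e6), 0)
  set.seed(41)
  for (k in 1:5) {
    x <- rpois(1, 200); y <- rpois(1, 500)
    expect_equal(log2_fold_change(x, y, 2e6, 3e6),
                 -log2_fold_change(y, x, 3e6, 2e6))
  }
})

test_that("the exact count mass is normalized and matches direct factorials", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)
  for (x in c(0, 3, 11, 20)) {
    s <- sum(ac_probability(x, 0:3000, 1.3e6, 0.9e6))
    expect_lt(abs(s - 1), 1e-9)
  }
  # independent direct-factorial evaluation for small counts
  set.seed(42)
  for (k in 1:20) {
    x <- sample(0:60, 1); y <- sample(0:60, 1)
    n1 <- sample(5e5:2e6, 1); n2 <- sample(5e5:2e6, 1)
    expect_equal(ac_probability(x, y, n1, n2),
                 oracle_ac_mass(x, y, n1, n2),
                 tolerance = 1e-12)
  }
})

test_that("two-sided p-values are symmetric, bounded and calibrated", {
  # equal counts in equally deep libraries: no evidence of change (the
  # conditional mean is r*(x+1), so the p-value sits just under 1)
  expect_gt(ac_pvalue(120, 120, 1e6, 1e6), 0.9)
  expect_lte(ac_pvalue(120, 120, 1e6, 1e6), 1)
  expect_lt(ac_pvalue(50, 0, 1e6, 1e6), 1e-10)
  set.seed(43)
  for (k in 1:10) {
    x <- rpois(1, 80); y <- rpois(1, 120)
    # the statistic conditions on the first library's count, so swapping
    # the libraries changes the conditioning; the two orientations must
    # nonetheless agree in significance (order of magnitude)
    p <- ac_pvalue(x, y, 2.1e6, 1.7e6)
    q <- ac_pvalue(y, x, 1.7e6, 2.1e6)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_lt(abs(log10(p) - log10(q)), 0.5)
    p1 <- ac_pvalue(x, y, 2e6, 2e6)
    q1 <- ac_pvalue(y, x, 2e6, 2e6)
    expect_lt(abs(log10(p1) - log10(q1)), 0.5)
  }
  # large counts stay finite and significant
  expect_lt(ac_pvalue(1e6, 2e6, 5e6, 5e6), 1e-10)
})

test_that("DE classes follow the ratio > 2 / <= 1/2 legend", {
  expect_equal(classify_de(1, 2.97), "up")
  expect_equal(classify_de(1, 1), "equal")
  expect_equal(classify_de(1, 0.4), "down")
  # boundaries: ratio exactly 2 is equal, exactly 1/2 is down
  expect_equal(classify_de(1, 2), "equal")
  expect_equal(classify_de(1, 0.5), "down")
})

test_that("the DE table is internally consistent", {
  counts <- data.frame(mirna = c("a", "b", "c"),
                       P = c(100, 10, 0), D1 = c(405, 10, 7),
                       stringsAsFactors = FALSE)
  d <- de_table(counts, c(P = 1e6, D1 = 1e6), "P", "D1")
  expect_equal(d$de_class[d$mirna == "a"], "up")
  expect_equal(d$de_class[d$mirna == "b"], "equal")
  expect_equal(d$log2fc[d$mirna == "a"],
               log2_fold_change(100, 405, 1e6, 1e6))
  expect_true(all(d$p_value > 0 & d$p_value <= 1))
  expect_equal(d$log2fc_2dp, round_half_up(d$log2fc, 2))
})

test_that("cluster preparation centers, scales and groups planted blocks", {
  m <- rbind(a = c(100, 100, 100), b = c(100, 100, 100))
  cp <- cluster_prep(m)
  expect_true(all(cp$transformed == 0))
  expect_equal(cp$constant_rows, c(a = 1L, b = 2L))

  # two identical rows merge at height 0
  m2 <- rbind(a = c(10, 20, 40), b = c(10, 20, 40), c = c(40, 20, 10))
  cp2 <- cluster_prep(m2)
  expect_equal(min(cp2$tree$height), 0)

  # a planted two-block matrix splits into its blocks at k = 2
  set.seed(44)
  up <- matrix(rep(c(10, 10, 400), each = 5), nrow = 5) *
    matrix(runif(15, 0.9, 1.1), nrow = 5)
  dn <- matrix(rep(c(400, 400, 10), each = 5), nrow = 5) *
    matrix(runif(15, 0.9, 1.1), nrow = 5)
  mm <- rbind(up, dn)
  rownames(mm) <- paste0("m", 1:10)
  grp <- stats::cutree(cluster_prep(mm)$tree, k = 2)
  expect_equal(length(unique(grp[1:5])), 1)
  expect_equal(length(unique(grp[6:10])), 1)
  expect_true(grp[1] != grp[10])

  expect_error(cluster_prep(matrix(1, 1, 3)), "at least 2")
})

test_that("top-n ranking is stable, tie-broken by name and size-capped", {
  e <- data.frame(mirna = c("b", "a", "c"), ne = c(5, 5, 1),
                  stringsAsFactors = FALSE)
  t1 <- top_n_mirnas(e, 1, "ne")
  expect_equal(t1$mirna, "a")            # tie broken by name
  expect_equal(nrow(top_n_mirnas(e, 10, "ne")), 3)
  perm <- e[c(3, 1, 2), ]
  expect_equal(top_n_mirnas(perm, 2, "ne")$mirna,
               top_n_mirnas(e, 2, "ne")$mirna)
})
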