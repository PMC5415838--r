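rc_rna <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

# build a precursor with an exact number of star mismatches, planted as one
# contiguous block so the flanking helices stay long enough to pair fully
build_precursor <- function(mature, n_mm, loop = "GGGAAACCC") {
  star <- strsplit(rc_rna(mature), "")[[1]]
  L <- length(star)
  if (n_mm > 0) {
    for (k in 9:(8 + n_mm)) {
      partner <- substr(mature, L - k + 1, L - k + 1)
      bad <- switch(partner, A = "A", U = "C", G = "G", C = "C")
      star[k] <- bad
    }
  }
  paste0(mature, loop, paste(star, collapse = ""))
}

test_that("candidate extraction filters, clips and merges windows", {
  set.seed(31)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000,
                                  replace = TRUE), collapse = ""))
  tags <- data.frame(sequence = c("T_MANY", "T_EDGE", "T_MID", "T_LOW"),
                     count = c(50, 50, 50, 2), stringsAsFactors = FALSE)
  aln <- data.frame(
    tag = c("T_MANY", "T_EDGE", "T_MID", "T_LOW"),
    contig = "chr1",
    start = c(500, 40, 1000, 1500),
    end = c(521, 61, 1021, 1521),
    strand = "+",
    n_loci = c(11L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  cand <- extract_candidates(tags, aln, genome)
  # > 10 genome hits: excluded; low support: excluded
  expect_false("T_MANY" %in% cand$tag)
  expect_false("T_LOW" %in% cand$tag)
  # window clipped at the contig edge
  e <- cand[cand$tag == "T_EDGE", ]
  expect_equal(e$win_start, 1L)
  expect_equal(e$tag_start, 40L)
  # mid-contig 22-nt tag: 150 + 22 + 150 window
  m <- cand[cand$tag == "T_MID", ]
  expect_equal(m$win_end - m$win_start + 1L, 322L)
  expect_equal(nchar(m$window), 322L)

  # overlapping windows merge, keeping the highest-count tag
  aln2 <- data.frame(tag = c("T_A", "T_B"), contig = "chr1",
                     start = c(1000, 1040), end = c(1021, 1061),
                     strand = "+", n_loci = 1L, stringsAsFactors = FALSE)
  tags2 <- data.frame(sequence = c("T_A", "T_B"), count = c(10, 90),
                      stringsAsFactors = FALSE)
  cand2 <- extract_candidates(tags2, aln2, genome)
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$tag, "T_B")
})

test_that("the hairpin screen enforces each criterion", {
  set.seed(32)
  hp <- plant_hairpin(22, star_mismatches = 1, loop_length = 9)
  base <- screen_candidate(hp$precursor, hp$mature_start, 22)
  expect_true(base$pass)

  # AU content outside 30-70% fails the AU criterion
  au_mature <- paste0("U", strrep("AU", 8), "GCGCG")   # 22 nt, AU ~ 0.77
  prec <- build_precursor(au_mature, 0)
  s <- screen_candidate(prec, 1, 22)
  expect_false(s$flag_au)
  expect_false(s$pass)

  # the star criterion is a strict "fewer than" bound: a hairpin with m
  # unpaired mature positions fails when the limit is m and passes at m + 1
  gc_mature <- "UGACGGCAUCGGCAUGCCAGUC"
  prec5 <- build_precursor(gc_mature, 5)
  s5 <- mirsat:::screen_hairpin(prec5, 1, 22)
  m <- s5$mismatches
  expect_gte(m, 1)
  expect_true(m < 6)                    # five planted mismatches stay under 6
  at_m <- mirsat:::screen_hairpin(
    prec5, 1, 22, novel_thresholds(max_star_mismatches = m))
  expect_false(at_m$flags[["star"]])
  at_m1 <- mirsat:::screen_hairpin(
    prec5, 1, 22, novel_thresholds(max_star_mismatches = m + 1L))
  expect_true(at_m1$flags[["star"]])

  # short stems cannot reach -20 kcal/mol
  weak <- "GGGCAAAGCCC"
  sw <- screen_candidate(weak, 2, 9)
  expect_false(sw$flag_mfe)
  expect_false(sw$pass)
})

test_that("screen tightening is monotone: a stricter threshold never
           converts fail into pass", {
  set.seed(33)
  strict <- novel_thresholds(mfe_max = -40, mfei_max = -1.2,
                             au_min = 0.4, au_max = 0.6,
                             max_star_mismatches = 3L)
  for (k in 1:5) {
    hp <- plant_hairpin(21, star_mismatches = sample(0:3, 1),
                        loop_length = 10)
    lax <- screen_candidate(hp$precursor, hp$mature_start, 21)
    hard <- screen_candidate(hp$precursor, hp$mature_start, 21,
                             thresholds = strict)
    expect_true(lax$pass >= hard$pass)
  }
})

test_that("dinucleotide shuffling preserves composition", {
  set.seed(34)
  x <- paste(sample(c("A", "C", "G", "U"), 200, replace = TRUE),
             collapse = "")
  y <- shuffle_dinucleotide(x)
  expect_equal(nchar(y), nchar(x))
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  expect_equal(sort(as.vector(dinucs(y))), sort(as.vector(dinucs(x))))
  expect_equal(dinucs(y)[names(dinucs(x))], dinucs(x))
})

test_that("Dicer-consistency uses the locus read-start distribution", {
  set.seed(35)
  hp <- plant_hairpin(22, star_mismatches = 0, loop_length = 9)
  # 90% of reads start at the mature 5' end: consistent
  ok <- screen_candidate(hp$precursor, hp$mature_start, 22,
                         read_starts = c(rep(hp$mature_start, 9),
                                         hp$star_start),
                         read_counts = rep(1, 10))
  expect_true(ok$flag_dicer)
  # scattered starts: inconsistent
  bad <- screen_candidate(hp$precursor, hp$mature_start, 22,
                          read_starts = c(rep(hp$mature_start, 5),
                                          rep(hp$star_start, 5)),
                          read_counts = rep(1, 10))
  expect_false(bad$flag_dicer)
  expect_false(bad$pass)
})
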