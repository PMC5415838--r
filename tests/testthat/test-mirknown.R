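make_ref <- function() {
  # two precursors: mature at a known window inside each
  m1 <- "UGAGGUAGUAGGUUGUAUAGUU"     # 22 nt
  m2 <- "UGGAAUGUAAAGAAGUAUGUAU"     # 22 nt
  loop <- "GGGAAACCC"
  rc <- function(x) paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]),
                          collapse = "")
  mirna_reference(
    mature_name = c("syn-let-7a-5p", "syn-miR-1"),
    mature = c(m1, m2),
    precursor_name = c("syn-let-7a", "syn-mir-1"),
    precursor = c(paste0(m1, loop, rc(m1)), paste0(m2, loop, rc(m2))),
    mature_start = c(1, 1), mature_end = c(22, 22))
}

test_that("reference integrity is validated on construction", {
  expect_error(
    mirna_reference("m", "UUUU", "p", "GGGGGGG", 1, 4),
    "reference-integrity")
  ref <- make_ref()
  expect_s3_class(ref, "mirna_reference")
})

test_that("known-miRNA matching requires a perfect in-window hit", {
  ref <- make_ref()
  m1 <- ref$mature[1]

  hit <- match_known(m1, ref)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mature_name, "syn-let-7a-5p")
  expect_equal(hit$arm, "miR-5p")

  # a single substitution breaks the perfect-match requirement
  mut <- m1
  substr(mut, 9, 9) <- if (substr(m1, 9, 9) == "A") "C" else "A"
  expect_equal(nrow(match_known(mut, ref)), 0)

  # a perfect precursor match far from the mature window does not count
  star_region <- substr(ref$precursor[1], 32, 53)
  expect_equal(nrow(match_known(star_region, ref)), 0)

  # a 1-nt 3' trim stays within the +/-2 shift tolerance
  iso <- substr(m1, 1, 21)
  expect_equal(nrow(match_known(iso, ref)), 1)
})

test_that("known-miRNA tallies count arms, precursors, tags and reads", {
  ref <- make_ref()
  tags <- data.frame(sequence = c(ref$mature[1], ref$mature[2], "ACGU"),
                     L1 = c(10, 0, 3), L2 = c(4, 6, 0),
                     count = c(14, 6, 3), stringsAsFactors = FALSE,
                     check.names = FALSE)
  hits <- match_known(tags$sequence, ref)
  tl <- tally_known(hits, ref, tags, c("L1", "L2"))
  r1 <- tl[tl$library == "L1", ]
  expect_equal(r1[["miR-5p"]], 1)
  expect_equal(r1[["miR"]], 0)       # syn-miR-1 has no reads in L1
  expect_equal(r1$reads, 10)
  r2 <- tl[tl$library == "L2", ]
  expect_equal(r2[["miR"]], 1)
  expect_equal(r2$reads, 10)

  empty <- tally_known(match_known(character(0), ref), ref,
                       tags[0, ], c())
  expect_equal(empty[["pre_miRs"]][empty$library == "reference"], 2)

  ke <- known_expression(hits, tags, c("L1", "L2"))
  expect_equal(ke$L1[ke$mirna == "syn-let-7a-5p"], 10)
  expect_equal(ke$L2[ke$mirna == "syn-miR-1"], 6)
})

test_that("base-edit detection finds exactly-one-mismatch tags", {
  ref <- make_ref()
  m1 <- ref$mature[1]
  ed <- m1
  substr(ed, 9, 9) <- if (substr(m1, 9, 9) == "A") "C" else "A"
  d2 <- ed
  substr(d2, 15, 15) <- if (substr(m1, 15, 15) == "G") "U" else "G"

  res <- detect_base_edits(c(ed, d2), ref, counts = c(7, 1))
  expect_equal(nrow(res$edits), 1)
  expect_equal(res$edits$position, 9)
  expect_equal(res$edits$mature_name, "syn-let-7a-5p")
  expect_equal(res$edits$ref_base, substr(m1, 9, 9))
  expect_equal(res$edits$count, 7)
  expect_equal(res$fraction, 0.5)

  # tie: a tag at distance 1 from two matures goes to the smallest name
  twin_ref <- mirna_reference(
    mature_name = c("syn-miR-9b", "syn-miR-9a"),
    mature = c("UGAGGUAGUAGGUUGUAUAGCA", "UGAGGUAGUAGGUUGUAUAGAU"),
    precursor_name = c("p1", "p2"),
    precursor = c("UGAGGUAGUAGGUUGUAUAGCAGGGAAACCC",
                  "UGAGGUAGUAGGUUGUAUAGAUGGGAAACCC"),
    mature_start = c(1, 1), mature_end = c(22, 22))
  probe <- "UGAGGUAGUAGGUUGUAUAGAA"   # distance 1 to both
  res <- detect_base_edits(probe, twin_ref)
  expect_equal(nrow(res$edits), 1)
  expect_true(res$edits$tie)
  expect_equal(res$edits$mature_name, "syn-miR-9a")
})

test_that("family assignment strips species, arm and variant decorations", {
  expect_equal(assign_family("bta-miR-2284x"), "miR-2284")
  expect_equal(assign_family("bta-let-7a-5p"), "let-7")
  expect_equal(assign_family("bta-miR-133a"), "miR-133")
  expect_equal(assign_family("bta-miR-154-2"), "miR-154")
  expect_equal(assign_family("bta-miR-2331-5p"), "miR-2331")
  expect_equal(assign_family("hsa-miR-21*"), "miR-21")
  expect_equal(assign_family("weird-name"), "unassigned")
  # idempotent: a family name maps to itself
  expect_equal(assign_family(assign_family("bta-miR-2284x")), "miR-2284")
})

test_that("positional nucleotide bias is count-weighted and normalized", {
  pb <- position_bias(rep(strrep("U", 22), 3))
  expect_true(all(pb$fractions[1:22, "U"] == 1))
  expect_true(all(is.na(pb$fractions[23:30, "U"])))

  pb <- position_bias(c("UACGUACGUACGUACGUACGUA", "AACGUACGUACGUACGUACGUA"),
                      counts = c(9, 1))
  expect_equal(unname(pb$fractions[1, "U"]), 0.9)
  expect_equal(sum(pb$fractions[1, ]), 1)
  rs <- rowSums(pb$fractions[1:22, ])
  expect_true(all(abs(rs - 1) < 1e-9))

  # generator forces a 5' U on planted matures: strong first-position U bias
  res <- small_pipeline()
  expect_gte(res$bias$P$u_summary[["pos1_U"]], 0.9)
})

test_that("perfect matches and base-edit candidates are disjoint", {
  res <- small_pipeline()
  expect_length(intersect(res$hits$tag, res$edits$edits$tag), 0)
})
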