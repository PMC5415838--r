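test_that("planted hairpins satisfy their construction contract", {
  set.seed(11)
  hp <- plant_hairpin(mature_length = 22, star_mismatches = 0,
                      loop_length = 8)
  expect_equal(nchar(hp$mature), 22)
  expect_equal(hp$mature_end - hp$mature_start + 1L, 22L)
  # zero star mismatches: the star is the exact reverse complement
  rc <- paste(rev(strsplit(chartr("ACGU", "UGCA", hp$mature), "")[[1]]),
              collapse = "")
  expect_equal(hp$star, rc)
  expect_equal(substr(hp$precursor, hp$mature_start, hp$mature_end),
               hp$mature)

  # closure: every planted hairpin passes the screen it was built against
  for (k in 1:4) {
    h <- plant_hairpin(sample(20:22, 1), star_mismatches = sample(0:3, 1),
                       loop_length = sample(8:12, 1))
    scr <- screen_candidate(h$precursor, h$mature_start, nchar(h$mature))
    expect_true(scr$pass)
  }
  expect_error(plant_hairpin(star_mismatches = 6), "star_mismatches")
})

test_that("genome generation is seeded, counted and placed correctly", {
  cfg <- small_config()
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$precursors$precursor, g2$precursors$precursor)

  # n_known + n_novel precursor rows
  expect_equal(nrow(g1$precursors), 9)
  expect_equal(sum(g1$precursors$kind == "known"), 6)
  expect_equal(sum(g1$precursors$kind == "novel"), 3)

  # features never overlap
  f <- rbind(g1$features[, c("start", "end")],
             g1$precursors[, c("start", "end")])
  f <- unique(f[order(f$start), ])
  expect_true(all(diff(f$start) > (f$end - f$start + 1)[-nrow(f)]))

  # embedded precursors are really in the genome
  for (i in seq_len(nrow(g1$precursors))) {
    p <- g1$precursors[i, ]
    seq_g <- substr(g1$genome[[1]], p$start, p$end)
    expected <- chartr("U", "T", p$precursor)
    if (p$strand == "-") {
      expected <- paste(rev(strsplit(chartr("ACGT", "TGCA", expected),
                                     "")[[1]]), collapse = "")
    }
    expect_equal(seq_g, expected)
  }

  # GC content of a 1e5 genome is within a tight binomial band of the target
  cfg2 <- synthetic_config(seed = 5, genome_length = 100000L)
  g <- make_genome(cfg2)
  gc <- sum(strsplit(g$genome[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 0.02)

  expect_error(make_genome(synthetic_config(genome_length = 5000L)),
               "10x|space")
})

test_that("read simulation conserves counts, honors rates and is seeded", {
  ds <- small_dataset()
  cfg <- ds$config
  for (s in 1:3) {
    st <- ds$stages[[s]]
    expect_equal(nrow(st$reads), cfg$library_sizes[s])
    expect_equal(nrow(st$labels), cfg$library_sizes[s])
  }
  # determinism: regenerating one stage reproduces it byte for byte
  again <- simulate_reads(cfg, ds$truth, 2)
  expect_identical(again$reads, ds$stages$D1$reads)

  # planted fold change is realized in raw label counts (mirna 1, log2fc=2
  # between P and D1 with equal library sizes): ratio within a generous
  # Poisson band around 4
  nm <- ds$truth$precursors$mature_name[1]
  lab_p <- ds$stages$P$labels
  lab_d1 <- ds$stages$D1$labels
  x <- sum(lab_p$source == paste0("miRNA:", nm))
  y <- sum(lab_d1$source == paste0("miRNA:", nm))
  expect_gt(x, 30)
  ratio <- y / x
  sdr <- ratio * sqrt(1 / x + 1 / y)
  expect_lt(abs(ratio - 4), 4 * sdr + 0.3)
  # and the truth table's expected counts encode the planted effect exactly
  ek <- ds$truth$expected_known
  expect_equal(unname(ek[nm, "D1"] / ek[nm, "P"]), 4)

  # referencing a nonexistent miRNA index fails
  bad <- small_config()
  bad$de_spec <- data.frame(mirna = 99L, stage = 2L, log2fc = 1)
  expect_error(make_truth(bad), "nonexistent")
})

test_that("contaminant injection matches configured binomial rates", {
  cfg <- small_config(seed = 202L)
  cfg$contamination_rates[["polyA"]] <- 0.01
  truth <- make_truth(cfg)
  st <- simulate_reads(cfg, truth, 1)
  n <- cfg$library_sizes[1]
  n_polya <- sum(st$labels$category == "polyA")
  sigma <- sqrt(n * 0.01 * 0.99)
  expect_lt(abs(n_polya - n * 0.01), 4 * sigma)
})

test_that("error-free inserts are exact planted subsequences", {
  ds <- small_dataset()
  genome <- ds$truth$genome[[1]]
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                          collapse = "")
  lab <- ds$stages$P$labels
  reads <- ds$stages$P$reads
  clean <- which(lab$category == "clean")
  pick <- sample(clean, 100)
  tr <- trim_adapter3(reads$sequence[pick], ds$config$adapter3)
  expect_true(all(tr$status == "ok"))
  found <- vapply(tr$insert, function(ins) {
    grepl(ins, genome, fixed = TRUE) || grepl(rc(ins), genome, fixed = TRUE)
  }, logical(1))
  expect_true(all(found))
})
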