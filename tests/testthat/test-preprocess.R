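ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("quality filter applies the N and low-quality base rules", {
  q40 <- function(n) strrep(intToUtf8(33 + 40), n)
  mk_qual <- function(scores) intToUtf8(scores + 33, multiple = FALSE)

  # one N fails regardless of quality
  r <- quality_filter("ACGNACGT", q40(8))
  expect_false(r$pass)
  expect_equal(r$reason, "N")

  # exactly 4 bases below Q10 is still acceptable
  r <- quality_filter("ACGTACGT", mk_qual(c(9, 9, 9, 9, 40, 40, 40, 40)))
  expect_true(r$pass)
  # 5 bases below Q10 is not
  r <- quality_filter("ACGTACGTA", mk_qual(c(9, 9, 9, 9, 9, 40, 40, 40, 40)))
  expect_false(r$pass)
  expect_equal(r$reason, "low_quality")

  # 7 bases at Q12 (none below 10) exceeds the 6-base Q13 rule
  r <- quality_filter("ACGTACGTAC", mk_qual(c(rep(12, 7), rep(40, 3))))
  expect_false(r$pass)
  # 6 bases at Q12 passes
  r <- quality_filter("ACGTACGTAC", mk_qual(c(rep(12, 6), rep(40, 4))))
  expect_true(r$pass)

  expect_error(quality_filter("ACGT", "!!!"), "malformed")
})

test_that("3' adapter trimming finds leftmost, partial and absent adapters", {
  insert <- "ACGTACGT"
  read <- paste0(insert, ADAPTER3, "CCCTTTAAACCC")
  tr <- trim_adapter3(read, ADAPTER3)
  expect_equal(tr$status, "ok")
  expect_equal(tr$insert, insert)

  # adapter at position 1: null insert
  tr <- trim_adapter3(paste0(ADAPTER3, "ACGTACGTACGTACGTACGTACGTACGTA"),
                      ADAPTER3)
  expect_equal(tr$status, "insert_null")

  # no adapter at all
  tr <- trim_adapter3(strrep("ACGT", 12), ADAPTER3)
  expect_equal(tr$status, "adaptor3_null")

  # one mismatch in the full adapter is tolerated (1 per 10 nt)
  mut <- ADAPTER3
  substr(mut, 8, 8) <- "A"   # C -> A
  tr <- trim_adapter3(paste0(insert, mut, "GGG"), ADAPTER3)
  expect_equal(tr$status, "ok")
  expect_equal(tr$insert, insert)

  # a terminal 6-nt adapter prefix is enough
  tr <- trim_adapter3(paste0("ACGTACGTACGTACGTACGTAC",
                             substr(ADAPTER3, 1, 6)), ADAPTER3)
  expect_equal(tr$status, "ok")
  expect_equal(nchar(tr$insert), 22)

  expect_error(trim_adapter3("ACGT", ""), "empty adapter")
  expect_error(trim_adapter3("ACGT", "ACG"), "at least 6")
})

test_that("contaminant cascade classifies in fixed priority order", {
  # insert beginning with the 5' adapter (one mismatch) is a 5' contaminant
  a5_like <- substr(ADAPTER5, 1, 20)
  substr(a5_like, 3, 3) <- "A"
  expect_equal(classify_contaminants(a5_like, ADAPTER5),
               "adaptor5_contaminants")

  expect_equal(classify_contaminants(strrep("C", 17), ADAPTER5),
               "smaller_than_18nt")
  expect_equal(classify_contaminants(strrep("A", 22), ADAPTER5), "polyA")
  expect_equal(classify_contaminants(strrep("ACGT", 5), ADAPTER5), "clean")
  expect_equal(classify_contaminants(strrep("ACGT", 10), ADAPTER5),
               "larger_than_30nt")
  # short beats polyA in the cascade
  expect_equal(classify_contaminants(strrep("A", 17), ADAPTER5),
               "smaller_than_18nt")
})

test_that("cleaning summary reproduces the subtraction identity", {
  s <- summarize_cleaning(c(high_quality = 5984373, adaptor3_null = 2916,
                            insert_null = 3115,
                            adaptor5_contaminants = 86464,
                            smaller_than_18nt = 20713, polyA = 110))
  expect_equal(s$count[s$type == "clean_reads"], 5871055)
  expect_equal(s$percent[s$type == "clean_reads"], 98.11)
  expect_equal(s$percent[s$type == "adaptor5_contaminants"], 1.44)

  z <- summarize_cleaning(c(high_quality = 0, adaptor3_null = 0,
                            insert_null = 0, adaptor5_contaminants = 0,
                            smaller_than_18nt = 0, polyA = 0))
  expect_equal(z$count[z$type == "clean_reads"], 0)
  expect_true(all(z$percent == 0))

  expect_error(summarize_cleaning(c(high_quality = 10, adaptor3_null = 20,
                                    insert_null = 0,
                                    adaptor5_contaminants = 0,
                                    smaller_than_18nt = 0, polyA = 0)),
               "negative")
})

test_that("tag collapsing counts, conserves and histograms", {
  s <- strrep("AC", 10)
  t2 <- strrep("GT", 10)
  col <- collapse_tags(list(A = c(s, s, t2), B = c(t2)))
  expect_equal(nrow(col$tags), 2)
  expect_equal(col$tags$count[col$tags$sequence == s], 2)
  expect_equal(col$tags$A[col$tags$sequence == s], 2)
  expect_equal(col$tags$B[col$tags$sequence == s], 0)
  expect_equal(sum(col$histogram$A), 3)
  expect_error(collapse_tags(list(A = "ACGT")), "18")
})

test_that("every read lands in exactly one category matching its label", {
  ds <- small_dataset()
  res <- small_pipeline()
  for (s in c("P", "D1", "D3")) {
    cl <- res$cleaned[[s]]
    expect_false(any(is.na(cl$category)))
    expect_equal(length(cl$category), nrow(ds$stages[[s]]$labels))
    # error_rate = 0: cleaning categories equal truth labels read for read
    expect_equal(cl$category, ds$stages[[s]]$labels$category)
  }
  # clean inserts re-classify as clean (idempotent cascade)
  again <- classify_contaminants(res$cleaned$P$inserts,
                                 ds$config$adapter5)
  expect_true(all(again == "clean"))
  # mode of the length histogram is at 22 nt by construction
  h <- res$histogram
  expect_equal(h$length[which.max(h$P)], 22)
})
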