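# Raw-read cleaning: quality filter, 3' adapter trimming, contaminant
# classification, tag collapsing and the cleaning summary table.

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file (Phred+33).
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # the reader re-wraps its input and warns about dropped (empty) metadata
  # columns; nothing is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality),
             con)
  invisible(path)
}

#' High-quality read filter
#'
#' A read fails if its sequence contains an N, more than 4 bases with quality
#' below 10, or more than 6 bases with quality below 13 (Phred+33).
#'
#' @param sequence character vector of read sequences.
#' @param quality character vector of Phred+33 quality strings.
#' @return data.frame with logical `pass` and `reason`
#'   (`""`/`"N"`/`"low_quality"`).
#' @export
quality_filter <- function(sequence, quality) {
  if (length(sequence) != length(quality) ||
      any(nchar(sequence) != nchar(quality))) {
    stop("quality_filter: malformed record (sequence/quality length mismatch)")
  }
  if (length(sequence) == 0) {
    return(data.frame(pass = logical(), reason = character()))
  }
  seqs <- Biostrings::DNAStringSet(sequence)
  n_count <- Biostrings::letterFrequency(seqs, "N")[, 1]
  qs <- Biostrings::BStringSet(quality)
  below10 <- rawToChar(as.raw(33:42))   # Q < 10
  below13 <- rawToChar(as.raw(33:45))   # Q < 13
  n10 <- Biostrings::letterFrequency(qs, below10)[, 1]
  n13 <- Biostrings::letterFrequency(qs, below13)[, 1]
  pass <- n_count == 0 & n10 <= 4 & n13 <= 6
  reason <- rep("", length(sequence))
  reason[n10 > 4 | n13 > 6] <- "low_quality"
  reason[n_count > 0] <- "N"
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Locate the 3' adapter in reads
#'
#' Finds the leftmost full-adapter occurrence, allowing one mismatch per
#' 10 nt of adapter; reads without a full occurrence are checked for a
#' terminal partial match of at least 6 nt of the adapter prefix at the read
#' end (longest partial wins), with the same 1-per-10-nt mismatch allowance.
#'
#' @param seqs character vector of read sequences.
#' @param adapter 3' adapter sequence (>= 6 nt).
#' @return integer vector of 1-based adapter start positions (`NA` if the
#'   adapter was not found).
#' @export
locate_adapter3 <- function(seqs, adapter) {
  if (is.null(adapter) || !nzchar(adapter)) {
    stop("locate_adapter3: empty adapter (configuration error)")
  }
  alen <- nchar(adapter)
  if (alen < 6) stop("locate_adapter3: adapter must be at least 6 nt")
  n <- length(seqs)
  if (n == 0) return(integer(0))
  subj <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern(adapter, subj, max.mismatch = alen %/% 10)
  st <- Biostrings::startIndex(hits)
  pos <- vapply(st, function(v) if (length(v)) min(v) else NA_integer_,
                integer(1))
  w <- nchar(seqs)
  for (p in seq(alen - 1L, 6L, by = -1L)) {
    todo <- which(is.na(pos) & w >= p)
    if (length(todo) == 0) next
    suf <- Biostrings::subseq(subj[todo], start = w[todo] - p + 1L)
    cnt <- Biostrings::vcountPattern(substr(adapter, 1, p), suf,
                                     max.mismatch = p %/% 10)
    found <- todo[cnt > 0]
    pos[found] <- w[found] - p + 1L
  }
  pos
}

#' Trim the 3' adapter and classify the trimming outcome
#'
#' @param seqs character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @return data.frame with `insert` (bases 5' of the adapter) and `status`:
#'   `"ok"`, `"insert_null"` (adapter at position 1) or `"adaptor3_null"`
#'   (no adapter found).
#' @export
trim_adapter3 <- function(seqs, adapter) {
  pos <- locate_adapter3(seqs, adapter)
  status <- ifelse(is.na(pos), "adaptor3_null",
                   ifelse(pos == 1L, "insert_null", "ok"))
  insert <- ifelse(status == "ok", substr(seqs, 1, pos - 1L), "")
  data.frame(insert = insert, status = status, stringsAsFactors = FALSE)
}

#' Classify trimmed inserts into contaminant categories
#'
#' Checks run in a fixed order so each insert lands in exactly one category:
#' 5' adapter contaminant (insert prefix matches the 5' adapter with at most
#' one mismatch), shorter than `min_len`, polyA (>= 80% A), longer than
#' `max_len`, otherwise clean.
#'
#' @param inserts character vector of trimmed inserts.
#' @param adapter5 5' adapter sequence.
#' @param min_len,max_len retained insert length range (nt).
#' @return character vector of categories: `"clean"`,
#'   `"adaptor5_contaminants"`, `"smaller_than_18nt"`, `"polyA"`,
#'   `"larger_than_30nt"`.
#' @export
classify_contaminants <- function(inserts, adapter5, min_len = 18L,
                                  max_len = 30L) {
  n <- length(inserts)
  if (n == 0) return(character(0))
  cat <- rep("clean", n)
  w <- nchar(inserts)

  is_a5 <- rep(FALSE, n)
  k <- pmin(w, nchar(adapter5))
  for (kk in unique(k[k > 0])) {
    idx <- which(k == kk)
    pre <- Biostrings::DNAStringSet(substr(inserts[idx], 1, kk))
    cnt <- Biostrings::vcountPattern(substr(adapter5, 1, kk), pre,
                                     max.mismatch = 1)
    is_a5[idx] <- cnt > 0
  }
  a_frac <- rep(0, n)
  nz <- which(w > 0)
  if (length(nz)) {
    a_frac[nz] <- Biostrings::letterFrequency(
      Biostrings::DNAStringSet(inserts[nz]), "A")[, 1] / w[nz]
  }
  # fixed cascade: assignments run lowest-priority first so that each later
  # (higher-priority) rule overrides -- net order is 5' contaminant, then
  # short, then polyA, then over-long
  cat[w > max_len] <- "larger_than_30nt"
  cat[a_frac >= 0.8] <- "polyA"
  cat[w < min_len] <- "smaller_than_18nt"
  cat[is_a5] <- "adaptor5_contaminants"
  cat
}

#' Run the full cleaning cascade on one library
#'
#' Applies, in order: the high-quality filter, 3' adapter trimming (null
#' adapter / null insert), then the contaminant cascade (5' contaminant,
#' short, polyA, over-long).  Every read is assigned to exactly one category.
#'
#' @param reads data.frame from [read_fastq()] (or [simulate_reads()]).
#' @param adapter3,adapter5 adapter sequences.
#' @param min_len,max_len retained insert length range.
#' @return list with `category` (per-read), `inserts` (clean inserts),
#'   `counts` (category counts) and `summary` (the cleaning table from
#'   [summarize_cleaning()]).
#' @export
clean_reads <- function(reads, adapter3, adapter5, min_len = 18L,
                        max_len = 30L) {
  qf <- quality_filter(reads$sequence, reads$quality)
  category <- rep(NA_character_, nrow(reads))
  category[!qf$pass] <- "low_quality"
  hq <- which(qf$pass)
  tr <- trim_adapter3(reads$sequence[hq], adapter3)
  category[hq[tr$status == "adaptor3_null"]] <- "adaptor3_null"
  category[hq[tr$status == "insert_null"]] <- "insert_null"
  ok <- which(tr$status == "ok")
  cc <- classify_contaminants(tr$insert[ok], adapter5, min_len, max_len)
  category[hq[ok]] <- cc
  counts <- c(
    total_reads = nrow(reads),
    high_quality = length(hq),
    adaptor3_null = sum(category == "adaptor3_null"),
    insert_null = sum(category == "insert_null"),
    adaptor5_contaminants = sum(category == "adaptor5_contaminants"),
    smaller_than_18nt = sum(category == "smaller_than_18nt"),
    polyA = sum(category == "polyA"),
    larger_than_30nt = sum(category == "larger_than_30nt")
  )
  list(category = category,
       inserts = tr$insert[ok][cc == "clean"],
       counts = counts,
       summary = summarize_cleaning(counts))
}

#' Cleaning summary table
#'
#' Computes the clean-read count by subtracting every removal category from
#' the high-quality count, with percentages of high-quality reads rounded
#' half-up to 2 decimals.  The rare over-long category is only reported when
#' non-zero.
#'
#' @param counts named numeric vector with `high_quality` and the removal
#'   categories (`adaptor3_null`, `insert_null`, `adaptor5_contaminants`,
#'   `smaller_than_18nt`, `polyA`, optionally `larger_than_30nt` and
#'   `total_reads`).
#' @return data.frame with `type`, `count`, `percent`.
#' @examples
#' summarize_cleaning(c(high_quality = 5984373, adaptor3_null = 2916,
#'                      insert_null = 3115, adaptor5_contaminants = 86464,
#'                      smaller_than_18nt = 20713, polyA = 110))
#' @export
summarize_cleaning <- function(counts) {
  counts <- as.list(counts)
  need <- c("high_quality", "adaptor3_null", "insert_null",
            "adaptor5_contaminants", "smaller_than_18nt", "polyA")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop("summarize_cleaning: missing counts: ", paste(missing, collapse = ", "))
  }
  if (any(unlist(counts) < 0)) stop("summarize_cleaning: negative counts")
  hq <- counts$high_quality
  removals <- c("adaptor3_null", "insert_null", "adaptor5_contaminants",
                "smaller_than_18nt", "polyA")
  long <- counts[["larger_than_30nt"]]
  if (!is.null(long) && long > 0) removals <- c(removals, "larger_than_30nt")
  clean <- hq - sum(unlist(counts[removals]))
  if (clean < 0) stop("summarize_cleaning: implied clean_reads is negative")
  rows <- c(if (!is.null(counts$total_reads)) "total_reads",
            "high_quality", removals)
  vals <- unlist(counts[rows])
  out <- data.frame(type = c(rows, "clean_reads"),
                    count = c(vals, clean),
                    stringsAsFactors = FALSE)
  pct <- if (hq > 0) round_half_up(out$count / hq * 100, 2) else
    rep(0, nrow(out))
  pct[out$type == "total_reads"] <- NA
  out$percent <- pct
  rownames(out) <- NULL
  out
}

#' Collapse clean inserts to unique tags with per-library counts
#'
#' @param insert_lists named list (one element per library) of clean insert
#'   vectors, all 18-30 nt.
#' @param min_len,max_len accepted tag length range (violations are an
#'   error: collapsing expects cleaned input).
#' @return list with `tags` (data.frame: sequence, per-library counts,
#'   `count` total, ordered by decreasing total) and `histogram` (data.frame:
#'   length, per-library counts and percentages of clean reads).
#' @export
collapse_tags <- function(insert_lists, min_len = 18L, max_len = 30L) {
  stopifnot(is.list(insert_lists), !is.null(names(insert_lists)))
  for (lib in names(insert_lists)) {
    w <- nchar(insert_lists[[lib]])
    if (length(w) && (min(w) < min_len || max(w) > max_len)) {
      stop("collapse_tags: inserts outside ", min_len, "-", max_len, " nt")
    }
  }
  tabs <- lapply(insert_lists, function(x) table(x))
  seqs <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)))
  mat <- vapply(tabs, function(t) {
    v <- as.numeric(t[seqs])
    v[is.na(v)] <- 0
    v
  }, numeric(length(seqs)))
  if (length(seqs) == 1) mat <- matrix(mat, nrow = 1,
                                       dimnames = list(NULL, names(tabs)))
  tags <- data.frame(sequence = seqs, mat, count = rowSums(mat),
                     stringsAsFactors = FALSE, check.names = FALSE)
  tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL

  lens <- min_len:max_len
  hist <- data.frame(length = lens)
  for (lib in names(insert_lists)) {
    cnt <- tabulate(nchar(insert_lists[[lib]]), nbins = max_len)[lens]
    hist[[lib]] <- cnt
    total <- length(insert_lists[[lib]])
    hist[[paste0(lib, "_pct")]] <-
      if (total > 0) round_half_up(cnt / total * 100, 2) else 0
  }
  list(tags = tags, histogram = hist)
}
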