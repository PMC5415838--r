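# Shared internal helpers.

#' Round half away from zero to a fixed number of decimals
#'
#' Table-style percentages are conventionally rounded half-up (2.345 -> 2.35),
#' unlike [base::round()]'s banker's rounding.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @noRd
dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @noRd
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTU", "TGCAA", toupper(s))
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGU", "UGCA", toupper(s))
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Random sequence with a target GC fraction; bases iid.
#' @noRd
random_seq <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

# Derive a deterministic substream seed from a master seed.  Offsets are
# fixed per operation so stages can be regenerated independently; the result
# is kept within 32-bit integer range.
#' @noRd
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

#' @noRd
gc_fraction_of <- function(x) {
  s <- strsplit(toupper(x), "")[[1]]
  mean(s %in% c("G", "C"))
}

#' @noRd
au_fraction_of <- function(x) {
  s <- strsplit(toupper(x), "")[[1]]
  mean(s %in% c("A", "U", "T"))
}

# Accept a DNAStringSet or a (named) character vector of contigs.
#' @noRd
as_contig_vector <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome)) {
    stop("genome must be a character vector or DNAStringSet")
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  genome
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "", ...)
}
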