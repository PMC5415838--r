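# Conserved miRNA identification: perfect mature+precursor matching,
# summary tallies, single-base edit detection, family assignment and
# positional nucleotide bias.

#' Build (and validate) a miRNA reference
#'
#' @param mature_name,mature,precursor_name,precursor,mature_start,mature_end
#'   parallel vectors describing each mature and its precursor (RNA
#'   alphabet; coordinates 1-based inclusive within the precursor).
#' @return validated data.frame of class `mirna_reference`.
#' @export
mirna_reference <- function(mature_name, mature, precursor_name, precursor,
                            mature_start, mature_end) {
  ref <- data.frame(mature_name = mature_name, mature = rna(mature),
                    precursor_name = precursor_name, precursor = rna(precursor),
                    mature_start = as.integer(mature_start),
                    mature_end = as.integer(mature_end),
                    stringsAsFactors = FALSE)
  win <- substr(ref$precursor, ref$mature_start, ref$mature_end)
  if (any(win != ref$mature)) {
    stop("mirna_reference: mature sequence does not match its precursor ",
         "window (reference-integrity error)")
  }
  class(ref) <- c("mirna_reference", "data.frame")
  ref
}

#' Load a miRNA reference from mature/hairpin FASTA plus a coordinate map
#'
#' @param mature_fa,hairpin_fa FASTA paths (U alphabet accepted).
#' @param map_tsv TSV with columns `mature_name`, `precursor_name`,
#'   `mature_start`, `mature_end`.
#' @return a [mirna_reference()].
#' @export
read_mirna_reference <- function(mature_fa, hairpin_fa, map_tsv) {
  mat <- Biostrings::readRNAStringSet(mature_fa)
  hp <- Biostrings::readRNAStringSet(hairpin_fa)
  map <- read_tsv(map_tsv)
  mirna_reference(map$mature_name,
                  as.character(mat)[map$mature_name],
                  map$precursor_name,
                  as.character(hp)[map$precursor_name],
                  map$mature_start, map$mature_end)
}

#' Match tags to known miRNAs by perfect mature + precursor alignment
#'
#' A tag is a conserved-miRNA hit iff it matches inside a reference precursor
#' with zero mismatches and its matched window overlaps the annotated mature
#' window within `max_shift` nt at both ends (tolerating small isomiR-like
#' length/position variants).
#'
#' @param tags character vector of tag sequences (DNA or RNA).
#' @param reference a [mirna_reference()].
#' @param max_shift maximum start/end shift against the mature window, nt.
#' @return data.frame with `tag`, `mature_name`, `arm` (miR / miR* /
#'   miR-5p / miR-3p, parsed from the mature name).
#' @export
match_known <- function(tags, reference, max_shift = 2L) {
  tags <- unique(tags)
  if (length(tags) == 0 || nrow(reference) == 0) {
    return(data.frame(tag = character(), mature_name = character(),
                      arm = character(), stringsAsFactors = FALSE))
  }
  tag_dna <- dna(tags)
  prec_dna <- Biostrings::DNAStringSet(dna(reference$precursor))
  hits <- list()
  for (w in sort(unique(nchar(tag_dna)))) {
    tw <- which(nchar(tag_dna) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tag_dna[tw]))
    for (p in seq_len(nrow(reference))) {
      m <- Biostrings::matchPDict(pd, prec_dna[[p]])
      st <- Biostrings::startIndex(m)
      for (h in which(lengths(st) > 0)) {
        for (s in st[[h]]) {
          if (abs(s - reference$mature_start[p]) <= max_shift &&
              abs((s + w - 1L) - reference$mature_end[p]) <= max_shift) {
            hits[[length(hits) + 1]] <- data.frame(
              tag = tags[tw[h]], mature_name = reference$mature_name[p],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(tag = character(), mature_name = character(),
                      arm = character(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, hits))
  out$arm <- arm_class(out$mature_name)
  rownames(out) <- NULL
  out
}

# arm class used in the known-miRNA summary table
#' @noRd
arm_class <- function(name) {
  ifelse(grepl("-5p$", name), "miR-5p",
         ifelse(grepl("-3p$", name), "miR-3p",
                ifelse(grepl("\\*$", name), "miR*", "miR")))
}

#' Known-miRNA summary tallies
#'
#' Counts distinct mature miRNAs by arm class, distinct precursors, unique
#' matched tags and matched reads, overall and per library.
#'
#' @param hits data.frame from [match_known()].
#' @param reference a [mirna_reference()].
#' @param tags data.frame from [collapse_tags()] (per-library counts).
#' @param libraries library column names.
#' @return data.frame, one row for the reference plus one per library.
#' @export
tally_known <- function(hits, reference, tags, libraries = NULL) {
  if (is.null(libraries)) {
    libraries <- setdiff(names(tags), c("sequence", "count"))
  }
  prec_of <- setNames(reference$precursor_name, reference$mature_name)
  tag_rows <- match(hits$tag, tags$sequence)
  tally_one <- function(mask) {
    h <- hits[mask, , drop = FALSE]
    c(miR = length(unique(h$mature_name[h$arm == "miR"])),
      `miR*` = length(unique(h$mature_name[h$arm == "miR*"])),
      `miR-5p` = length(unique(h$mature_name[h$arm == "miR-5p"])),
      `miR-3p` = length(unique(h$mature_name[h$arm == "miR-3p"])),
      pre_miRs = length(unique(prec_of[h$mature_name])))
  }
  rows <- list()
  ref_row <- c(tally_one(rep(TRUE, nrow(hits))), unique_tags = NA, reads = NA)
  ref_row[["miR"]] <- sum(arm_class(reference$mature_name) == "miR")
  ref_row[["miR*"]] <- sum(arm_class(reference$mature_name) == "miR*")
  ref_row[["miR-5p"]] <- sum(arm_class(reference$mature_name) == "miR-5p")
  ref_row[["miR-3p"]] <- sum(arm_class(reference$mature_name) == "miR-3p")
  ref_row[["pre_miRs"]] <- length(unique(reference$precursor_name))
  rows[["reference"]] <- ref_row
  for (lib in libraries) {
    cnt <- tags[[lib]][tag_rows]
    cnt[is.na(cnt)] <- 0
    mask <- cnt > 0
    rows[[lib]] <- c(tally_one(mask),
                     unique_tags = length(unique(hits$tag[mask])),
                     reads = sum(cnt))
  }
  out <- data.frame(library = names(rows), do.call(rbind, rows),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-miRNA expression counts from matched tags
#'
#' @param hits data.frame from [match_known()].
#' @param tags data.frame from [collapse_tags()].
#' @param libraries library column names.
#' @return data.frame: `mirna` plus one read-count column per library.
#' @export
known_expression <- function(hits, tags, libraries = NULL) {
  if (is.null(libraries)) {
    libraries <- setdiff(names(tags), c("sequence", "count"))
  }
  idx <- match(hits$tag, tags$sequence)
  out <- data.frame(mirna = sort(unique(hits$mature_name)),
                    stringsAsFactors = FALSE)
  for (lib in libraries) {
    cnt <- tags[[lib]][idx]
    cnt[is.na(cnt)] <- 0
    agg <- tapply(cnt, hits$mature_name, sum, default = 0)
    out[[lib]] <- as.numeric(agg[out$mirna])
  }
  out
}

#' Detect single-base edits against known matures
#'
#' Compares unannotated tags (not already perfect matches) with reference
#' mature sequences over their common 5'-anchored prefix (length difference
#' at most 2 nt) and reports tags at Hamming distance exactly 1.  Ties
#' between matures at distance 1 are assigned to the lexicographically
#' smallest name and flagged.
#'
#' @param tags character vector of candidate tag sequences.
#' @param reference a [mirna_reference()].
#' @param counts optional numeric read counts parallel to `tags`.
#' @return list with `edits` (data.frame: tag, mature_name, position,
#'   ref_base, obs_base, count, tie) and `fraction` (edited tags /
#'   candidate tags).
#' @export
detect_base_edits <- function(tags, reference, counts = NULL) {
  if (is.null(counts)) counts <- rep(1, length(tags))
  if (length(tags) == 0) {
    return(list(edits = data.frame(), fraction = NA_real_))
  }
  ord <- order(reference$mature_name)
  mat_names <- reference$mature_name[ord]
  mat_seqs <- rna(reference$mature[ord])
  res <- hamming_best_cpp(rna(tags), mat_seqs, 2L)
  sel <- which(!is.na(res$dist) & res$dist == 1L)
  if (length(sel) == 0) {
    return(list(edits = data.frame(tag = character(), mature_name = character(),
                                   position = integer(), ref_base = character(),
                                   obs_base = character(), count = numeric(),
                                   tie = logical(), stringsAsFactors = FALSE),
                fraction = 0))
  }
  pos <- res$pos[sel]
  mi <- res$idx[sel]
  edits <- data.frame(
    tag = tags[sel],
    mature_name = mat_names[mi],
    position = pos,
    ref_base = substr(mat_seqs[mi], pos, pos),
    obs_base = substr(rna(tags[sel]), pos, pos),
    count = counts[sel],
    tie = res$nbest[sel] > 1,
    stringsAsFactors = FALSE)
  rownames(edits) <- NULL
  list(edits = edits, fraction = length(sel) / length(tags))
}

#' Assign a miRNA gene family from a miRBase-style name
#'
#' Strips the species prefix, arm suffixes (-5p/-3p/-star/*), trailing
#' lowercase variant letters and duplicate-locus numerals, preserving the
#' let-7 stem; names that do not parse are returned as `"unassigned"`.
#'
#' @param name character vector of miRNA names.
#' @return character vector of family names.
#' @examples
#' assign_family(c("bta-miR-2284x", "bta-let-7a-5p", "bta-miR-133a"))
#' @export
assign_family <- function(name) {
  # strip a species prefix only when a let/miR stem follows, so family
  # names themselves pass through unchanged
  x <- sub("^[A-Za-z]{2,5}-(?=(let|mir))", "", name, perl = TRUE,
           ignore.case = TRUE)
  x <- sub("[-_]?(5p|3p|star)$", "", x, ignore.case = TRUE)
  x <- sub("\\*$", "", x)
  m <- regmatches(x, regexec("^(let|miR|mir)-([0-9]+)", x))
  vapply(m, function(g) {
    if (length(g) == 0) return("unassigned")
    stem <- if (tolower(g[2]) == "let") "let" else "miR"
    paste0(stem, "-", g[3])
  }, character(1))
}

#' Positional nucleotide bias of matched tags
#'
#' Count-weighted base fractions per position (1..`max_pos`) for one
#' library.
#'
#' @param tags character vector of tag sequences.
#' @param counts numeric read counts parallel to `tags`.
#' @param max_pos deepest position reported.
#' @return list with `fractions` (matrix position x base A/C/G/U) and
#'   `u_summary` (U fraction at positions 1, 9 and the per-tag terminal
#'   position).
#' @export
position_bias <- function(tags, counts = NULL, max_pos = 30L) {
  if (is.null(counts)) counts <- rep(1, length(tags))
  tags <- rna(tags)
  if (any(nchar(tags) > max_pos)) stop("position_bias: tag longer than max_pos")
  bases <- c("A", "C", "G", "U")
  frac <- matrix(NA_real_, nrow = max_pos, ncol = 4,
                 dimnames = list(NULL, bases))
  for (p in seq_len(max_pos)) {
    has <- nchar(tags) >= p
    if (!any(has)) next
    b <- substr(tags[has], p, p)
    tot <- sum(counts[has])
    frac[p, ] <- vapply(bases, function(x) sum(counts[has][b == x]) / tot,
                        numeric(1))
  }
  term <- substr(tags, nchar(tags), nchar(tags))
  u_term <- sum(counts[term == "U"]) / sum(counts)
  list(fractions = frac,
       u_summary = c(pos1_U = unname(frac[1, "U"]),
                     pos9_U = if (nrow(frac) >= 9) unname(frac[9, "U"]) else NA,
                     terminal_U = u_term))
}
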