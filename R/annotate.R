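# Genome mapping of unique tags and the annotation priority cascade.

# Table-2 category system in cascade order (highest priority first).
#' Default annotation priority cascade
#' @return character vector of categories, highest priority first.
#' @export
annotation_priority <- function() {
  c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA", "repeat",
    "exon_sense", "exon_antisense", "intron_sense", "intron_antisense")
}

#' Map unique tags to the genome
#'
#' Exact (default) or near-exact search of every tag against both strands of
#' every contig; all loci are reported and the per-tag locus count recorded.
#' Tags containing non-ACGT characters are skipped with a warning.
#'
#' @param tags character vector of tag sequences (18-30 nt).
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param mismatches maximum mismatches (default 0, i.e. perfect matches).
#' @return data.frame with `tag`, `contig`, `start`, `end` (1-based,
#'   inclusive), `strand`, `n_loci`.
#' @export
map_tags <- function(tags, genome, mismatches = 0L) {
  genome <- as_contig_vector(genome)
  tags <- unique(tags)
  bad <- grepl("[^ACGT]", tags)
  if (any(bad)) {
    warning(sprintf("map_tags: skipped %d tags with non-ACGT characters",
                    sum(bad)))
    tags <- tags[!bad]
  }
  subj <- Biostrings::DNAStringSet(genome)
  subj_rc <- Biostrings::reverseComplement(subj)
  clen <- nchar(genome)

  res <- list()
  emit <- function(tag_v, contig, start_v, w, strand) {
    if (length(start_v) == 0) return(invisible(NULL))
    res[[length(res) + 1]] <<- data.frame(
      tag = tag_v, contig = contig, start = start_v,
      end = start_v + w - 1L, strand = strand, stringsAsFactors = FALSE)
    invisible(NULL)
  }

  if (mismatches == 0) {
    for (w in sort(unique(nchar(tags)))) {
      tw <- tags[nchar(tags) == w]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(tw))
      for (ci in seq_along(subj)) {
        ctg <- names(genome)[ci]
        m <- Biostrings::matchPDict(pd, subj[[ci]])
        st <- Biostrings::startIndex(m)
        hit <- which(lengths(st) > 0)
        for (h in hit) emit(rep(tw[h], length(st[[h]])), ctg, st[[h]], w, "+")
        m <- Biostrings::matchPDict(pd, subj_rc[[ci]])
        st <- Biostrings::startIndex(m)
        hit <- which(lengths(st) > 0)
        for (h in hit) {
          # minus-strand: position on the reverse complement maps back to
          # genome coordinates from the right end
          gs <- clen[ci] - (st[[h]] + w - 1L) + 1L
          emit(rep(tw[h], length(gs)), ctg, gs, w, "-")
        }
      }
    }
  } else {
    # mismatch-tolerant fallback: per-tag scan (slower; intended for small
    # inputs)
    for (tg in tags) {
      w <- nchar(tg)
      for (ci in seq_along(subj)) {
        ctg <- names(genome)[ci]
        m <- Biostrings::matchPattern(tg, subj[[ci]], max.mismatch = mismatches)
        emit(rep(tg, length(m)), ctg, BiocGenerics::start(m), w, "+")
        m <- Biostrings::matchPattern(tg, subj_rc[[ci]], max.mismatch = mismatches)
        if (length(m) > 0) {
          gs <- clen[ci] - (BiocGenerics::start(m) + w - 1L) + 1L
          emit(rep(tg, length(m)), ctg, gs, w, "-")
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(tag = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_loci = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  nl <- table(out$tag)
  out$n_loci <- as.integer(nl[out$tag])
  rownames(out) <- NULL
  out
}

#' Classify tags into annotation categories via the priority cascade
#'
#' Each tag is assigned the single highest-priority category across all of
#' its genomic loci and overlapping features.  Exon and intron assignments
#' are split into sense/antisense by strand agreement between the tag hit
#' and the feature.  Tags with no alignment or no feature overlap are
#' `unann`.
#'
#' @param tags character vector of all tag sequences to classify.
#' @param alignments data.frame from [map_tags()].
#' @param features data.frame with `contig`, `start`, `end`, `strand`,
#'   `type`, `id`; `type` uses the base classes (`miRNA`, `rRNA`, ...,
#'   `repeat`, `exon`, `intron`).
#' @param priority category cascade, highest first.
#' @return data.frame with `tag`, `category`, `feature` (id or `NA`),
#'   `n_loci`.
#' @export
classify_tags <- function(tags, alignments, features,
                          priority = annotation_priority()) {
  tags <- unique(tags)
  out <- data.frame(tag = tags, category = "unann", feature = NA_character_,
                    n_loci = 0L, stringsAsFactors = FALSE)
  if (nrow(alignments) > 0) {
    nl <- tapply(alignments$n_loci, alignments$tag, max)
    idx <- match(names(nl), out$tag)
    out$n_loci[idx[!is.na(idx)]] <- as.integer(nl[!is.na(idx)])
  }
  if (nrow(alignments) == 0 || nrow(features) == 0) return(out)

  gr_aln <- GenomicRanges::GRanges(
    seqnames = alignments$contig,
    ranges = IRanges::IRanges(alignments$start, alignments$end),
    strand = alignments$strand)
  gr_feat <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  ov <- GenomicRanges::findOverlaps(gr_aln, gr_feat, ignore.strand = TRUE)
  if (length(ov) == 0) return(out)

  qa <- S4Vectors::queryHits(ov)
  sa <- S4Vectors::subjectHits(ov)
  ftype <- features$type[sa]
  same_strand <- alignments$strand[qa] == features$strand[sa]
  cat <- ftype
  cat[ftype == "exon"] <- ifelse(same_strand[ftype == "exon"],
                                 "exon_sense", "exon_antisense")
  cat[ftype == "intron"] <- ifelse(same_strand[ftype == "intron"],
                                   "intron_sense", "intron_antisense")
  pri <- match(cat, priority)
  keep <- !is.na(pri)
  hits <- data.frame(tag = alignments$tag[qa][keep], category = cat[keep],
                     feature = features$id[sa][keep], pri = pri[keep],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$pri), , drop = FALSE]
  best <- hits[!duplicated(hits$tag), , drop = FALSE]
  idx <- match(best$tag, out$tag)
  out$category[idx] <- best$category
  out$feature[idx] <- best$feature
  out
}

#' Annotation summary matrix (unique tags and total reads per category)
#'
#' @param annotation data.frame from [classify_tags()].
#' @param tags data.frame from [collapse_tags()] (`sequence` plus one count
#'   column per library).
#' @param libraries library column names in `tags` (default: all columns
#'   between `sequence` and `count`).
#' @return data.frame with one row per category (plus `Total`), and per
#'   library the unique-tag and read counts with percentages (half-up,
#'   2 decimals).
#' @export
summarize_annotation <- function(annotation, tags, libraries = NULL) {
  if (is.null(libraries)) {
    libraries <- setdiff(names(tags), c("sequence", "count"))
  }
  cats <- c(annotation_priority(), "unann")
  cat_of <- setNames(annotation$category, annotation$tag)
  tag_cat <- factor(unname(cat_of[tags$sequence]), levels = cats)
  out <- data.frame(category = c("Total", cats), stringsAsFactors = FALSE)
  for (lib in libraries) {
    cnt <- tags[[lib]]
    present <- cnt > 0
    uniq <- as.numeric(table(tag_cat[present]))
    reads <- as.numeric(tapply(cnt, tag_cat, sum, default = 0))
    u_tot <- sum(present)
    r_tot <- sum(cnt)
    out[[paste0(lib, "_unique")]] <- c(u_tot, uniq)
    out[[paste0(lib, "_unique_pct")]] <-
      round_half_up(c(u_tot, uniq) / max(u_tot, 1) * 100, 2)
    out[[paste0(lib, "_reads")]] <- c(r_tot, reads)
    out[[paste0(lib, "_reads_pct")]] <-
      round_half_up(c(r_tot, reads) / max(r_tot, 1) * 100, 2)
  }
  out
}
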