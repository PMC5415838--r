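# Novel miRNA discovery: candidate extraction, hairpin screening.

#' Default thresholds for the novel-miRNA hairpin screen
#'
#' @param mature_len_min,mature_len_max accepted mature length range (nt).
#' @param max_star_mismatches maximum unpaired mature positions (must be
#'   strictly less than this value to pass; the classical criterion is
#'   "fewer than six mismatches with the opposite star sequence").
#' @param au_min,au_max accepted AU fraction of the mature.
#' @param mfe_max maximum (most positive) accepted precursor MFE, kcal/mol.
#' @param mfei_max maximum accepted MFEI.
#' @param max_loop_run longest tolerated internal unpaired stretch inside the
#'   mature ("no loop or break").
#' @param dicer_min_fraction minimum fraction of locus reads starting within
#'   +/- 2 nt of the mature 5' end (only evaluated when read support is
#'   available).
#' @return named list of thresholds.
#' @export
novel_thresholds <- function(mature_len_min = 20L, mature_len_max = 22L,
                             max_star_mismatches = 6L,
                             au_min = 0.30, au_max = 0.70,
                             mfe_max = -20, mfei_max = -0.85,
                             max_loop_run = 3L,
                             dicer_min_fraction = 0.80) {
  list(mature_len_min = mature_len_min, mature_len_max = mature_len_max,
       max_star_mismatches = max_star_mismatches,
       au_min = au_min, au_max = au_max,
       mfe_max = mfe_max, mfei_max = mfei_max,
       max_loop_run = max_loop_run,
       dicer_min_fraction = dicer_min_fraction)
}

# Evaluate the hairpin criteria for a FIXED window with the mature at a known
# offset.  Returns per-criterion flags plus structural details.  This is the
# shared core of screen_candidate() (which searches sub-windows) and of the
# generator's rejection sampling.
#' @noRd
screen_hairpin <- function(window, mature_start, mature_len,
                           thresholds = novel_thresholds(),
                           read_starts = NULL, read_counts = NULL) {
  window <- rna(window)
  n <- nchar(window)
  m1 <- mature_start
  m2 <- mature_start + mature_len - 1L
  stopifnot(m1 >= 1, m2 <= n)
  fr <- rna_fold(window)
  pt <- pair_table(fr$structure)
  mpos <- m1:m2
  partners <- pt[mpos]
  paired <- partners > 0
  n_unpaired <- sum(!paired)

  flag_len <- mature_len >= thresholds$mature_len_min &&
    mature_len <= thresholds$mature_len_max

  # an appropriate hairpin: the window folds into a single stem-loop
  # (exactly one terminal loop)
  n_loops <- length(gregexpr("\\(\\.*\\)", fr$structure, perl = TRUE)[[1]])
  if (!grepl("\\(\\.*\\)", fr$structure)) n_loops <- 0
  flag_hairpin <- n_loops == 1

  # one arm: every partner on the same side of the mature, which for a nested
  # structure also forces them into a single stem
  flag_arm <- FALSE
  if (any(paired)) {
    flag_arm <- all(partners[paired] > m2) || all(partners[paired] < m1)
  }

  # star criterion: fewer than max_star_mismatches unpaired mature bases
  flag_star <- n_unpaired < thresholds$max_star_mismatches

  # no loop or break: no internal unpaired run in the mature longer than
  # max_loop_run
  runs <- rle(!paired)
  internal_runs <- runs$lengths[runs$values]
  flag_break <- length(internal_runs) == 0 ||
    max(internal_runs) <= thresholds$max_loop_run

  mature_seq <- substr(window, m1, m2)
  au <- au_fraction_of(mature_seq)
  flag_au <- au >= thresholds$au_min && au <= thresholds$au_max

  flag_mfe <- fr$mfe < thresholds$mfe_max
  gc <- gc_fraction_of(window)
  ix <- if (gc > 0 && gc < 1) mfei(fr$mfe, n, gc)$mfei else 0
  flag_mfei <- gc > 0 && gc < 1 && ix <= thresholds$mfei_max

  flag_dicer <- TRUE
  if (!is.null(read_starts) && length(read_starts) > 0) {
    if (is.null(read_counts)) read_counts <- rep(1, length(read_starts))
    near <- abs(read_starts - m1) <= 2
    flag_dicer <- sum(read_counts[near]) / sum(read_counts) >=
      thresholds$dicer_min_fraction
  }

  star_window <- if (any(paired)) range(partners[paired]) else c(NA_integer_, NA_integer_)
  list(
    flags = c(length = flag_len, hairpin = flag_hairpin, arm = flag_arm,
              star = flag_star, no_break = flag_break, au = flag_au,
              mfe = flag_mfe, mfei = flag_mfei, dicer = flag_dicer),
    pass = flag_len && flag_hairpin && flag_arm && flag_star && flag_break &&
      flag_au && flag_mfe && flag_mfei && flag_dicer,
    mfe = fr$mfe, mfei = ix, au = au,
    mismatches = n_unpaired,
    structure = fr$structure,
    star_start = star_window[1], star_end = star_window[2]
  )
}

#' Screen a flanked locus window for a miRNA-like hairpin
#'
#' Excises candidate precursors around the seeding tag and evaluates the
#' hairpin criteria: mature length 20-22 nt; the mature entirely within one
#' arm of a folded hairpin; fewer than six unpaired positions against the
#' opposite star arm; no internal unpaired stretch longer than 3 nt in the
#' mature; mature AU content 30-70%; precursor MFE below -20 kcal/mol; MFEI
#' at most -0.85; and, when read support is supplied, at least 80% of locus
#' reads starting within 2 nt of the mature 5' end (Dicer consistency).
#'
#' Precursor excision tries a deterministic grid of sub-windows: 0/5/10 nt
#' beyond the mature on one side and 24-60 nt (4-nt steps) on the other,
#' in both arm orientations, mirroring how hairpin-discovery tools excise
#' precursors from a flanked locus.  The candidate passes if any sub-window
#' satisfies every criterion; the reported structure is the passing (or
#' otherwise lowest-energy) sub-window.
#'
#' @param window flanked locus sequence (RNA or DNA), 5'->3' on the tag
#'   strand.
#' @param tag_start 1-based start of the seeding tag inside `window`.
#' @param tag_len tag length (the putative mature length).
#' @param thresholds see [novel_thresholds()].
#' @param read_starts,read_counts optional positions (1-based, in `window`
#'   coordinates) and counts of all reads mapped to the locus, used for the
#'   Dicer-consistency criterion.
#' @return a one-row data.frame with the verdict, per-criterion flags and
#'   structural details of the best sub-window.
#' @export
screen_candidate <- function(window, tag_start, tag_len,
                             thresholds = novel_thresholds(),
                             read_starts = NULL, read_counts = NULL) {
  window <- rna(window)
  n <- nchar(window)
  tag_end <- tag_start + tag_len - 1L
  stopifnot(tag_start >= 1, tag_end <= n)

  small <- c(0L, 5L, 10L)
  large <- seq(24L, 60L, by = 4L)
  grid <- rbind(expand.grid(a = small, b = large),
                expand.grid(a = large, b = small))

  best <- NULL
  best_pass <- FALSE
  best_mfe <- Inf
  best_bounds <- c(NA_integer_, NA_integer_)
  for (g in seq_len(nrow(grid))) {
    s1 <- tag_start - grid$a[g]
    s2 <- tag_end + grid$b[g]
    if (s1 < 1 || s2 > n) next
    sub <- substr(window, s1, s2)
    rs <- rc <- NULL
    if (!is.null(read_starts)) {
      keep <- read_starts >= s1 & read_starts <= s2
      rs <- read_starts[keep] - s1 + 1L
      rc <- if (is.null(read_counts)) NULL else read_counts[keep]
    }
    res <- screen_hairpin(sub, tag_start - s1 + 1L, tag_len, thresholds, rs, rc)
    better <- if (res$pass && !best_pass) TRUE
      else if (res$pass == best_pass) res$mfe < best_mfe else FALSE
    if (is.null(best) || better) {
      best <- res
      best_pass <- res$pass
      best_mfe <- res$mfe
      best_bounds <- c(s1, s2)
    }
    if (best_pass && res$pass) next
  }
  if (is.null(best)) {
    best <- screen_hairpin(window, tag_start, tag_len, thresholds,
                           read_starts, read_counts)
    best_bounds <- c(1L, n)
  }
  data.frame(
    pass = best$pass,
    sub_start = best_bounds[1], sub_end = best_bounds[2],
    mfe = best$mfe, mfei = best$mfei, au = best$au,
    mismatches = best$mismatches,
    flag_length = unname(best$flags["length"]),
    flag_hairpin = unname(best$flags["hairpin"]),
    flag_arm = unname(best$flags["arm"]),
    flag_star = unname(best$flags["star"]),
    flag_no_break = unname(best$flags["no_break"]),
    flag_au = unname(best$flags["au"]),
    flag_mfe = unname(best$flags["mfe"]),
    flag_mfei = unname(best$flags["mfei"]),
    flag_dicer = unname(best$flags["dicer"]),
    structure = best$structure,
    stringsAsFactors = FALSE
  )
}

#' Extract flanked candidate windows for novel-miRNA screening
#'
#' Unannotated tags with at most `max_loci` genome hits and total read count
#' of at least `min_count` seed candidate loci; each locus is extended by
#' `flank` nt on both sides (clipped at contig edges) and minus-strand
#' windows are reverse-complemented so the tag always reads 5'->3'.
#' Overlapping windows are merged and the highest-count tag defines the
#' putative mature.
#'
#' @param tags data.frame with columns `sequence` and `count` (total reads
#'   across libraries), restricted by the caller to unannotated tags.
#' @param alignments data.frame from [map_tags()] (columns `tag`, `contig`,
#'   `start`, `end`, `strand`, `n_loci`).
#' @param genome named character vector (or `DNAStringSet`) of contigs.
#' @param flank flank length, nt.
#' @param max_loci tags with more genome hits are discarded.
#' @param min_count minimum total read support for a seeding tag.
#' @return data.frame of candidate windows with the tag position inside each.
#' @export
extract_candidates <- function(tags, alignments, genome, flank = 150L,
                               max_loci = 10L, min_count = 5L) {
  genome <- as_contig_vector(genome)
  keep_tags <- tags$sequence[tags$count >= min_count]
  aln <- alignments[alignments$tag %in% keep_tags &
                      alignments$n_loci <= max_loci &
                      alignments$n_loci >= 1, , drop = FALSE]
  if (nrow(aln) == 0) {
    return(data.frame(tag = character(), contig = character(),
                      win_start = integer(), win_end = integer(),
                      strand = character(), tag_start = integer(),
                      count = numeric(), window = character(),
                      stringsAsFactors = FALSE))
  }
  cnt <- setNames(tags$count, tags$sequence)
  aln$count <- unname(cnt[aln$tag])

  out <- lapply(seq_len(nrow(aln)), function(i) {
    ctg <- genome[[aln$contig[i]]]
    L <- nchar(ctg)
    ws <- max(1L, aln$start[i] - flank)
    we <- min(L, aln$end[i] + flank)
    win <- substr(ctg, ws, we)
    if (aln$strand[i] == "-") {
      win <- revcomp_chr(win)
      tag_start <- we - aln$end[i] + 1L
    } else {
      tag_start <- aln$start[i] - ws + 1L
    }
    data.frame(tag = aln$tag[i], contig = aln$contig[i],
               win_start = ws, win_end = we, strand = aln$strand[i],
               tag_start = tag_start, count = aln$count[i],
               window = rna(win), stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, out)

  # merge overlapping windows (same contig); the highest-count tag wins
  cand <- cand[order(cand$contig, cand$win_start), , drop = FALSE]
  keep <- logical(nrow(cand))
  group_best <- 1L
  cur_end <- -1L
  cur_contig <- ""
  for (i in seq_len(nrow(cand))) {
    if (cand$contig[i] != cur_contig || cand$win_start[i] > cur_end) {
      if (cur_end >= 0) keep[group_best] <- TRUE
      group_best <- i
      cur_contig <- cand$contig[i]
      cur_end <- cand$win_end[i]
    } else {
      cur_end <- max(cur_end, cand$win_end[i])
      if (cand$count[i] > cand$count[group_best]) group_best <- i
    }
  }
  if (cur_end >= 0) keep[group_best] <- TRUE
  rownames(cand) <- NULL
  cand[keep, , drop = FALSE]
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes a sequence while preserving its exact
#' dinucleotide (and hence mononucleotide) composition, the standard negative
#' control for RNA secondary-structure screens.
#'
#' @param x a single sequence (character).
#' @param max_tries resampling budget for the connectivity check.
#' @return shuffled sequence with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(x, max_tries = 200L) {
  s <- strsplit(toupper(x), "")[[1]]
  n <- length(s)
  if (n < 3) return(x)
  verts <- unique(s)
  edges <- lapply(setNames(verts, verts), function(v) s[which(s == v) + 1])
  edges <- lapply(edges, function(e) e[!is.na(e)])
  last <- s[n]
  for (try in seq_len(max_tries)) {
    # pick a candidate "last edge" per vertex (except the terminal one) and
    # require that these edges form a tree rooted at the terminal vertex
    last_edge <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) NA_character_
      else sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (!is.na(cur) && cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- if (cur %in% names(last_edge)) last_edge[[cur]] else NA
      }
      if (is.na(cur) || cur %in% seen) { ok <- FALSE; break }
    }
    if (!ok) next
    # shuffle the remaining edges and append each vertex's last edge
    pool <- lapply(setNames(verts, verts), function(v) {
      e <- edges[[v]]
      if (v != last && !is.na(last_edge[[v]])) {
        drop <- match(last_edge[[v]], e)
        e <- e[-drop]
      }
      e <- if (length(e) > 1) sample(e) else e
      if (v != last && !is.na(last_edge[[v]])) c(e, last_edge[[v]]) else e
    })
    used <- setNames(integer(length(verts)), verts)
    out <- character(n)
    out[1] <- s[1]
    good <- TRUE
    for (i in 2:n) {
      v <- out[i - 1]
      used[v] <- used[v] + 1L
      if (used[v] > length(pool[[v]])) { good <- FALSE; break }
      out[i] <- pool[[v]][used[v]]
    }
    if (good) return(paste(out, collapse = ""))
  }
  # extremely skewed compositions can defeat the sampler; fall back to a
  # plain permutation (preserves mononucleotide composition only)
  paste(sample(s), collapse = "")
}

#' Screen all candidate windows and report hairpin verdicts
#'
#' @param candidates output of [extract_candidates()].
#' @param alignments full tag alignment table, used to compute per-locus read
#'   support for the Dicer-consistency criterion.
#' @param tag_counts named numeric vector of total read counts per tag
#'   sequence.
#' @param thresholds see [novel_thresholds()].
#' @return `candidates` with screening columns appended (verdict, flags, MFE,
#'   MFEI, AU fraction, star mismatches, dot-bracket structure).
#' @export
screen_candidates <- function(candidates, alignments = NULL, tag_counts = NULL,
                              thresholds = novel_thresholds()) {
  if (nrow(candidates) == 0) {
    return(cbind(candidates, screen_candidate("GGGGGAAAACCCCC", 1, 5)[0, ]))
  }
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    ca <- candidates[i, ]
    rs <- rc <- NULL
    if (!is.null(alignments)) {
      loc <- alignments[alignments$contig == ca$contig &
                          alignments$strand == ca$strand &
                          alignments$start >= ca$win_start &
                          alignments$start <= ca$win_end, , drop = FALSE]
      if (nrow(loc) > 0) {
        if (ca$strand == "-") {
          # window is reverse-complemented: a read's 5' end on the minus
          # strand corresponds to its genomic end
          rs <- ca$win_end - loc$end + 1L
        } else {
          rs <- loc$start - ca$win_start + 1L
        }
        rc <- if (is.null(tag_counts)) rep(1, nrow(loc)) else
          unname(tag_counts[loc$tag])
        rc[is.na(rc)] <- 1
      }
    }
    screen_candidate(ca$window, ca$tag_start, nchar(ca$tag), thresholds, rs, rc)
  })
  cbind(candidates, do.call(rbind, res))
}
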