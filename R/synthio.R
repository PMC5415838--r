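# Synthetic small RNA-seq dataset generator with planted ground truth.
#
# The generator emulates the design of a three-library (proliferation, day-1
# and day-3 differentiation) bovine satellite-cell small RNA experiment:
# ~6 M raw reads per library cleaned down to ~98% usable reads, a length mode
# at 22 nt, an annotation mix dominated by miRNA reads, planted known miRNAs
# with configurable fold changes between stages, and planted novel hairpin
# precursors that satisfy the package's screening criteria by construction.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the emulated study conditions: three libraries, a
#' 200 kb genome, 20 known and 10 novel planted precursors, 3e5 reads per
#' stage, contamination rates patterned on the published cleaning table
#' (~0.05% missing 3' adapter, ~0.05% null insert, ~1.4% 5' contaminants,
#' ~0.35% short inserts, trace polyA), and a clean-read class mix dominated
#' by miRNA reads (~82%) with ~14% unannotated background.
#'
#' @param seed master seed; all randomness derives from it via fixed
#'   per-operation substream offsets.
#' @param genome_length single-contig genome size, bases.
#' @param gc_fraction genome GC fraction.
#' @param n_known_precursors,n_novel_precursors planted precursor counts.
#' @param n_decoy_features named counts of decoy features per annotation
#'   class.
#' @param library_sizes raw reads per stage (3 values).
#' @param de_spec data.frame(mirna, stage, log2fc): planted log2 fold changes
#'   of known miRNA `mirna` (index) in stage 2 (D1) or 3 (D3) relative to
#'   stage 1 (P).
#' @param contamination_rates named proportions of raw reads per contaminant
#'   class: `low_quality`, `adaptor3_null`, `insert_null`, `adaptor5`,
#'   `short`, `polyA`.
#' @param error_rate per-base substitution probability in biological inserts.
#' @param quality_model mean and sd of simulated Phred scores.
#' @param adapter3,adapter5 adapter sequences.
#' @param read_length instrument read length (cycles).
#' @param class_mix named proportions of clean reads per source class; the
#'   remainder is unannotated genomic background.
#' @param abundance_sdlog log-normal sd of planted miRNA abundances (heavy
#'   tail).
#' @param isomir_rate fraction of known-miRNA reads trimmed by one 3' base.
#' @param star_read_fraction fraction of novel-locus reads from the star arm.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             genome_length = 200000L,
                             gc_fraction = 0.5,
                             n_known_precursors = 20L,
                             n_novel_precursors = 10L,
                             n_decoy_features = c(rRNA = 5L, tRNA = 5L,
                                                  snRNA = 4L, snoRNA = 4L,
                                                  scRNA = 3L, srpRNA = 3L,
                                                  repeat_ = 5L, exon = 6L,
                                                  intron = 6L),
                             library_sizes = c(3e5, 3e5, 3e5),
                             de_spec = default_de_spec(),
                             contamination_rates = c(low_quality = 0.0026,
                                                     adaptor3_null = 5e-4,
                                                     insert_null = 5e-4,
                                                     adaptor5 = 0.0144,
                                                     short = 0.0035,
                                                     polyA = 2e-4),
                             error_rate = 0.002,
                             quality_model = c(mean = 38, sd = 2),
                             adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                             adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                             read_length = 50L,
                             class_mix = c(miRNA = 0.825, novel = 0.005,
                                           rRNA = 0.011, tRNA = 0.008,
                                           snRNA = 4e-4, snoRNA = 3e-4,
                                           scRNA = 2e-4, srpRNA = 5e-5,
                                           repeat_ = 0.0027,
                                           exon_sense = 0.0012,
                                           exon_antisense = 2e-4,
                                           intron_sense = 0.0013,
                                           intron_antisense = 8e-4),
                             abundance_sdlog = 1.5,
                             isomir_rate = 0.10,
                             star_read_fraction = 0.10) {
  stopifnot(length(library_sizes) == 3, all(library_sizes > 0))
  stopifnot(all(contamination_rates >= 0), all(contamination_rates <= 1))
  stopifnot(sum(contamination_rates) < 1, sum(class_mix) < 1)
  stopifnot(error_rate >= 0, error_rate <= 1)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction,
              n_known_precursors = as.integer(n_known_precursors),
              n_novel_precursors = as.integer(n_novel_precursors),
              n_decoy_features = n_decoy_features,
              library_sizes = library_sizes, de_spec = de_spec,
              contamination_rates = contamination_rates,
              error_rate = error_rate, quality_model = quality_model,
              adapter3 = toupper(adapter3), adapter5 = toupper(adapter5),
              read_length = as.integer(read_length), class_mix = class_mix,
              abundance_sdlog = abundance_sdlog, isomir_rate = isomir_rate,
              star_read_fraction = star_read_fraction)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default planted differential-expression specification
#'
#' Ten known miRNAs receive planted log2 fold changes relative to the
#' proliferation stage, eight of them with |log2FC| >= 2 in both directions,
#' split between the two differentiation stages.
#' @return data.frame with columns `mirna`, `stage`, `log2fc`.
#' @export
default_de_spec <- function() {
  data.frame(
    mirna = 1:10,
    stage = c(2L, 2L, 2L, 3L, 3L, 3L, 2L, 3L, 2L, 3L),
    log2fc = c(2.5, -2.5, 3, 2, -2, 2.2, -3, -2.2, 1, -1)
  )
}

# stage labels used throughout reports
stage_names <- c("P", "D1", "D3")

#' Construct a planted hairpin precursor
#'
#' Builds mature + loop + star (or star + loop + mature), with the star the
#' reverse complement of the mature carrying `star_mismatches` non-pairing
#' substitutions, and rejection-samples the construction until the folded
#' precursor satisfies every structural screening criterion (mature within
#' one arm, AU content 30-70%, MFE below threshold, ...).  The mature is
#' given a 5' U, the dominant first base of real miRNAs.
#'
#' @param mature_length mature length, 20-22 nt.
#' @param star_mismatches substitutions in the star arm, 0-5.
#' @param loop_length terminal loop length, nt.
#' @param thresholds screening thresholds, see [novel_thresholds()].
#' @param max_tries rejection-sampling budget; exceeding it is an error that
#'   reports the most frequently failed criterion.
#' @return list with `precursor` (RNA), `mature_start`, `mature_end`,
#'   `star_start`, `star_end`, `arm` ("5p"/"3p"), `mature`, `star`.
#' @export
plant_hairpin <- function(mature_length = 22L, star_mismatches = 1L,
                          loop_length = 9L, thresholds = novel_thresholds(),
                          max_tries = 1000L) {
  stopifnot(mature_length >= 20, mature_length <= 22)
  stopifnot(star_mismatches >= 0, star_mismatches < 6)
  bases <- c("A", "C", "G", "U")
  pairs_with <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  fail_counts <- integer(0)
  for (try in seq_len(max_tries)) {
    p_au <- runif(1, 0.35, 0.65)
    prob <- c(p_au / 2, (1 - p_au) / 2, (1 - p_au) / 2, p_au / 2)
    mat <- sample(bases, mature_length, replace = TRUE, prob = prob)
    mat[1] <- "U"
    star <- rev(chartr("ACGU", "UGCA", mat))
    if (star_mismatches > 0) {
      pos <- sample(3:(mature_length - 2), star_mismatches)
      for (k in pos) {
        partner <- mat[mature_length - k + 1]
        choices <- bases[!vapply(bases, pairs_with, logical(1), b = partner)]
        star[k] <- sample(choices, 1)
      }
    }
    loop <- sample(bases, loop_length, replace = TRUE)
    arm <- sample(c("5p", "3p"), 1)
    if (arm == "5p") {
      prec <- c(mat, loop, star)
      m1 <- 1L
    } else {
      prec <- c(star, loop, mat)
      m1 <- length(star) + loop_length + 1L
    }
    prec_s <- paste(prec, collapse = "")
    res <- screen_hairpin(prec_s, m1, mature_length, thresholds)
    if (res$pass) {
      m2 <- m1 + mature_length - 1L
      if (arm == "5p") {
        s1 <- mature_length + loop_length + 1L
        s2 <- nchar(prec_s)
      } else {
        s1 <- 1L
        s2 <- mature_length
      }
      return(list(precursor = prec_s, mature_start = m1, mature_end = m2,
                  star_start = s1, star_end = s2, arm = arm,
                  mature = paste(mat, collapse = ""),
                  star = paste(star, collapse = "")))
    }
    failed <- names(res$flags)[!res$flags]
    for (f in failed) {
      fail_counts[f] <- if (is.na(fail_counts[f])) 1L else fail_counts[f] + 1L
    }
  }
  worst <- names(which.max(fail_counts))
  stop(sprintf(
    "plant_hairpin: %d consecutive rejections; most frequent failure: %s",
    max_tries, worst))
}

# decoy feature lengths per class (jittered at placement)
decoy_lengths <- c(rRNA = 120L, tRNA = 75L, snRNA = 150L, snoRNA = 100L,
                   scRNA = 120L, srpRNA = 300L, repeat_ = 200L, exon = 250L,
                   intron = 400L)

#' Generate the synthetic genome, features and planted precursors
#'
#' Lays out planted known/novel precursors and decoy features in
#' non-overlapping blocks on one random contig, embeds the precursor
#' sequences (reverse-complemented on the minus strand) and re-rolls each
#' novel precursor until its flanked genomic window passes
#' [screen_candidate()] with default thresholds, so the generator's planted
#' truth is closed under the package's own screen.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `genome` (named character), `features` (data.frame:
#'   contig, start, end, strand, type, id), `precursors` (truth table rows
#'   for every planted precursor) and `reference` (the miRBase-style mature/
#'   precursor reference for the known set).
#' @export
make_genome <- function(cfg) {
  set.seed(substream_seed(cfg$seed, 1))
  n_known <- cfg$n_known_precursors
  n_novel <- cfg$n_novel_precursors
  decoys <- cfg$n_decoy_features

  feat_types <- c(rep("known", n_known), rep("novel", n_novel),
                  rep(names(decoys), decoys))
  lens <- c(rep(60L, n_known + n_novel),
            unlist(lapply(names(decoys), function(cl) {
              pmax(60L, decoy_lengths[[cl]] +
                     sample(-20:20, decoys[[cl]], replace = TRUE))
            })))
  if (cfg$genome_length < 10 * sum(lens)) {
    stop("make_genome: genome_length must be at least 10x total feature length")
  }
  n_feat <- length(feat_types)
  block <- cfg$genome_length %/% n_feat
  margin <- 200L
  if (any(block < lens + 2 * margin)) {
    stop("make_genome: insufficient space to place features without overlap")
  }
  ord <- sample(n_feat)   # shuffle feature order across blocks
  genome <- random_seq(cfg$genome_length, cfg$gc_fraction)

  feat <- data.frame(contig = "chr1", start = NA_integer_, end = NA_integer_,
                     strand = sample(c("+", "-"), n_feat, replace = TRUE),
                     type = feat_types, id = NA_character_,
                     stringsAsFactors = FALSE)
  for (b in seq_len(n_feat)) {
    i <- ord[b]
    off <- sample.int(block - lens[i] - 2 * margin, 1) + margin
    feat$start[i] <- (b - 1L) * block + off
    feat$end[i] <- feat$start[i] + lens[i] - 1L
  }
  counters <- integer(0)
  for (i in seq_len(n_feat)) {
    tp <- feat$type[i]
    counters[tp] <- if (is.na(counters[tp])) 1L else counters[tp] + 1L
    feat$id[i] <- switch(tp,
      known = sprintf("syn-mir-%d", 100L + counters[tp]),
      novel = sprintf("syn-nov-%d", counters[tp]),
      sprintf("%s-%d", sub("_$", "", tp), counters[tp]))
  }

  arm_styles <- sample(c("plain", "5p", "3p", "star"), n_known, replace = TRUE,
                       prob = c(0.3, 0.35, 0.25, 0.1))
  prec_rows <- list()
  embed <- function(i, hp) {
    # place the precursor at the left edge of the 60 nt slot
    p_len <- nchar(hp$precursor)
    start <- feat$start[i]
    end <- start + p_len - 1L
    seq_dna <- dna(hp$precursor)
    if (feat$strand[i] == "-") seq_dna <- revcomp_chr(seq_dna)
    substr(genome, start, end) <<- seq_dna
    if (feat$strand[i] == "+") {
      mg <- c(start + hp$mature_start - 1L, start + hp$mature_end - 1L)
      sg <- c(start + hp$star_start - 1L, start + hp$star_end - 1L)
    } else {
      mg <- c(end - hp$mature_end + 1L, end - hp$mature_start + 1L)
      sg <- c(end - hp$star_end + 1L, end - hp$star_start + 1L)
    }
    list(start = start, end = end, mature = mg, star = sg)
  }

  ki <- which(feat$type == "known")
  for (j in seq_along(ki)) {
    i <- ki[j]
    hp <- plant_hairpin(sample(20:22, 1, prob = c(0.1, 0.15, 0.75)),
                        star_mismatches = sample(0:3, 1),
                        loop_length = sample(8:12, 1))
    pl <- embed(i, hp)
    base <- sprintf("syn-miR-%d", 100L + j)
    mature_name <- switch(arm_styles[j],
                          plain = base,
                          `5p` = paste0(base, "-5p"),
                          `3p` = paste0(base, "-3p"),
                          star = paste0(base, "*"))
    prec_rows[[length(prec_rows) + 1]] <- data.frame(
      name = feat$id[i], mature_name = mature_name, kind = "known",
      contig = "chr1", start = pl$start, end = pl$end,
      strand = feat$strand[i],
      mature_gstart = pl$mature[1], mature_gend = pl$mature[2],
      star_gstart = pl$star[1], star_gend = pl$star[2],
      precursor = hp$precursor, mature = hp$mature, star = hp$star,
      mature_start = hp$mature_start, mature_end = hp$mature_end,
      arm = arm_styles[j], stringsAsFactors = FALSE)
    feat$start[i] <- pl$start
    feat$end[i] <- pl$end
  }

  ni <- which(feat$type == "novel")
  for (j in seq_along(ni)) {
    i <- ni[j]
    ok <- FALSE
    for (try in seq_len(50)) {
      hp <- plant_hairpin(sample(20:22, 1, prob = c(0.1, 0.15, 0.75)),
                          star_mismatches = sample(0:3, 1),
                          loop_length = sample(8:12, 1))
      pl <- embed(i, hp)
      # closure check: the flanked genomic window must pass the same screen
      # the pipeline applies
      ws <- max(1L, pl$mature[1] - 150L)
      we <- min(cfg$genome_length, pl$mature[2] + 150L)
      win <- substr(genome, ws, we)
      if (feat$strand[i] == "-") {
        win <- revcomp_chr(win)
        tag_start <- we - pl$mature[2] + 1L
      } else {
        tag_start <- pl$mature[1] - ws + 1L
      }
      scr <- screen_candidate(win, tag_start, nchar(hp$mature))
      if (scr$pass) { ok <- TRUE; break }
    }
    if (!ok) stop("make_genome: failed to plant a screen-passing novel precursor")
    prec_rows[[length(prec_rows) + 1]] <- data.frame(
      name = feat$id[i], mature_name = paste0(feat$id[i], "-mat"),
      kind = "novel", contig = "chr1", start = pl$start, end = pl$end,
      strand = feat$strand[i],
      mature_gstart = pl$mature[1], mature_gend = pl$mature[2],
      star_gstart = pl$star[1], star_gend = pl$star[2],
      precursor = hp$precursor, mature = hp$mature, star = hp$star,
      mature_start = hp$mature_start, mature_end = hp$mature_end,
      arm = hp$arm, stringsAsFactors = FALSE)
    feat$start[i] <- pl$start
    feat$end[i] <- pl$end
  }
  precursors <- do.call(rbind, prec_rows)

  # annotation features: known precursors (type miRNA) + decoys; novel loci
  # stay unannotated on purpose
  known_feat <- feat[feat$type == "known", , drop = FALSE]
  known_feat$type <- "miRNA"
  decoy_feat <- feat[!(feat$type %in% c("known", "novel")), , drop = FALSE]
  decoy_feat$type <- sub("_$", "", decoy_feat$type)
  features <- rbind(known_feat, decoy_feat)
  rownames(features) <- NULL

  kp <- precursors[precursors$kind == "known", , drop = FALSE]
  reference <- data.frame(
    mature_name = kp$mature_name, mature = kp$mature,
    precursor_name = kp$name, precursor = kp$precursor,
    mature_start = kp$mature_start, mature_end = kp$mature_end,
    stringsAsFactors = FALSE)

  list(genome = c(chr1 = genome), features = features,
       precursors = precursors, reference = reference)
}

# per-stage true abundances; planted fold changes applied multiplicatively.
# Planted miRNAs have their baseline share capped at 0.5% so the library-
# composition shift caused by the planted effects stays small enough for the
# background class to absorb, letting the generator realize every planted
# fold change exactly in expected counts.
#' @noRd
make_abundances <- function(cfg, n_known, n_novel) {
  set.seed(substream_seed(cfg$seed, 2))
  base <- rlnorm(n_known, meanlog = 0, sdlog = cfg$abundance_sdlog)
  if (nrow(cfg$de_spec) > 0) {
    if (any(cfg$de_spec$mirna > n_known) || any(cfg$de_spec$mirna < 1)) {
      stop("de_spec references a nonexistent miRNA index")
    }
    planted <- unique(cfg$de_spec$mirna)
    for (it in 1:20) {
      cap <- 0.005 * sum(base)
      if (all(base[planted] <= cap + 1e-12)) break
      base[planted] <- pmin(base[planted], cap)
    }
  }
  ab <- matrix(rep(base, 3), ncol = 3,
               dimnames = list(NULL, stage_names))
  for (r in seq_len(nrow(cfg$de_spec))) {
    ab[cfg$de_spec$mirna[r], cfg$de_spec$stage[r]] <-
      base[cfg$de_spec$mirna[r]] * 2^cfg$de_spec$log2fc[r]
  }
  nov <- matrix(runif(n_novel * 3, 0.5, 1.5), ncol = 3,
                dimnames = list(NULL, stage_names))
  list(known = ab, novel = nov)
}

#' Build the full synthetic truth object
#'
#' Runs [make_genome()], draws per-stage abundances and computes the expected
#' clean-read counts per planted miRNA, producing the object that
#' [simulate_reads()] consumes.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_truth`.
#' @export
make_truth <- function(cfg) {
  g <- make_genome(cfg)
  n_known <- cfg$n_known_precursors
  n_novel <- cfg$n_novel_precursors
  ab <- make_abundances(cfg, n_known, n_novel)
  clean_frac <- 1 - sum(cfg$contamination_rates)
  # the per-stage miRNA budget scales with the composition shift the planted
  # effects cause, so expected counts realize every planted fold change
  exp_known <- sapply(1:3, function(s) {
    budget <- cfg$library_sizes[s] * clean_frac * cfg$class_mix[["miRNA"]]
    budget * ab$known[, s] / sum(ab$known[, 1])
  })
  colnames(exp_known) <- stage_names
  rownames(exp_known) <-
    g$precursors$mature_name[g$precursors$kind == "known"]
  exp_novel <- sapply(1:3, function(s) {
    budget <- cfg$library_sizes[s] * clean_frac * cfg$class_mix[["novel"]]
    budget * ab$novel[, s] / sum(ab$novel[, s])
  })
  colnames(exp_novel) <- stage_names
  rownames(exp_novel) <- g$precursors$name[g$precursors$kind == "novel"]
  structure(c(g, list(abundances = ab, expected_known = exp_known,
                      expected_novel = exp_novel, config = cfg)),
            class = "synthetic_truth")
}

# vectorised random filler: one big string sliced per read
#' @noRd
slice_random <- function(lens, gc = 0.5) {
  total <- sum(lens)
  if (total == 0) return(character(length(lens)))
  big <- random_seq(total, gc)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  substring(big, starts, ends)
}

# apply iid per-base substitutions to a character vector of inserts
#' @noRd
apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  seqs
}

#' Simulate one stage's FASTQ library with per-read truth labels
#'
#' Reads are insert + 3' adapter + random filler, truncated to the instrument
#' read length, with quality strings drawn from a seeded pool matching the
#' configured Phred model.  Contaminant classes (low-quality, missing 3'
#' adapter, null insert, 5' adapter contaminant, short insert, polyA) are
#' injected at the configured rates and each constructed contaminant is
#' verified against the package's own classifiers so truth labels and
#' cleaning categories agree exactly when `error_rate = 0`.
#'
#' @param cfg a [synthetic_config()].
#' @param truth a [make_truth()] object.
#' @param stage 1 (P), 2 (D1) or 3 (D3).
#' @return list with `reads` (data.frame id/sequence/quality) and `labels`
#'   (data.frame id/category/source).
#' @export
simulate_reads <- function(cfg, truth, stage) {
  stopifnot(stage %in% 1:3)
  set.seed(substream_seed(cfg$seed, 10 + stage))
  n <- cfg$library_sizes[stage]
  rates <- cfg$contamination_rates
  p <- c(rates, clean = 1 - sum(rates))
  n_cat <- drop(rmultinom(1, n, p))
  names(n_cat) <- names(p)

  genome <- truth$genome[[1]]
  glen <- nchar(genome)
  feats <- truth$features
  prec <- truth$precursors
  known <- prec[prec$kind == "known", , drop = FALSE]
  novel <- prec[prec$kind == "novel", , drop = FALSE]

  mix <- cfg$class_mix
  mix <- c(mix, unann = 1 - sum(mix))
  n_class <- drop(rmultinom(1, n_cat[["clean"]], mix))
  names(n_class) <- names(mix)

  # planted fold changes shift the miRNA share of the library; scale the
  # miRNA class budget accordingly and let the unannotated background absorb
  # the difference, so expected per-miRNA counts realize the planted effects
  scale_s <- sum(truth$abundances$known[, stage]) /
    sum(truth$abundances$known[, 1])
  delta <- round(n_class[["miRNA"]] * (scale_s - 1))
  if (delta > n_class[["unann"]]) {
    stop("simulate_reads: background too small to absorb the planted ",
         "composition shift")
  }
  n_class[["miRNA"]] <- n_class[["miRNA"]] + delta
  n_class[["unann"]] <- n_class[["unann"]] - delta

  inserts <- character(0)
  sources <- character(0)

  ## known miRNA reads
  if (n_class[["miRNA"]] > 0) {
    ab <- truth$abundances$known[, stage]
    cnt <- drop(rmultinom(1, n_class[["miRNA"]], ab / sum(ab)))
    ins <- rep(dna(known$mature), cnt)
    src <- rep(paste0("miRNA:", known$mature_name), cnt)
    trim <- runif(length(ins)) < cfg$isomir_rate & nchar(ins) >= 21
    ins[trim] <- substr(ins[trim], 1, nchar(ins[trim]) - 1)
    inserts <- c(inserts, ins)
    sources <- c(sources, src)
  }
  ## novel locus reads (mature-dominant, some star)
  if (n_class[["novel"]] > 0) {
    ab <- truth$abundances$novel[, stage]
    cnt <- drop(rmultinom(1, n_class[["novel"]], ab / sum(ab)))
    for (j in seq_len(nrow(novel))) {
      if (cnt[j] == 0) next
      n_star <- rbinom(1, cnt[j], cfg$star_read_fraction)
      ins <- c(rep(dna(novel$mature[j]), cnt[j] - n_star),
               rep(dna(novel$star[j]), n_star))
      inserts <- c(inserts, ins)
      sources <- c(sources, rep(paste0("novel:", novel$name[j]), cnt[j]))
    }
  }
  ## decoy feature classes
  len_probs <- c(1, 1, 2, 3, 8, 3, 2, 1, 1, 1, 1, 1, 1)
  draw_feature_reads <- function(class_label, feat_type, m, antisense = FALSE) {
    if (m == 0) return(invisible(NULL))
    rows <- feats[feats$type == feat_type, , drop = FALSE]
    pick <- rows[sample(nrow(rows), m, replace = TRUE), , drop = FALSE]
    L <- sample(18:30, m, replace = TRUE, prob = len_probs)
    L <- pmin(L, pick$end - pick$start + 1L)
    off <- floor(runif(m) * (pick$end - pick$start + 2L - L))
    s <- pick$start + off
    ins <- substring(genome, s, s + L - 1L)
    read_strand <- ifelse(rep(antisense, m), chartr("+-", "-+", pick$strand),
                          pick$strand)
    minus <- read_strand == "-"
    ins[minus] <- revcomp_chr(ins[minus])
    inserts <<- c(inserts, ins)
    sources <<- c(sources, rep(class_label, m))
    invisible(NULL)
  }
  draw_feature_reads("rRNA", "rRNA", n_class[["rRNA"]])
  draw_feature_reads("tRNA", "tRNA", n_class[["tRNA"]])
  draw_feature_reads("snRNA", "snRNA", n_class[["snRNA"]])
  draw_feature_reads("snoRNA", "snoRNA", n_class[["snoRNA"]])
  draw_feature_reads("scRNA", "scRNA", n_class[["scRNA"]])
  draw_feature_reads("srpRNA", "srpRNA", n_class[["srpRNA"]])
  draw_feature_reads("repeat", "repeat", n_class[["repeat_"]])
  draw_feature_reads("exon_sense", "exon", n_class[["exon_sense"]])
  draw_feature_reads("exon_antisense", "exon", n_class[["exon_antisense"]],
                     antisense = TRUE)
  draw_feature_reads("intron_sense", "intron", n_class[["intron_sense"]])
  draw_feature_reads("intron_antisense", "intron",
                     n_class[["intron_antisense"]], antisense = TRUE)

  ## unannotated genomic background (outside planted features)
  m <- n_class[["unann"]]
  if (m > 0) {
    all_feat <- rbind(feats[, c("start", "end")],
                      prec[, c("start", "end")])
    got_s <- integer(0); got_l <- integer(0)
    while (length(got_s) < m) {
      need <- (m - length(got_s)) * 2 + 10
      L <- sample(18:30, need, replace = TRUE, prob = len_probs)
      s <- sample.int(glen - 31L, need, replace = TRUE)
      bad <- rep(FALSE, need)
      # reject draws overlapping any planted feature
      ov <- outer(s, all_feat$end, "<=") & outer(s + L - 1L, all_feat$start, ">=")
      bad <- rowSums(ov) > 0
      got_s <- c(got_s, s[!bad])
      got_l <- c(got_l, L[!bad])
    }
    got_s <- got_s[seq_len(m)]; got_l <- got_l[seq_len(m)]
    ins <- substring(genome, got_s, got_s + got_l - 1L)
    minus <- runif(m) < 0.5
    ins[minus] <- revcomp_chr(ins[minus])
    # avoid accidental contaminant classification (e.g. A-rich windows)
    redo <- which(poly_a_like(ins) | adapter5_like(ins, cfg$adapter5))
    for (i in redo) {
      repeat {
        s <- sample.int(glen - 31L, 1)
        cand <- substr(genome, s, s + got_l[i] - 1L)
        if (!poly_a_like(cand) && !adapter5_like(cand, cfg$adapter5) &&
            !any(s <= all_feat$end & s + got_l[i] - 1L >= all_feat$start)) {
          ins[i] <- cand
          break
        }
      }
    }
    inserts <- c(inserts, ins)
    sources <- c(sources, rep("unann", m))
  }

  inserts <- apply_errors(inserts, cfg$error_rate)
  categories <- rep("clean", length(inserts))

  ## contaminant constructions (verified against the package classifiers)
  add <- function(ins, category, source) {
    inserts <<- c(inserts, ins)
    categories <<- c(categories, rep(category, length(ins)))
    sources <<- c(sources, rep(source, length(ins)))
  }
  if (n_cat[["insert_null"]] > 0) {
    add(rep("", n_cat[["insert_null"]]), "insert_null", "contaminant")
  }
  if (n_cat[["adaptor5"]] > 0) {
    L <- sample(18:26, n_cat[["adaptor5"]], replace = TRUE)
    add(substr(rep(cfg$adapter5, n_cat[["adaptor5"]]), 1, L),
        "adaptor5_contaminants", "contaminant")
  }
  if (n_cat[["short"]] > 0) {
    L <- sample(8:17, n_cat[["short"]], replace = TRUE)
    ins <- slice_random(L, cfg$gc_fraction)
    redo <- which(adapter5_like(ins, cfg$adapter5))
    for (i in redo) {
      repeat {
        cand <- random_seq(L[i], cfg$gc_fraction)
        if (!adapter5_like(cand, cfg$adapter5)) { ins[i] <- cand; break }
      }
    }
    add(ins, "smaller_than_18nt", "contaminant")
  }
  if (n_cat[["polyA"]] > 0) {
    L <- sample(18:30, n_cat[["polyA"]], replace = TRUE)
    add(strrep("A", L), "polyA", "contaminant")
  }

  ## assemble clean-style reads: insert + adapter3 + filler
  rl <- cfg$read_length
  tails <- paste0(inserts, cfg$adapter3)
  fill_len <- pmax(0L, rl - nchar(tails))
  reads <- substr(paste0(tails, slice_random(fill_len, 0.5)), 1, rl)

  ## adaptor3_null: pure random reads with no adapter occurrence
  if (n_cat[["adaptor3_null"]] > 0) {
    m3 <- n_cat[["adaptor3_null"]]
    r3 <- slice_random(rep(rl, m3), 0.5)
    redo <- which(!is.na(locate_adapter3(r3, cfg$adapter3)))
    for (i in redo) {
      repeat {
        cand <- random_seq(rl, 0.5)
        if (is.na(locate_adapter3(cand, cfg$adapter3))) { r3[i] <- cand; break }
      }
    }
    reads <- c(reads, r3)
    categories <- c(categories, rep("adaptor3_null", m3))
    sources <- c(sources, rep("contaminant", m3))
  }

  ## quality strings from a seeded pool
  qpool <- quality_pool(rl, cfg$quality_model, 2000L)
  quals <- qpool[sample.int(length(qpool), length(reads), replace = TRUE)]

  ## low-quality reads: genomic read with either an N or too many low scores
  if (n_cat[["low_quality"]] > 0) {
    mq <- n_cat[["low_quality"]]
    s <- sample.int(glen - rl, mq, replace = TRUE)
    rq <- substring(genome, s, s + rl - 1L)
    qq <- qpool[sample.int(length(qpool), mq, replace = TRUE)]
    kind <- sample(1:3, mq, replace = TRUE)
    for (i in seq_len(mq)) {
      if (kind[i] == 1) {
        p <- sample.int(rl, 1)
        substr(rq[i], p, p) <- "N"
      } else if (kind[i] == 2) {
        pos <- sample.int(rl, 5)              # 5 bases below Q10
        for (p in pos) substr(qq[i], p, p) <- rawToChar(as.raw(33 + 5))
      } else {
        pos <- sample.int(rl, 7)              # 7 bases below Q13 (none < 10)
        for (p in pos) substr(qq[i], p, p) <- rawToChar(as.raw(33 + 11))
      }
    }
    reads <- c(reads, rq)
    quals <- c(quals, qq)
    categories <- c(categories, rep("low_quality", mq))
    sources <- c(sources, rep("contaminant", mq))
  }

  perm <- sample(length(reads))
  ids <- sprintf("S%dR%07d", stage, seq_along(reads))
  list(
    reads = data.frame(id = ids, sequence = reads[perm], quality = quals[perm],
                       stringsAsFactors = FALSE),
    labels = data.frame(id = ids, category = categories[perm],
                        source = sources[perm], stringsAsFactors = FALSE)
  )
}

#' @noRd
quality_pool <- function(read_length, quality_model, n_pool = 2000L) {
  q <- matrix(pmin(40L, pmax(20L,
        round(rnorm(read_length * n_pool, quality_model[["mean"]],
                    quality_model[["sd"]])))),
      nrow = read_length)
  apply(q, 2, function(col) intToUtf8(col + 33L))
}

# quick predicate mirrors of the preprocess classifiers, used by the
# generator to guarantee label/category agreement
#' @noRd
poly_a_like <- function(x) {
  a <- vapply(strsplit(toupper(x), ""), function(s) mean(s == "A"), numeric(1))
  a >= 0.8
}

#' @noRd
adapter5_like <- function(x, adapter5) {
  vapply(x, function(s) {
    k <- min(nchar(s), nchar(adapter5))
    if (k == 0) return(FALSE)
    a <- strsplit(substr(s, 1, k), "")[[1]]
    b <- strsplit(substr(adapter5, 1, k), "")[[1]]
    sum(a != b) <= 1
  }, logical(1), USE.NAMES = FALSE)
}

#' Generate the complete synthetic dataset in memory
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_dataset` with the truth object and one
#'   `reads`/`labels` pair per stage.
#' @export
make_dataset <- function(cfg) {
  truth <- make_truth(cfg)
  stages <- lapply(1:3, function(s) simulate_reads(cfg, truth, s))
  names(stages) <- stage_names
  structure(list(truth = truth, stages = stages, config = cfg),
            class = "synthetic_dataset")
}
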