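# End-to-end orchestration: dataset simulation to disk, and the full
# pipeline over on-disk inputs with a report bundle mirroring the standard
# summary tables.

#' Write a synthetic dataset to disk
#'
#' Produces the full file bundle: `genome.fa`, `features.gff3` (1-based,
#' inclusive), miRBase-style `mature.fa`/`hairpin.fa` (U alphabet) with a
#' `mature_map.tsv` window table, one Phred+33 FASTQ per stage, the planted
#' `truth.tsv` precursor table and per-read `read_labels_<stage>.tsv`.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the in-memory [make_dataset()] object.
#' @export
simulate_dataset <- function(cfg, dir) {
  ds <- make_dataset(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- ds$truth

  writeLines(c(">chr1", truth$genome[[1]]), file.path(dir, "genome.fa"))

  feat <- truth$features
  gr <- GenomicRanges::GRanges(
    seqnames = feat$contig,
    ranges = IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand, type = feat$type, ID = feat$id)
  rtracklayer::export(gr, file.path(dir, "features.gff3"), format = "gff3")

  ref <- truth$reference
  writeLines(paste0(">", ref$mature_name, "\n", rna(ref$mature)),
             file.path(dir, "mature.fa"))
  writeLines(paste0(">", ref$precursor_name, "\n", rna(ref$precursor)),
             file.path(dir, "hairpin.fa"))
  write_tsv(ref[, c("mature_name", "precursor_name", "mature_start",
                    "mature_end")],
            file.path(dir, "mature_map.tsv"))

  for (s in 1:3) {
    write_fastq(ds$stages[[s]]$reads,
                file.path(dir, sprintf("reads_%s.fastq", stage_names[s])))
    write_tsv(ds$stages[[s]]$labels,
              file.path(dir, sprintf("read_labels_%s.tsv", stage_names[s])))
  }
  write_tsv(truth$precursors, file.path(dir, "truth.tsv"))
  ek <- data.frame(mirna = rownames(truth$expected_known),
                   truth$expected_known, check.names = FALSE)
  write_tsv(ek, file.path(dir, "expected_known.tsv"))
  invisible(ds)
}

#' Pipeline configuration
#'
#' @param dir directory holding a [simulate_dataset()] bundle; individual
#'   paths may be overridden.
#' @param outdir report output directory.
#' @param genome,features,mature,hairpin,mature_map,fastq input paths
#'   (`fastq` is a named vector, one per stage).
#' @param transcripts optional transcript FASTA for target prediction.
#' @param adapter3,adapter5 adapter sequences.
#' @param mismatches genome-mapping mismatch limit.
#' @param thresholds novel-screen thresholds, see [novel_thresholds()].
#' @param max_loci,min_count candidate-extraction limits.
#' @param p_max optional p-value cutoff for DE classes.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(dir, outdir = file.path(dir, "report"),
                            genome = file.path(dir, "genome.fa"),
                            features = file.path(dir, "features.gff3"),
                            mature = file.path(dir, "mature.fa"),
                            hairpin = file.path(dir, "hairpin.fa"),
                            mature_map = file.path(dir, "mature_map.tsv"),
                            fastq = setNames(
                              file.path(dir, sprintf("reads_%s.fastq",
                                                     stage_names)),
                              stage_names),
                            transcripts = NULL,
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            mismatches = 0L,
                            thresholds = novel_thresholds(),
                            max_loci = 10L, min_count = 5L,
                            p_max = NULL) {
  cfg <- list(genome = genome, features = features, mature = mature,
              hairpin = hairpin, mature_map = mature_map, fastq = fastq,
              transcripts = transcripts, adapter3 = adapter3,
              adapter5 = adapter5, mismatches = mismatches,
              thresholds = thresholds, max_loci = max_loci,
              min_count = min_count, p_max = p_max, outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
read_genome_fa <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @noRd
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$ID)
  } else {
    paste0("feat", seq_along(gr))
  }
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             type = as.character(S4Vectors::mcols(gr)$type),
             id = id, stringsAsFactors = FALSE)
}

#' Run the full pipeline and write the report bundle
#'
#' Executes preprocess, annotation, known-miRNA identification, novel-miRNA
#' screening, differential expression and (optionally) target prediction,
#' writing `table1_style.tsv` .. `table4_style.tsv` plus the per-stage
#' result files and a run manifest into the configured output directory.
#' Fails fast (before writing anything) if any input path is missing.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with every intermediate result.
#' @export
run_pipeline <- function(cfg) {
  t0 <- proc.time()[["elapsed"]]
  inputs <- c(cfg$genome, cfg$features, cfg$mature, cfg$hairpin,
              cfg$mature_map, cfg$fastq, cfg$transcripts)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("run_pipeline: missing input file(s): ",
         paste(missing, collapse = ", "))
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }

  ## preprocess
  libs <- names(cfg$fastq)
  cleaned <- lapply(cfg$fastq, function(p) {
    clean_reads(read_fastq(p), cfg$adapter3, cfg$adapter5)
  })
  table1 <- data.frame(type = cleaned[[1]]$summary$type,
                       stringsAsFactors = FALSE)
  for (lib in libs) {
    s <- cleaned[[lib]]$summary
    table1[[paste0(lib, "_count")]] <- s$count[match(table1$type, s$type)]
    table1[[paste0(lib, "_pct")]] <- s$percent[match(table1$type, s$type)]
  }
  write_tsv(table1, file.path(cfg$outdir, "table1_style.tsv"))
  collapsed <- collapse_tags(lapply(cleaned, `[[`, "inserts"))
  tags <- collapsed$tags
  write_tsv(tags, file.path(cfg$outdir, "tags.tsv"))
  write_tsv(collapsed$histogram, file.path(cfg$outdir, "length_histogram.tsv"))
  clean_totals <- vapply(cleaned, function(x) length(x$inserts), numeric(1))
  tick("preprocess")

  ## mapping + annotation
  genome <- read_genome_fa(cfg$genome)
  features <- read_features_gff3(cfg$features)
  aln <- map_tags(tags$sequence, genome, cfg$mismatches)
  annotation <- classify_tags(tags$sequence, aln, features)
  write_tsv(annotation, file.path(cfg$outdir, "annotation.tsv"))
  table2 <- summarize_annotation(annotation, tags, libs)
  write_tsv(table2, file.path(cfg$outdir, "table2_style.tsv"))
  tick("annotate")

  ## known miRNAs
  reference <- read_mirna_reference(cfg$mature, cfg$hairpin, cfg$mature_map)
  hits <- match_known(tags$sequence, reference)
  table3 <- tally_known(hits, reference, tags, libs)
  write_tsv(table3, file.path(cfg$outdir, "table3_style.tsv"))
  expr_counts <- known_expression(hits, tags, libs)
  write_tsv(expr_counts, file.path(cfg$outdir, "known_expression.tsv"))
  unann_tags <- annotation$tag[annotation$category == "unann"]
  unann_tags <- setdiff(unann_tags, hits$tag)
  edit_counts <- tags$count[match(unann_tags, tags$sequence)]
  edits <- detect_base_edits(unann_tags, reference, edit_counts)
  write_tsv(edits$edits, file.path(cfg$outdir, "base_edits.tsv"))
  fam <- data.frame(mirna = reference$mature_name,
                    family = assign_family(reference$mature_name),
                    stringsAsFactors = FALSE)
  write_tsv(fam, file.path(cfg$outdir, "families.tsv"))
  bias <- lapply(libs, function(lib) {
    idx <- match(hits$tag, tags$sequence)
    position_bias(hits$tag, tags[[lib]][idx])
  })
  names(bias) <- libs
  bias_tab <- do.call(rbind, lapply(libs, function(lib) {
    f <- bias[[lib]]$fractions
    data.frame(library = lib, position = seq_len(nrow(f)), f,
               check.names = FALSE)
  }))
  write_tsv(bias_tab, file.path(cfg$outdir, "position_bias.tsv"))
  tick("mirknown")

  ## novel miRNAs
  unann_df <- tags[tags$sequence %in% unann_tags, c("sequence", "count")]
  cand <- extract_candidates(unann_df, aln, genome,
                             max_loci = cfg$max_loci,
                             min_count = cfg$min_count)
  tag_counts <- setNames(tags$count, tags$sequence)
  novel <- screen_candidates(cand, aln, tag_counts, cfg$thresholds)
  write_tsv(novel[, setdiff(names(novel), "window")],
            file.path(cfg$outdir, "novel_candidates.tsv"))
  passing <- novel[novel$pass, , drop = FALSE]
  if (nrow(passing) > 0) {
    hp_seq <- substr(passing$window, passing$sub_start, passing$sub_end)
    writeLines(paste0(">nov-", seq_len(nrow(passing)), "\n", hp_seq),
               file.path(cfg$outdir, "novel_hairpins.fa"))
    writeLines(paste0(">nov-", seq_len(nrow(passing)), "-mat\n",
                      rna(passing$tag)),
               file.path(cfg$outdir, "novel_mature.fa"))
    # sub-window coordinates are in (possibly reverse-complemented) window
    # space; map back to genomic coordinates per strand
    g_start <- ifelse(passing$strand == "+",
                      passing$win_start + passing$sub_start - 1L,
                      passing$win_end - passing$sub_end + 1L)
    g_end <- ifelse(passing$strand == "+",
                    passing$win_start + passing$sub_end - 1L,
                    passing$win_end - passing$sub_start + 1L)
    bed <- data.frame(chrom = passing$contig,
                      start = g_start - 1L,
                      end = g_end,
                      name = paste0("nov-", seq_len(nrow(passing))),
                      score = 0, strand = passing$strand)
    utils::write.table(bed, file.path(cfg$outdir, "novel_loci.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  tick("mirnovel")

  ## differential expression
  totals <- setNames(as.numeric(clean_totals), libs)
  de <- list()
  pairs <- list(c(libs[1], libs[2]), c(libs[1], libs[3]), c(libs[2], libs[3]))
  for (pr in pairs) {
    key <- paste0(pr[2], "_vs_", pr[1])
    de[[key]] <- de_table(expr_counts, totals, pr[1], pr[2], cfg$p_max)
    write_tsv(de[[key]], file.path(cfg$outdir, paste0("de_", key, ".tsv")))
  }
  up_rows <- do.call(rbind, lapply(names(de), function(k) {
    d <- de[[k]][de[[k]]$de_class == "up", , drop = FALSE]
    if (nrow(d)) cbind(comparison = k, d) else NULL
  }))
  if (is.null(up_rows)) up_rows <- data.frame()
  write_tsv(up_rows, file.path(cfg$outdir, "table4_style.tsv"))

  ne <- sapply(libs, function(lib) {
    normalize_expression(expr_counts[[lib]], totals[[lib]])
  })
  rownames(ne) <- expr_counts$mirna
  top10 <- lapply(libs, function(lib) {
    e <- data.frame(mirna = expr_counts$mirna, ne = ne[, lib])
    top_n_mirnas(e, 10, "ne")
  })
  names(top10) <- libs
  clust <- if (nrow(ne) >= 2) cluster_prep(ne) else NULL
  tick("expression")

  ## optional target prediction
  targets <- NULL
  if (!is.null(cfg$transcripts)) {
    tx <- Biostrings::readBStringSet(cfg$transcripts)
    tx <- setNames(as.character(tx), sub("\\s.*$", "", names(tx)))
    targets <- do.call(rbind, lapply(seq_len(nrow(reference)), function(i) {
      find_targets(reference$mature[i], tx,
                   mirna_name = reference$mature_name[i])
    }))
    write_tsv(targets, file.path(cfg$outdir, "targets.tsv"))
  }
  tick("downstream")

  ## manifest
  cfg_file <- tempfile()
  dput(cfg[setdiff(names(cfg), "thresholds")], cfg_file)
  manifest <- c(
    sprintf("package: mirsat %s",
            as.character(utils::packageVersion("mirsat"))),
    sprintf("R: %s", R.version.string),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_file))),
    sprintf("stage_seconds: %s",
            paste(sprintf("%s=%.1f", names(timings), unlist(timings)),
                  collapse = " ")))
  unlink(cfg_file)
  writeLines(manifest, file.path(cfg$outdir, "manifest.txt"))

  invisible(list(cleaned = cleaned, tags = tags, histogram = collapsed$histogram,
                 clean_totals = totals, alignments = aln,
                 annotation = annotation, table1 = table1, table2 = table2,
                 table3 = table3, reference = reference, hits = hits,
                 expr_counts = expr_counts, edits = edits, families = fam,
                 bias = bias, candidates = novel, de = de, ne = ne,
                 top10 = top10, cluster = clust, targets = targets))
}
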