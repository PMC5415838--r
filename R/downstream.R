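# Seed-complementarity target prediction with Allen-style penalty scoring,
# and relative RT-qPCR quantification.

# complementarity classes for an (miRNA base, target base) pair, both 5'->3'
# in their own strands: the miRNA position i faces target position L - i + 1
#' @noRd
pairing_class <- function(m_base, t_base) {
  duo <- paste0(m_base, t_base)
  ifelse(duo %in% c("AU", "UA", "GC", "CG"), "match",
         ifelse(duo %in% c("GU", "UG"), "wobble", "mismatch"))
}

#' Allen-style penalty score of an ungapped miRNA:site alignment
#'
#' Per-position penalties: Watson-Crick match 0, G:U wobble 0.5, mismatch
#' 1.0; penalties are doubled at miRNA positions 2-13 (the seed-proximal
#' region).  The score is the sum over all positions.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA).
#' @param site target site, 5'->3' on the transcript, same length.
#' @return numeric penalty score (0 = perfect complement).
#' @export
penalty_score <- function(mirna, site) {
  m <- strsplit(rna(mirna), "")[[1]]
  s <- strsplit(rna(site), "")[[1]]
  if (length(m) != length(s)) {
    stop("penalty_score: miRNA and site must have equal length")
  }
  L <- length(m)
  cls <- pairing_class(m, rev(s))
  pen <- c(match = 0, wobble = 0.5, mismatch = 1)[cls]
  dbl <- seq_len(L) >= 2 & seq_len(L) <= 13
  sum(pen * ifelse(dbl, 2, 1))
}

# intermolecular duplex energy under the reference pair model (GC -3.0,
# AU -2.0, GU -1.0 kcal/mol, mismatches free); no intramolecular folding
#' @noRd
duplex_energy <- function(mirna, site) {
  m <- strsplit(rna(mirna), "")[[1]]
  s <- strsplit(rna(site), "")[[1]]
  duo <- paste0(m, rev(s))
  e <- numeric(length(duo))
  e[duo %in% c("GC", "CG")] <- -3
  e[duo %in% c("AU", "UA")] <- -2
  e[duo %in% c("GU", "UG")] <- -1
  sum(e)
}

#' Predict miRNA target sites in transcripts
#'
#' Slides the miRNA along every transcript window of its own length, keeps
#' windows with [penalty_score()] at most `max_score` and duplex energy at
#' most `energy_max` (kcal/mol, same pair model as the folding engine).
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcripts named character vector (or `DNAStringSet`/
#'   `RNAStringSet`) of transcript/3'UTR sequences.
#' @param max_score maximum penalty score (default 4.0).
#' @param energy_max maximum duplex energy (default -10 kcal/mol).
#' @param mirna_name optional name recorded in the output.
#' @return data.frame: `mirna`, `transcript`, `start` (1-based on the
#'   transcript), `score`, `energy`, `site`.
#' @export
find_targets <- function(mirna, transcripts, max_score = 4.0,
                         energy_max = -10, mirna_name = "miRNA") {
  if (methods::is(transcripts, "XStringSet")) {
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  }
  transcripts <- rna(transcripts)
  mirna <- rna(mirna)
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  pen_tab <- c(match = 0, wobble = 0.5, mismatch = 1)
  dbl <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)

  hits <- list()
  for (tx in names(transcripts)) {
    seq_tx <- transcripts[[tx]]
    n <- nchar(seq_tx)
    if (n < L) next
    W <- n - L + 1L
    score <- numeric(W)
    energy <- numeric(W)
    # position i of the miRNA faces transcript position start + L - i
    for (i in seq_len(L)) {
      tb <- substring(seq_tx, seq_len(W) + L - i, seq_len(W) + L - i)
      duo <- paste0(m[i], tb)
      cls <- ifelse(duo %in% c("AU", "UA", "GC", "CG"), "match",
                    ifelse(duo %in% c("GU", "UG"), "wobble", "mismatch"))
      score <- score + pen_tab[cls] * dbl[i]
      energy <- energy +
        ifelse(duo %in% c("GC", "CG"), -3,
               ifelse(duo %in% c("AU", "UA"), -2,
                      ifelse(duo %in% c("GU", "UG"), -1, 0)))
    }
    keep <- which(score <= max_score & energy <= energy_max)
    if (length(keep)) {
      hits[[length(hits) + 1]] <- data.frame(
        mirna = mirna_name, transcript = tx, start = keep,
        score = score[keep], energy = energy[keep],
        site = substring(seq_tx, keep, keep + L - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(mirna = character(), transcript = character(),
                      start = integer(), score = numeric(), energy = numeric(),
                      site = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per condition;
#' `ddCt = dCt_treatment - dCt_control`; relative fold `N = 2^-ddCt`.
#'
#' @param ct_target_treatment,ct_reference_treatment cycle thresholds in the
#'   treatment condition.
#' @param ct_target_control,ct_reference_control cycle thresholds in the
#'   control condition.
#' @return list with `dct_treatment`, `dct_control`, `ddct` and `fold`
#'   (`N = 2^-ddCt`).
#' @export
ddct <- function(ct_target_treatment, ct_reference_treatment,
                 ct_target_control, ct_reference_control) {
  stopifnot(is.finite(ct_target_treatment), is.finite(ct_reference_treatment),
            is.finite(ct_target_control), is.finite(ct_reference_control))
  dct_t <- ct_target_treatment - ct_reference_treatment
  dct_c <- ct_target_control - ct_reference_control
  dd <- dct_t - dct_c
  list(dct_treatment = dct_t, dct_control = dct_c, ddct = dd, fold = 2^-dd)
}
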