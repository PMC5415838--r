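# RNA secondary structure: folding engine wrapper and structure utilities.

#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' Deterministic minimum free energy folding under the package's reference
#' energy model: a base pair contributes GC -3.0, AU -2.0 or GU -1.0
#' kcal/mol per stacked pair, i.e. only when it sits directly on the next
#' pair inward (so a helix of k pairs contributes k-1 stacking energies and
#' isolated pairs are never stabilizing); a pair closing a hairpin loop adds
#' +4.0, a bulge/internal loop +3.0 and a multibranch loop +4.0; unpaired
#' bases are free.  Hairpin loops contain at least 3 unpaired bases and
#' bulge/internal loops at most 30 unpaired bases in total.  The model is
#' intentionally small so that tests
#' can verify the dynamic program against exhaustive structure enumeration;
#' the absolute energy cutoffs used elsewhere in the package (for example the
#' -20 kcal/mol precursor threshold) are interpreted under this same model.
#'
#' @param sequence RNA (or DNA; T is converted to U) sequence, length <= 400.
#' @return an object of class `fold_result`: a list with `sequence`,
#'   `structure` (dot-bracket) and `mfe` (kcal/mol, <= 0).
#' @examples
#' rna_fold("GGGGAAAACCCC")
#' @export
rna_fold <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- rna(sequence)
  if (nchar(s) > 400) {
    stop("rna_fold: sequence longer than 400 nt")
  }
  if (grepl("[^ACGU]", s)) {
    stop("rna_fold: invalid characters (RNA alphabet ACGU required)")
  }
  res <- fold_engine_cpp(s)
  structure(
    list(sequence = s, structure = res$structure, mfe = res$mfe),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sprintf("MFE = %.2f kcal/mol", x$mfe),
      "\n", sep = "")
  invisible(x)
}

#' Pairing table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector; entry i is the partner of base i, or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("pair_table: unbalanced structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      stop("pair_table: invalid character in structure")
    }
  }
  if (length(stack) > 0) stop("pair_table: unbalanced structure")
  pt
}

#' Adjusted MFE and minimal free energy index
#'
#' `AMFE = mfe * 100 / length`; `MFEI = AMFE / (gc_fraction * 100)`.  The
#' MFEI is the classical discriminator between pre-miRNA hairpins and other
#' structured RNAs.
#'
#' @param mfe minimum free energy, kcal/mol (<= 0).
#' @param length sequence length, nt (> 0).
#' @param gc_fraction GC fraction in (0, 1).
#' @return named list with `amfe` and `mfei`.
#' @examples
#' mfei(-42.5, 85, 0.5)   # AMFE -50, MFEI -1
#' @export
mfei <- function(mfe, length, gc_fraction) {
  if (length <= 0) stop("mfei: length must be positive")
  if (any(gc_fraction <= 0) || any(gc_fraction >= 1)) {
    stop("mfei: gc_fraction must be strictly inside (0, 1)")
  }
  amfe <- mfe * 100 / length
  list(amfe = amfe, mfei = amfe / (gc_fraction * 100))
}
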