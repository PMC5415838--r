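# Count normalization, fold changes, the exact two-library count statistic
# (Audic-Claverie), DE classification, clustering prep and ranking.

#' Normalize a count to reads per million with a 0.01 floor
#'
#' `NE = count / clean_total * 1e6`, floored at 0.01 (zero and near-zero
#' counts map to 0.01 so that fold changes stay finite).
#'
#' @param count miRNA read count(s).
#' @param clean_total clean-read total of the library (> 0).
#' @return normalized expression (TPM), >= 0.01.
#' @export
normalize_expression <- function(count, clean_total) {
  if (any(clean_total <= 0)) stop("normalize_expression: clean_total must be > 0")
  if (any(count < 0)) stop("normalize_expression: negative count")
  pmax(count / clean_total * 1e6, 0.01)
}

#' Log2 fold change between two libraries on normalized expression
#'
#' @param x,y counts in libraries A (control) and B (treatment).
#' @param n1,n2 clean-read totals of A and B.
#' @return `log2(NE_B / NE_A)` using floored normalized expression.
#' @examples
#' log2_fold_change(16887, 38687, 5871055, 5922188)   # 1.18
#' @export
log2_fold_change <- function(x, y, n1, n2) {
  log2(normalize_expression(y, n2) / normalize_expression(x, n1))
}

#' Exact two-library count probability mass
#'
#' The probability of observing `y` counts in library 2 given `x` counts in
#' library 1 with clean-read totals N1, N2:
#' `p(y|x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))`,
#' evaluated in log space via extended-precision log-gamma so it is finite,
#' stable for counts up to 1e7 and agrees with exact rational arithmetic to
#' well below 1e-12 relative.
#'
#' @param x count in library 1 (conditioning count).
#' @param y count(s) in library 2.
#' @param n1,n2 clean-read totals.
#' @param log return the log mass.
#' @return probability mass (vectorized over `y`).
#' @export
ac_probability <- function(x, y, n1, n2, log = FALSE) {
  if (any(c(x, y) < 0)) stop("ac_probability: negative counts")
  if (any(c(n1, n2) <= 0)) stop("ac_probability: totals must be positive")
  stopifnot(length(x) == 1)
  ac_mass_cpp(x, as.numeric(y), n2 / n1, log)
}

# sum of ac_probability masses for k in [lo, hi], computed over a window
# wide enough that the truncated tail is far below double precision
#' @noRd
ac_tail_sum <- function(x, lo, hi, n1, n2) {
  if (hi < lo) return(0)
  k <- lo:hi
  sum(ac_probability(x, k, n1, n2))
}

#' Two-sided p-value of the exact two-library count statistic
#'
#' Lower tail `C = sum_{k <= y} p(k|x)`, upper tail
#' `D = sum_{k >= y} p(k|x)`; the two-sided p-value is
#' `min(1, 2 * min(C, D) - p(y|x))`.  Both inclusive tails count the
#' observed outcome, so the doubled minimum double-counts its mass; the
#' mid-style correction removes that double count, keeps p in (0, 1] and
#' makes the statistic near-uniform under a null of proportional Poisson
#' counts.  The smaller tail is summed directly (the mass
#' is concentrated within a few tens of standard deviations of its mean, so
#' summation windows stay short even for counts in the millions) and the
#' other obtained by complement.
#'
#' @param x,y counts in the two libraries.
#' @param n1,n2 clean-read totals.
#' @return p-value in (0, 1].
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  if (length(y) > 1 || length(x) > 1) {
    return(mapply(ac_pvalue, x, y, MoreArgs = list(n1 = n1, n2 = n2)))
  }
  r <- n2 / n1
  mu <- r * (x + 1)                        # mean of the y|x distribution
  sdv <- sqrt(r * (1 + r) * (x + 1))
  w <- 200 + ceiling(30 * sdv)
  mass_y <- ac_probability(x, y, n1, n2)
  if (y <= mu) {
    C <- ac_tail_sum(x, max(0, y - w), y, n1, n2)
    D <- 1 - C + mass_y
  } else {
    D <- ac_tail_sum(x, y, y + w, n1, n2)
    C <- 1 - D + mass_y
  }
  # both tails include y itself; subtract the double-counted point mass
  min(1, 2 * min(C, D) - mass_y)
}

#' Classify differential expression by normalized-expression ratio
#'
#' `up` when the treatment/control NE ratio exceeds 2, `down` when it is at
#' most 1/2, otherwise `equal` (the scatter-plot legend convention).
#'
#' @param ne_control,ne_treatment floored normalized expression values.
#' @return character vector: `"up"`, `"down"` or `"equal"`.
#' @export
classify_de <- function(ne_control, ne_treatment) {
  ratio <- ne_treatment / ne_control
  ifelse(ratio > 2, "up", ifelse(ratio <= 0.5, "down", "equal"))
}

#' Differential-expression table for one library pair
#'
#' @param counts data.frame: `mirna` plus one count column per library.
#' @param totals named clean-read totals (same names as count columns).
#' @param control,treatment library names to compare.
#' @param p_max optional p-value cutoff intersected with the ratio classes
#'   (default `NULL`: classification by ratio only).
#' @return data.frame with counts, NE, log2 fold change (`log2fc`, full
#'   precision; `log2fc_2dp` rounded half-up), `p_value` and `de_class`.
#' @export
de_table <- function(counts, totals, control, treatment, p_max = NULL) {
  x <- counts[[control]]
  y <- counts[[treatment]]
  n1 <- totals[[control]]
  n2 <- totals[[treatment]]
  ne_a <- normalize_expression(x, n1)
  ne_b <- normalize_expression(y, n2)
  lfc <- log2(ne_b / ne_a)
  pv <- ac_pvalue(x, y, n1, n2)
  cls <- classify_de(ne_a, ne_b)
  if (!is.null(p_max)) cls[pv > p_max & cls != "equal"] <- "equal"
  out <- data.frame(mirna = counts$mirna,
                    count_control = x, count_treatment = y,
                    ne_control = ne_a, ne_treatment = ne_b,
                    log2fc = lfc, log2fc_2dp = round_half_up(lfc, 2),
                    p_value = pv, de_class = cls,
                    stringsAsFactors = FALSE)
  out[order(-out$log2fc), , drop = FALSE]
}

#' Prepare an expression matrix for hierarchical clustering
#'
#' Log2 transform, per-row median centering, per-row scaling to unit vector
#' norm, then average-linkage clustering on 1 - Pearson correlation.
#' Constant rows (zero variance after transform) get distance 0 to every
#' other row and are reported.
#'
#' @param mat numeric matrix (miRNA x library) of normalized expression.
#' @return list with `transformed` (matrix) and `tree` (an [stats::hclust]
#'   object), plus `constant_rows`.
#' @export
cluster_prep <- function(mat) {
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("cluster_prep: need at least 2 rows and 2 columns")
  }
  lm <- log2(mat)
  lm <- sweep(lm, 1, apply(lm, 1, median))
  norms <- sqrt(rowSums(lm^2))
  constant <- norms == 0
  lm[!constant, ] <- lm[!constant, , drop = FALSE] / norms[!constant]
  cr <- suppressWarnings(cor(t(lm)))
  d <- 1 - cr
  d[is.na(d)] <- 0      # constant rows: define distance 0
  d[constant, ] <- 0
  d[, constant] <- 0
  diag(d) <- 0
  tree <- hclust(as.dist(d), method = "average")
  list(transformed = lm, tree = tree, constant_rows = which(constant))
}

#' Rank miRNAs by normalized expression
#'
#' @param expr data.frame with `mirna` and the column named in `by`.
#' @param n how many to return.
#' @param by column to rank on.
#' @return the top `n` rows, descending, ties broken by name.
#' @export
top_n_mirnas <- function(expr, n, by) {
  stopifnot(n >= 1)
  ord <- order(-expr[[by]], expr$mirna)
  utils::head(expr[ord, , drop = FALSE], n)
}
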