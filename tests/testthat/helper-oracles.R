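# Independent oracles used across test files.

# --- exhaustive folding oracle -------------------------------------------
# Enumerates every nested structure (pairs span >= 5 so hairpin loops hold
# >= 3 bases) and scores it under the reference energy model: pair energies
# GC -3 / AU -2 / GU -1 contribute only when the pair stacks directly on the
# next pair inward; loop penalties hairpin +4, bulge/internal +3,
# multibranch +4.  Only suitable for short sequences (<= ~18 nt).

oracle_pair_e <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AU", "UA")) return(-2)
  if (key %in% c("GU", "UG")) return(-1)
  NA_real_
}

oracle_structures <- function(s, i, j) {
  if (j - i + 1 < 5) return(list(list()))
  out <- lapply(oracle_structures(s, i + 1, j), identity)
  for (k in (i + 4):j) {
    if (is.na(oracle_pair_e(s[i], s[k]))) next
    left <- oracle_structures(s, i + 1, k - 1)
    right <- if (k + 1 <= j) oracle_structures(s, k + 1, j) else list(list())
    for (L in left) for (R in right) {
      out[[length(out) + 1]] <- c(list(c(i, k)), L, R)
    }
  }
  out
}

oracle_energy <- function(s, pairs) {
  if (length(pairs) == 0) return(0)
  starts <- vapply(pairs, `[`, numeric(1), 1)
  ends <- vapply(pairs, `[`, numeric(1), 2)
  score_pair <- function(i, j) {
    inside <- which(starts > i & ends < j)
    # direct children: not nested in another pair inside (i, j)
    direct <- inside[vapply(inside, function(c1) {
      !any(vapply(inside, function(c2) {
        c2 != c1 && starts[c2] < starts[c1] && ends[c2] > ends[c1]
      }, logical(1)))
    }, logical(1))]
    if (length(direct) == 0) return(4)
    if (length(direct) == 1) {
      k <- starts[direct]; l <- ends[direct]
      child <- score_pair(k, l)
      if (k == i + 1 && l == j - 1) {
        return(oracle_pair_e(s[i], s[j]) + child)
      }
      return(3 + child)
    }
    4 + sum(vapply(direct, function(d) score_pair(starts[d], ends[d]),
                   numeric(1)))
  }
  top <- which(vapply(seq_along(pairs), function(c1) {
    !any(vapply(seq_along(pairs), function(c2) {
      c2 != c1 && starts[c2] < starts[c1] && ends[c2] > ends[c1]
    }, logical(1)))
  }, logical(1)))
  sum(vapply(top, function(t1) score_pair(starts[t1], ends[t1]), numeric(1)))
}

oracle_fold_mfe <- function(seq) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  structs <- oracle_structures(s, 1, length(s))
  min(vapply(structs, function(p) oracle_energy(s, p), numeric(1)))
}

# score a dot-bracket string under the same model (checks the traceback)
oracle_energy_db <- function(seq, db) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  pt <- mirsat::pair_table(db)
  pairs <- lapply(which(pt > seq_along(pt)), function(i) c(i, pt[i]))
  oracle_energy(s, pairs)
}

# --- naive genome mapping oracle -----------------------------------------
oracle_map <- function(tag, genome_str) {
  hits <- list()
  w <- nchar(tag)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tag else rc(tag)
    for (i in seq_len(nchar(genome_str) - w + 1)) {
      if (substr(genome_str, i, i + w - 1) == q) {
        hits[[length(hits) + 1]] <- data.frame(start = i, strand = strand)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), strand = character()))
  }
  do.call(rbind, hits)
}

# --- direct-evaluation oracle for the two-library count mass --------------
# (independent route: plain factorial arithmetic, valid for small counts)
oracle_ac_mass <- function(x, y, n1, n2) {
  r <- n2 / n1
  r^y * factorial(x + y) / (factorial(x) * factorial(y) * (1 + r)^(x + y + 1))
}
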