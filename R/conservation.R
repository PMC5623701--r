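#' Tally the residues at one alignment column
#'
#' Counts each of the 20 amino acids plus the gap at a 1-based column.
#' `X` (unknown/non-canonical residue) is tallied as a gap, so that all
#' downstream statistics are over the canonical alphabet.
#'
#' @param aln A [prot_aln()] alignment.
#' @param index 1-based column index.
#' @return An object of class `column_profile`: list with `counts` (named
#'   integer over the 20 amino acids and `-`), `n_total` and `n_gap`.
#' @export
column_profile <- function(aln, index) {
  if (index < 1L || index > aln$L)
    stop("column index out of range [1, ", aln$L, "]: ", index)
  col <- substr(aln$seqs, index, index)
  col[col == "X"] <- GAP
  counts <- table(factor(col, levels = c(AA20, GAP)))
  counts <- stats::setNames(as.integer(counts), c(AA20, GAP))
  structure(list(counts = counts,
                 n_total = length(col),
                 n_gap = unname(counts[GAP]),
                 index = as.integer(index)),
            class = "column_profile")
}

# all column profiles at once (columns x symbols count matrix)
profile_matrix <- function(aln) {
  m <- as.matrix(aln)
  m[m == "X"] <- GAP
  apply(m, 2, function(col) {
    tab <- table(factor(col, levels = c(AA20, GAP)))
    as.integer(tab)
  })  # (21 symbols) x L
}

#' Identity conservation of a column
#'
#' The most frequent non-gap residue and its percentage of *all* sequences
#' (gapped sequences stay in the denominator, the convention under which
#' the package's census statistics are defined). Ties break alphabetically.
#'
#' @param profile A [column_profile()].
#' @return List with `residue` (`NA` for an all-gap column) and `percent`
#'   (exact, unrounded; 0 for an all-gap column).
#' @export
identity_conservation <- function(profile) {
  cnt <- profile$counts[AA20]
  if (all(cnt == 0L))
    return(list(residue = NA_character_, percent = 0))
  best <- which.max(cnt)   # AA20 is alphabetical, which.max takes first
  list(residue = names(cnt)[best],
       percent = 100 * unname(cnt[best]) / profile$n_total)
}

#' Residue-class similarity of a column
#'
#' Pooled percentage of sequences carrying any member of a physicochemical
#' residue class (e.g. the aliphatic class I/V/L/M), gaps in the
#' denominator.
#'
#' @param profile A [column_profile()].
#' @param members Character vector of class member letters.
#' @return Percent in `[0, 100]`.
#' @export
class_similarity <- function(profile, members) {
  members <- unique(toupper(members))
  if (!length(members) || !all(members %in% AA20))
    stop("class members must be canonical amino acid letters")
  100 * sum(profile$counts[members]) / profile$n_total
}

#' Default residue similarity classes
#'
#' Aliphatic hydrophobic (I, V, L, M), aromatic (F, W, Y) and acid-amide
#' (D, N). Classes may overlap and are freely user-configurable.
#'
#' @return Named list of character vectors.
#' @export
default_residue_classes <- function() {
  list(aliphatic = c("I", "V", "L", "M"),
       aromatic = c("F", "W", "Y"),
       acid_amide = c("D", "N"))
}

#' Identity-conservation census of an alignment
#'
#' Per-column modal residue and conservation percentage, plus counts of
#' columns at >= 80%, >= 60% (including >= 80%) and in \[40%, 60%). Bins
#' are computed on the exact, unrounded percentages; the per-column table
#' carries a rounded percentage for reporting (nearest integer, ties away
#' from zero).
#'
#' @param aln A [prot_aln()] alignment.
#' @param thresholds Descending numeric thresholds, default `c(80, 60, 40)`.
#' @return List with `table` (data.frame: index, residue, percent,
#'   percent_rounded) and `bins` (named counts `ge80`, `ge60`, `b40_60`).
#' @export
conservation_census <- function(aln, thresholds = c(80, 60, 40)) {
  stopifnot(length(thresholds) == 3L, !is.unsorted(rev(thresholds)))
  pm <- profile_matrix(aln)[seq_along(AA20), , drop = FALSE]
  n <- length(aln$ids)
  best <- apply(pm, 2, which.max)
  pct <- 100 * pm[cbind(best, seq_len(aln$L))] / n
  residue <- AA20[best]
  residue[colSums(pm) == 0L] <- NA_character_
  pct[colSums(pm) == 0L] <- 0
  tab <- data.frame(index = seq_len(aln$L), residue = residue,
                    percent = pct,
                    percent_rounded = round_half_away(pct),
                    stringsAsFactors = FALSE)
  bins <- c(ge80 = sum(pct >= thresholds[1]),
            ge60 = sum(pct >= thresholds[2]),
            b40_60 = sum(pct >= thresholds[3] & pct < thresholds[2]))
  list(table = tab, bins = bins)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Residue-class similarity census
#'
#' For every column not already identity-conserved at the threshold, the
#' best class similarity over a class set; returns the columns whose best
#' class reaches the threshold, with the winning class.
#'
#' @param aln A [prot_aln()] alignment.
#' @param class_set Named list of residue classes, default
#'   [default_residue_classes()].
#' @param threshold Similarity threshold in percent (default 60).
#' @return data.frame: index, class, class_percent, identity_percent.
#' @export
similarity_census <- function(aln, class_set = default_residue_classes(),
                              threshold = 60) {
  if (!length(class_set)) stop("class_set must be non-empty")
  cen <- conservation_census(aln)$table
  pm <- profile_matrix(aln)[seq_along(AA20), , drop = FALSE]
  rownames(pm) <- AA20
  n <- length(aln$ids)
  class_pct <- vapply(class_set, function(members)
    100 * colSums(pm[members, , drop = FALSE]) / n, numeric(aln$L))
  class_pct <- matrix(class_pct, nrow = aln$L,
                      dimnames = list(NULL, names(class_set)))
  eligible <- cen$percent < threshold
  best <- apply(class_pct, 1, which.max)
  best_pct <- class_pct[cbind(seq_len(aln$L), best)]
  keep <- eligible & best_pct >= threshold
  data.frame(index = which(keep),
             class = colnames(class_pct)[best[keep]],
             class_percent = best_pct[keep],
             identity_percent = cen$percent[keep],
             stringsAsFactors = FALSE)
}
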