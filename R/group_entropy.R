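# Group entropy vs family entropy scan: per column, the Kullback-Leibler
# divergence of a group's pseudocounted residue distribution from the
# complement groups' distribution (group entropy, GE) and of the
# family-wide distribution from a background (family entropy, FE).
# Group-specific conserved sites have high GE and low FE.

#' Parameters for the group-entropy scan
#'
#' @param beta Pseudocount mass spread over the background (default 1.0):
#'   group frequencies are `(n_a + beta * q_a) / (N_nongap + beta)`.
#' @param q Background distribution over the 20 residues (default uniform).
#' @param theta_g Group-entropy selection threshold in bits (default 10).
#' @param theta_f Family-entropy ceiling in bits (default 3).
#' @param gap_max Maximum tolerated gap fraction, within the group and
#'   within its complement, before a column is marked unscored (default
#'   0.5; set 0 for the strict "any gap excludes the column" rule).
#' @param mode `"threshold"` selects columns with `GE >= theta_g` and
#'   `FE <= theta_f`; `"top_k"` selects the top `k` columns by GE among
#'   those with `FE <= theta_f`.
#' @param top_k Number of columns per group in `top_k` mode (default 10).
#' @return List of class `gent_params`.
#' @export
gent_params <- function(beta = 1.0,
                        q = background_distribution("uniform"),
                        theta_g = 10.0, theta_f = 3.0, gap_max = 0.5,
                        mode = c("threshold", "top_k"), top_k = 10L) {
  mode <- match.arg(mode)
  stopifnot(beta >= 0, theta_f >= 0, gap_max >= 0, gap_max <= 1,
            top_k >= 1L)
  check_distribution(q)
  if (any(q <= 0)) stop("background q must be strictly positive")
  structure(list(beta = beta, q = q, theta_g = theta_g, theta_f = theta_f,
                 gap_max = gap_max, mode = mode, top_k = as.integer(top_k)),
            class = "gent_params")
}

# residue counts at a column for a set of row indices of the alignment
# matrix (gaps and X excluded)
.residue_counts <- function(m, rows, j) {
  col <- m[rows, j]
  col <- col[col %in% AA20]
  tab <- tabulate(match(col, AA20), nbins = 20L)
  stats::setNames(tab, AA20)
}

#' Pseudocounted residue frequencies of one group at one column
#'
#' `f_a = (n_a + beta * q_a) / (N_nongap + beta)` where `n_a` counts the
#' residue among the group's non-gap members at the column.
#'
#' @param aln A [prot_aln()] alignment.
#' @param partition A [group_partition()].
#' @param group Group label.
#' @param index 1-based column index.
#' @param beta Pseudocount mass.
#' @param q Background distribution.
#' @return Named numeric 20-vector summing to 1.
#' @export
group_frequencies <- function(aln, partition, group, index, beta = 1.0,
                              q = background_distribution("uniform")) {
  ids <- group_ids(partition, group)
  if (!length(ids)) stop("empty group: ", group)
  m <- as.matrix(aln)
  cnt <- .residue_counts(m, match(ids, aln$ids), index)
  (cnt + beta * q) / (sum(cnt) + beta)
}

.kl_bits <- function(f, r) {
  nz <- f > 0
  sum(f[nz] * log2(f[nz] / r[nz]))
}

#' Group entropy of one column for one group (bits)
#'
#' KL divergence of the group's pseudocounted residue distribution from
#' the distribution of all sequences *not* in the group. Returns `NA` with
#' attribute `excluded = TRUE` when the gap fraction in the group or in
#' its complement exceeds `gap_max` (an explicit unscored marker, never a
#' silent zero).
#'
#' @param aln A [prot_aln()] alignment.
#' @param partition A [group_partition()] with at least two groups.
#' @param group Group label.
#' @param index 1-based column index.
#' @param params A [gent_params()] object.
#' @return Group entropy in bits, or `NA` when unscored.
#' @export
group_entropy <- function(aln, partition, group, index,
                          params = gent_params()) {
  scan <- gent_scan(aln, partition, params, columns = index)
  rec <- scan[scan$group == group & scan$index == index, ]
  if (rec$excluded) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    return(out)
  }
  rec$group_entropy
}

#' Family entropy of one column (bits)
#'
#' KL divergence of the family-wide pseudocounted residue distribution
#' from the background `q`: high values mean the column is conserved
#' across the whole family.
#'
#' @inheritParams group_entropy
#' @return Family entropy in bits, or `NA` when the family-wide non-gap
#'   count is zero.
#' @export
family_entropy <- function(aln, index, params = gent_params()) {
  m <- as.matrix(aln)
  cnt <- .residue_counts(m, seq_along(aln$ids), index)
  if (sum(cnt) == 0L) return(NA_real_)
  f <- (cnt + params$beta * params$q) / (sum(cnt) + params$beta)
  .kl_bits(f, params$q)
}

# up to two modal residues of a count vector; the runner-up is reported
# only when its frequency among counted residues reaches min_frac
.common_residues <- function(cnt, min_frac = 0.25) {
  n <- sum(cnt)
  if (n == 0L) return(NA_character_)
  ord <- order(-cnt, names(cnt))
  out <- names(cnt)[ord[1]]
  if (cnt[ord[2]] / n >= min_frac) out <- c(out, names(cnt)[ord[2]])
  paste(out, collapse = ",")
}

#' Group-entropy scan of an alignment
#'
#' For every group and every column, computes group entropy (against the
#' complement groups), family entropy (against the background), the
#' group's modal residue, and the modal residue(s) of each other group (a
#' runner-up is added when it reaches 25% of the other group's residues).
#' Columns whose gap fraction exceeds `gap_max` in the group or complement
#' are kept in the output flagged `excluded` with `NA` entropies. Records
#' are sorted per group by descending group entropy, ties by ascending
#' index.
#'
#' @param aln A [prot_aln()] alignment.
#' @param partition A [group_partition()] with >= 2 groups.
#' @param params A [gent_params()] object.
#' @param columns Optional subset of column indices (default all).
#' @return data.frame: group, index, group_entropy, family_entropy,
#'   highest_group_residue, common_<other group> columns, excluded,
#'   selected.
#' @export
gent_scan <- function(aln, partition, params = gent_params(),
                      columns = seq_len(aln$L)) {
  validate_partition(partition, aln)
  if (length(partition$groups) < 2L)
    stop("group entropy needs at least 2 groups (no complement otherwise)")
  m <- as.matrix(aln)
  m[m == "X"] <- GAP
  groups <- partition$groups
  rows <- lapply(groups, function(g) match(group_ids(partition, g),
                                           aln$ids))
  names(rows) <- groups

  # per-group residue count array: group x residue x column
  counts <- lapply(rows, function(rr) {
    sub <- m[rr, , drop = FALSE]
    vapply(columns, function(j) {
      col <- sub[, j]
      tabulate(match(col[col != GAP], AA20), nbins = 20L)
    }, integer(20))  # 20 x |columns|
  })
  sizes <- vapply(rows, length, 0L)
  nongap <- vapply(counts, colSums, numeric(length(columns)))
  nongap <- matrix(nongap, nrow = length(columns),
                   dimnames = list(NULL, groups))

  beta <- params$beta; q <- params$q
  fam_cnt <- Reduce(`+`, counts)                    # 20 x |columns|
  fam_tot <- colSums(fam_cnt)
  fe <- vapply(seq_along(columns), function(jj) {
    if (fam_tot[jj] == 0) return(NA_real_)
    f <- (fam_cnt[, jj] + beta * q) / (fam_tot[jj] + beta)
    .kl_bits(f, q)
  }, 0)

  out <- list()
  for (g in groups) {
    others <- setdiff(groups, g)
    comp_cnt <- Reduce(`+`, counts[others])         # 20 x |columns|
    comp_size <- sum(sizes[others])
    gap_g <- 1 - nongap[, g] / sizes[g]
    gap_c <- 1 - colSums(comp_cnt) / comp_size
    excluded <- gap_g > params$gap_max | gap_c > params$gap_max |
      nongap[, g] == 0 | colSums(comp_cnt) == 0
    ge <- rep(NA_real_, length(columns))
    modal <- rep(NA_character_, length(columns))
    for (jj in seq_along(columns)) {
      if (excluded[jj]) next
      cg <- counts[[g]][, jj]
      f <- (cg + beta * q) / (sum(cg) + beta)
      r <- (comp_cnt[, jj] + beta * q) / (sum(comp_cnt[, jj]) + beta)
      ge[jj] <- .kl_bits(f, r)
      modal[jj] <- AA20[order(-cg, AA20)[1]]
    }
    rec <- data.frame(group = g, index = columns, group_entropy = ge,
                      family_entropy = fe,
                      highest_group_residue = modal,
                      stringsAsFactors = FALSE)
    for (o in groups) {
      rec[[paste0("common_", o)]] <- if (o == g) NA_character_ else
        vapply(seq_along(columns), function(jj)
          .common_residues(stats::setNames(counts[[o]][, jj], AA20)), "")
    }
    rec$excluded <- excluded
    sel <- rep(FALSE, nrow(rec))
    elig <- !excluded & !is.na(fe) & fe <= params$theta_f
    if (params$mode == "threshold") {
      sel[elig & ge >= params$theta_g] <- TRUE
    } else {
      cand <- which(elig)
      cand <- cand[order(-ge[cand], columns[cand])]
      sel[utils::head(cand, params$top_k)] <- TRUE
    }
    rec$selected <- sel
    rec <- rec[order(is.na(rec$group_entropy), -xtfrm(rec$group_entropy),
                     rec$index), ]
    out[[g]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
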