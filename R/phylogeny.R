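# Distance-based phylogenetics: gap-fraction trimming, maximum-likelihood
# pairwise distances under the Jones-Taylor-Thornton (JTT) model,
# neighbor joining, column bootstrap and majority-rule consensus.

#' Trim heavily gapped alignment columns
#'
#' Removes columns whose gap fraction (gaps and X pooled) exceeds the
#' threshold, the pre-phylogeny cleaning step.
#'
#' @param aln A [prot_aln()] alignment.
#' @param gap_fraction_max Maximum tolerated gap fraction (default 0.8).
#' @return List with `alignment` (trimmed [prot_aln()]) and `index_map`
#'   (integer vector: trimmed column -> original 1-based column).
#' @export
trim_alignment <- function(aln, gap_fraction_max = 0.8) {
  pm <- profile_matrix(aln)
  gapf <- pm[21L, ] / length(aln$ids)
  keep <- which(gapf <= gap_fraction_max)
  if (!length(keep))
    stop("all columns exceed the gap threshold; nothing left to analyze")
  m <- as.matrix(aln)[, keep, drop = FALSE]
  seqs <- apply(m, 1, paste, collapse = "")
  list(alignment = prot_aln(stats::setNames(seqs, aln$ids)),
       index_map = keep)
}

.as_phydat <- function(aln) {
  m <- as.matrix(aln)
  m[m == "X"] <- "-"
  phangorn::phyDat(m, type = "AA")
}

#' Pairwise ML distance matrix under the JTT model
#'
#' Maximum-likelihood evolutionary distances (expected substitutions per
#' site) for every sequence pair, maximizing the site likelihood under the
#' JTT rate matrix; gaps are treated as missing data. Distances are capped
#' at `d_max` (with a warning) when the optimizer runs away on saturated
#' pairs.
#'
#' @param aln A [prot_aln()] alignment (usually trimmed).
#' @param d_max Distance cap in substitutions/site (default 10).
#' @return A `dist` object over the sequence ids.
#' @export
jtt_distance_matrix <- function(aln, d_max = 10) {
  d <- phangorn::dist.ml(.as_phydat(aln), model = "JTT")
  if (any(!is.finite(d) | d > d_max)) {
    warning("distance(s) capped at d_max = ", d_max)
    d[!is.finite(d) | d > d_max] <- d_max
  }
  d
}

#' JTT distance between two sequences
#'
#' @param seq_i,seq_j Aligned residue strings of equal length (gaps
#'   allowed).
#' @param d_max Distance cap (default 10).
#' @return ML distance in substitutions/site; 0 for identical sequences.
#' @export
jtt_distance <- function(seq_i, seq_j, d_max = 10) {
  aln <- prot_aln(c(i = seq_i, j = seq_j))
  m <- as.matrix(aln)
  ok <- m[1, ] %in% AA20 & m[2, ] %in% AA20
  if (!any(ok))
    stop("sequences share no co-non-gap site; distance undefined")
  as.numeric(jtt_distance_matrix(aln, d_max))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (exact on additive distances);
#' negative branch lengths, which can arise on non-additive input, are
#' clamped to zero.
#'
#' @param d A `dist` object or symmetric distance matrix (>= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Column-bootstrap neighbor-joining trees
#'
#' Each replicate resamples the alignment columns with replacement
#' (replicate `i` is seeded with `seed + i`, so the list is fully
#' reproducible and individual replicates can be regenerated in
#' isolation), recomputes JTT distances and builds an NJ tree.
#'
#' @param aln A [prot_aln()] alignment (trim first; see
#'   [trim_alignment()]).
#' @param n Number of replicates (default 250, the conventional NJ
#'   bootstrap depth).
#' @param seed Integer seed.
#' @param d_max Distance cap passed to [jtt_distance_matrix()].
#' @return List of `phylo` trees (empty for `n = 0`).
#' @export
bootstrap_trees <- function(aln, n = 250L, seed = 1L, d_max = 10) {
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) {
    set.seed((seed + i) %% .Machine$integer.max)
    cols <- sample.int(aln$L, aln$L, replace = TRUE)
    m <- as.matrix(aln)[, cols, drop = FALSE]
    boot <- prot_aln(stats::setNames(apply(m, 1, paste, collapse = ""),
                                     aln$ids))
    neighbor_joining(jtt_distance_matrix(boot, d_max))
  })
}

# canonical bipartition key of a set of leaves, relative to all labels:
# the side not containing the alphabetically first label, sorted
.split_key <- function(leaves, all_labels) {
  first <- min(all_labels)
  side <- if (first %in% leaves) setdiff(all_labels, leaves) else leaves
  paste(sort(side), collapse = "|")
}

# frequency table of non-trivial bipartitions in a list of trees
.split_frequencies <- function(trees) {
  labels <- sort(trees[[1]]$tip.label)
  keys <- lapply(trees, function(tr) {
    if (!setequal(tr$tip.label, labels))
      stop("trees have mismatched leaf sets")
    pp <- ape::prop.part(tr)
    ks <- vapply(pp, function(cl) {
      leaves <- attr(pp, "labels")[cl]
      if (length(leaves) <= 1L || length(leaves) >= length(labels) - 1L)
        return(NA_character_)
      .split_key(leaves, labels)
    }, "")
    unique(ks[!is.na(ks)])
  })
  table(unlist(keys))
}

#' Majority-rule consensus tree with split supports
#'
#' Retains exactly the bipartitions present in more than half of the input
#' trees (strict majority: a split in exactly 50% of trees is dropped) and
#' annotates each retained internal edge with its support,
#' `100 x frequency`, as node labels.
#'
#' @param trees List of `phylo` trees over identical leaf sets.
#' @param p Retention proportion (default 0.5, strict majority).
#' @return A `phylo` consensus tree with `node.label` supports in
#'   `(50, 100]`.
#' @export
majority_consensus <- function(trees, p = 0.5) {
  if (!length(trees)) stop("need at least one tree")
  if (length(trees) == 1L) {
    tr <- trees[[1]]
    tr$node.label <- rep("100", tr$Nnode)
    return(tr)
  }
  freqs <- .split_frequencies(trees)
  cons <- ape::consensus(trees, p = p, check.labels = TRUE)
  labels <- sort(cons$tip.label)
  n_tip <- length(cons$tip.label)
  node.label <- character(cons$Nnode)
  for (node in seq_len(cons$Nnode) + n_tip) {
    tips <- ape::extract.clade(cons, node)$tip.label
    if (length(tips) >= n_tip) { node.label[node - n_tip] <- ""; next }
    key <- .split_key(tips, labels)
    f <- if (key %in% names(freqs)) as.integer(freqs[[key]]) else NA_integer_
    node.label[node - n_tip] <-
      if (is.na(f)) "" else format(100 * f / length(trees))
  }
  cons$node.label <- node.label
  cons
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file (internal node labels are parsed as
#'   support values).
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

#' Parse a Newick string
#' @param text Newick string.
#' @return A `phylo` tree.
#' @export
parse_newick <- function(text) {
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, "')')")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree in string")
  tr
}

#' Write a tree as Newick
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
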