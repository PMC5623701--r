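# Simplified evolutionary trace: cut a UPGMA dendrogram of the sequences
# into P subgroups and flag columns that are invariant inside every
# subgroup; such columns are additionally "group-specific" when at least
# two subgroups carry different residues.

#' UPGMA dendrogram of aligned sequences
#'
#' Average-linkage clustering of the alignment's pairwise JTT distances,
#' the ultrametric dendrogram that the trace partitions cut.
#'
#' @param d A `dist` object or symmetric distance matrix over the
#'   sequences (e.g. from [jtt_distance_matrix()]).
#' @return An `hclust` object.
#' @export
upgma_dendrogram <- function(d) {
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Cut a dendrogram into P trace subgroups
#'
#' Cutting at the `P - 1` greatest merge heights yields exactly `P`
#' subtrees. Subgroups are returned sorted by their alphabetically first
#' leaf, members sorted by name, so the partition is deterministic.
#'
#' @param dendrogram An `hclust` object (see [upgma_dendrogram()]).
#' @param P Number of subgroups, `1 <= P <= number of leaves`.
#' @return List of class `trace_partition`: character vectors of leaf ids.
#' @export
partition_tree <- function(dendrogram, P) {
  n <- length(dendrogram$labels)
  if (P < 1L || P > n)
    stop("P must be between 1 and the number of leaves (", n, ")")
  cl <- stats::cutree(dendrogram, k = P)
  subgroups <- split(names(cl), cl)
  subgroups <- lapply(subgroups, sort)
  subgroups <- subgroups[order(vapply(subgroups, `[`, "", 1L))]
  names(subgroups) <- NULL
  structure(subgroups, class = "trace_partition", P = as.integer(P))
}

#' Trace and group-specific residues under a partition
#'
#' A column is a *trace* column when every subgroup is internally
#' invariant there; by default a gap (or X) inside a subgroup breaks its
#' invariance. A trace column is additionally *group-specific* when at
#' least two subgroups carry different residues.
#'
#' @param aln A [prot_aln()] alignment.
#' @param partition A [partition_tree()] result (or any list of disjoint
#'   leaf-id sets covering the alignment).
#' @param ignore_gaps If `TRUE`, gaps are dropped before testing
#'   invariance instead of breaking it (a fully gapped subgroup then
#'   counts as invariant with no residue).
#' @return data.frame: index, trace, group_specific, and one residue
#'   column per subgroup (`NA` when the subgroup is not invariant there).
#' @export
trace_residues <- function(aln, partition, ignore_gaps = FALSE) {
  leaves <- unlist(partition)
  if (anyDuplicated(leaves) || !all(leaves %in% aln$ids))
    stop("partition must consist of disjoint subsets of alignment ids")
  m <- as.matrix(aln)
  m[m == "X"] <- GAP
  P <- length(partition)
  res_mat <- matrix(NA_character_, nrow = aln$L, ncol = P)
  inv_mat <- matrix(FALSE, nrow = aln$L, ncol = P)
  for (k in seq_len(P)) {
    sub <- m[match(partition[[k]], aln$ids), , drop = FALSE]
    for (j in seq_len(aln$L)) {
      col <- sub[, j]
      if (ignore_gaps) col <- col[col != GAP]
      u <- unique(col)
      if (length(u) == 1L && (length(col) == 0L || u[1] != GAP)) {
        inv_mat[j, k] <- TRUE
        if (length(col)) res_mat[j, k] <- u[1]
      } else if (length(u) == 0L) {
        inv_mat[j, k] <- TRUE    # fully gapped subgroup, ignore_gaps mode
      }
    }
  }
  trace <- rowSums(inv_mat) == P
  gs <- trace & apply(res_mat, 1, function(r)
    length(unique(r[!is.na(r)])) >= 2L)
  out <- data.frame(index = seq_len(aln$L), trace = trace,
                    group_specific = gs, stringsAsFactors = FALSE)
  colnames(res_mat) <- paste0("subgroup_", seq_len(P))
  cbind(out, as.data.frame(res_mat, stringsAsFactors = FALSE))
}
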