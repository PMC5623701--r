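# Column conservation estimators: Jensen-Shannon divergence, property
# entropy, von Neumann entropy, relative entropy, Shannon entropy and sum
# of pairs, each oriented so that higher = more conserved, swept over
# background distributions and BLOSUM matrices with consensus intersection.

BACKGROUND_NAMES <- c("blosum62", "swissprot", "pf")
MATRIX_NAMES <- c("blosum62", "blosum35", "blosum40", "blosum45",
                  "blosum50", "blosum80", "blosum100")
ESTIMATOR_NAMES <- c("js_divergence", "property_entropy", "vn_entropy",
                     "relative_entropy", "shannon_entropy", "sum_of_pairs")

# cache for bundled data parsed at first use
.gc_cache <- new.env(parent = emptyenv())

#' Amino acid background distribution
#'
#' Built-in compositions: `blosum62` (the matrix's marginal frequencies),
#' `swissprot` (Swiss-Prot database composition), `pf` (Pfam composition)
#' and `uniform`. Frequencies are strictly positive and renormalized to
#' sum to 1.
#'
#' @param name One of `"blosum62"`, `"swissprot"`, `"pf"`, `"uniform"`.
#' @return Named numeric 20-vector in the package's alphabetical residue
#'   order.
#' @export
background_distribution <- function(name = c("blosum62", "swissprot", "pf",
                                             "uniform")) {
  name <- match.arg(name)
  if (name == "uniform")
    return(stats::setNames(rep(1 / 20, 20), AA20))
  key <- paste0("bg_", name)
  if (is.null(.gc_cache[[key]])) {
    path <- system.file("extdata", "backgrounds.tsv", package = "groupcons")
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    q <- stats::setNames(tab[[name]], tab$aa)[AA20]
    stopifnot(all(q > 0))
    .gc_cache[[key]] <- q / sum(q)
  }
  .gc_cache[[key]]
}

#' BLOSUM substitution matrix
#'
#' Returns the 20x20 score matrix for one of the seven supported BLOSUM
#' variants, restricted to the canonical residues in the package's
#' alphabetical order. BLOSUM45/50/62/80/100 come from Biostrings;
#' BLOSUM35/40 are bundled with the package.
#'
#' @param name One of `"blosum35"`, `"blosum40"`, `"blosum45"`,
#'   `"blosum50"`, `"blosum62"`, `"blosum80"`, `"blosum100"`.
#' @return Symmetric numeric 20x20 matrix.
#' @export
substitution_matrix <- function(name = MATRIX_NAMES) {
  name <- match.arg(name)
  key <- paste0("mat_", name)
  if (!is.null(.gc_cache[[key]])) return(.gc_cache[[key]])
  if (name %in% c("blosum35", "blosum40")) {
    path <- system.file("extdata", paste0(toupper(name), ".txt"),
                        package = "groupcons")
    lines <- grep("^\\s*#", readLines(path), invert = TRUE, value = TRUE)
    lines <- lines[nzchar(trimws(lines))]
    cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    body <- do.call(rbind, lapply(lines[-1], function(ln)
      strsplit(trimws(ln), "\\s+")[[1]]))
    M <- matrix(as.numeric(body[, -1]), nrow = nrow(body),
                dimnames = list(body[, 1], cols))
  } else {
    env <- new.env()
    utils::data(list = toupper(name), package = "Biostrings", envir = env)
    M <- env[[toupper(name)]]
  }
  M <- M[AA20, AA20]
  stopifnot(isSymmetric(unname(M)))
  .gc_cache[[key]] <- M
  M
}

#' Similarity transform of a substitution matrix
#'
#' Rescales scores to `[0, 1]` by `(M - min M) / (max M - min M)` and then
#' normalizes to a unit diagonal via `S_ab / sqrt(S_aa * S_bb)` (clamped at
#' 1). Used by the von Neumann entropy and sum-of-pairs estimators, which
#' require a non-negative similarity with `S_aa = 1`.
#'
#' @param M Symmetric substitution score matrix (see
#'   [substitution_matrix()]).
#' @return Symmetric 20x20 similarity matrix with unit diagonal, values in
#'   `[0, 1]`.
#' @export
similarity_transform <- function(M) {
  S <- (M - min(M)) / (max(M) - min(M))
  d <- sqrt(diag(S))
  S <- S / outer(d, d)
  S <- (S + t(S)) / 2
  pmin(S, 1)
}

check_distribution <- function(p, tol = 1e-8) {
  if (length(p) != 20L || any(p < 0) || abs(sum(p) - 1) > tol)
    stop("p must be a 20-vector of non-negative frequencies summing to 1")
  invisible(p)
}

#' Non-gap residue frequencies of a column profile
#'
#' Frequencies over the 20 amino acids among non-gap residues, with a small
#' pseudocount added to every residue and renormalized so logarithms stay
#' finite.
#'
#' @param profile A [column_profile()].
#' @param pseudocount Pseudo-frequency added per residue (default `1e-6`).
#' @return Named numeric 20-vector, or `NULL` for an all-gap column.
#' @export
column_frequencies <- function(profile, pseudocount = 1e-6) {
  cnt <- profile$counts[AA20]
  n <- sum(cnt)
  if (n == 0L) return(NULL)
  p <- cnt / n + pseudocount
  p / sum(p)
}

#' Shannon entropy of a residue distribution (bits)
#'
#' @param p Residue distribution (20-vector summing to 1).
#' @return Entropy in bits, in `[0, log2(20)]`. The conservation score used
#'   by the estimator sweep is `log2(20) - H`.
#' @export
shannon_entropy <- function(p) {
  check_distribution(p)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Kullback-Leibler relative entropy (bits)
#'
#' `RE(p, q) = sum p_a log2(p_a / q_a)`; non-negative, zero iff `p == q`.
#'
#' @param p Residue distribution.
#' @param q Strictly positive background distribution.
#' @return Relative entropy in bits.
#' @export
relative_entropy <- function(p, q) {
  check_distribution(p)
  check_distribution(q)
  if (any(q <= 0)) stop("background q must be strictly positive")
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence (bits)
#'
#' `JSD = lambda RE(p, r) + (1 - lambda) RE(q, r)` with
#' `r = lambda p + (1 - lambda) q`; bounded by 1 bit at `lambda = 0.5`.
#'
#' @param p,q Residue distributions.
#' @param lambda Mixing weight in `(0, 1)`, default 0.5.
#' @return Divergence in bits.
#' @export
js_divergence <- function(p, q, lambda = 0.5) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  check_distribution(p)
  check_distribution(q)
  r <- lambda * p + (1 - lambda) * q
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  lambda * kl(p, r) + (1 - lambda) * kl(q, r)
}

#' Default physicochemical partition of the 20 amino acids
#'
#' Six disjoint classes: aliphatic+C `{A,V,L,I,M,C}`, aromatic `{F,W,Y,H}`,
#' polar `{S,T,N,Q}`, basic `{K,R}`, acidic `{D,E}`, special `{G,P}`.
#'
#' @return Named list of character vectors covering all 20 residues.
#' @export
default_property_partition <- function() {
  list(aliphatic = c("A", "V", "L", "I", "M", "C"),
       aromatic = c("F", "W", "Y", "H"),
       polar = c("S", "T", "N", "Q"),
       basic = c("K", "R"),
       acidic = c("D", "E"),
       special = c("G", "P"))
}

#' Property entropy of a residue distribution (bits)
#'
#' Shannon entropy after aggregating the distribution over a disjoint
#' physicochemical partition of the 20 residues. The conservation score
#' used by the sweep is `log2(K) - H` for a K-class partition.
#'
#' @param p Residue distribution.
#' @param partition Disjoint covering partition, default
#'   [default_property_partition()].
#' @return Entropy in bits, in `[0, log2(K)]`.
#' @export
property_entropy <- function(p, partition = default_property_partition()) {
  check_distribution(p)
  members <- unlist(partition)
  if (anyDuplicated(members) || !setequal(members, AA20))
    stop("partition must cover all 20 amino acids disjointly")
  pc <- vapply(partition, function(m) sum(p[m]), 0)
  nz <- pc > 0
  -sum(pc[nz] * log2(pc[nz]))
}

#' Mean pairwise similarity of a column (sum of pairs)
#'
#' Average similarity score over all unordered pairs of non-gap residues in
#' a column, using a unit-diagonal similarity matrix (see
#' [similarity_transform()]), so that an invariant column scores 1.
#'
#' @param residues Character vector of non-gap residues (length >= 2), or a
#'   column including gaps (gaps/X are dropped).
#' @param S Similarity matrix over the 20 residues.
#' @return Mean pairwise score, or `NA_real_` when fewer than 2 residues
#'   remain.
#' @export
sum_of_pairs <- function(residues, S) {
  residues <- residues[residues %in% AA20]
  n <- length(residues)
  if (n < 2L) return(NA_real_)
  cnt <- table(factor(residues, levels = AA20))
  cnt <- as.numeric(cnt)
  tot <- (t(cnt) %*% S %*% cnt - sum(cnt * diag(S))) / 2
  as.numeric(tot) / (n * (n - 1) / 2)
}

#' Von Neumann entropy of a column (bits)
#'
#' Entropy of the density matrix `rho = D S D / tr(D S D)` with
#' `D = diag(sqrt(p))` and `S` a unit-diagonal residue similarity: the
#' eigenvalue spectrum of `rho` blends residue frequencies with pairwise
#' similarity. With `S = I` it reduces exactly to the Shannon entropy. The
#' conservation score used by the sweep is `log2(20) - VN`.
#'
#' @param p Residue distribution.
#' @param S Similarity matrix (unit diagonal); default identity.
#' @return Entropy in bits.
#' @export
vn_entropy <- function(p, S = diag(20)) {
  check_distribution(p)
  d <- sqrt(p)
  rho <- outer(d, d) * S
  tr <- sum(diag(rho))
  if (tr <= 0) stop("density matrix has zero trace")
  rho <- rho / tr
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12]
  -sum(ev * log2(ev))
}

#' Score every column of an alignment with one estimator
#'
#' Computes the chosen estimator for every column under one background and
#' one substitution matrix, oriented so higher = more conserved, and
#' applies the gap adjustment (multiplication by the column's non-gap
#' fraction) so heavily gapped columns cannot rank as conserved.
#'
#' @param aln A [prot_aln()] alignment.
#' @param method One of `"js_divergence"`, `"property_entropy"`,
#'   `"vn_entropy"`, `"relative_entropy"`, `"shannon_entropy"`,
#'   `"sum_of_pairs"`.
#' @param background Background name (see [background_distribution()]).
#' @param matrix Matrix name (see [substitution_matrix()]).
#' @param pseudocount Per-residue pseudo-frequency, default `1e-6`.
#' @param gap_adjust Multiply scores by the non-gap fraction (default
#'   `TRUE`).
#' @return data.frame: index, method, background, matrix, score (raw),
#'   gap_fraction, adjusted. All-gap columns score `NA`.
#' @export
score_alignment <- function(aln, method = ESTIMATOR_NAMES,
                            background = "blosum62", matrix = "blosum62",
                            pseudocount = 1e-6, gap_adjust = TRUE) {
  method <- match.arg(method)
  q <- background_distribution(background)
  S <- similarity_transform(substitution_matrix(matrix))
  m <- as.matrix(aln)
  pm <- profile_matrix(aln)            # 21 symbols x L, gaps in last row
  n_seq <- length(aln$ids)
  raw <- numeric(aln$L)
  gapf <- pm[21L, ] / n_seq
  for (j in seq_len(aln$L)) {
    cnt <- pm[seq_along(AA20), j]
    n_res <- sum(cnt)
    if (n_res == 0L) { raw[j] <- NA_real_; next }
    p <- cnt / n_res + pseudocount
    p <- stats::setNames(p / sum(p), AA20)
    raw[j] <- switch(method,
      shannon_entropy = log2(20) - shannon_entropy(p),
      relative_entropy = relative_entropy(p, q),
      js_divergence = js_divergence(p, q),
      property_entropy = log2(length(default_property_partition())) -
        property_entropy(p),
      vn_entropy = log2(20) - vn_entropy(p, S),
      sum_of_pairs = sum_of_pairs(m[, j], S))
  }
  adjusted <- if (gap_adjust) raw * (1 - gapf) else raw
  data.frame(index = seq_len(aln$L), method = method,
             background = background, matrix = matrix,
             score = raw, gap_fraction = gapf, adjusted = adjusted,
             stringsAsFactors = FALSE)
}

#' Columns identified by one scoring run
#'
#' The top fraction of columns by gap-adjusted score: `k = max(1,
#' floor(top_fraction * n_scored))` columns, ordered by score descending
#' with ties broken by ascending index.
#'
#' @param scores Output of [score_alignment()].
#' @param top_fraction Fraction of scored columns to flag, default 0.05.
#' @return Integer vector of 1-based column indices.
#' @export
identified_columns <- function(scores, top_fraction = 0.05) {
  ok <- !is.na(scores$adjusted)
  n <- sum(ok)
  if (n == 0L) return(integer())
  k <- max(1L, floor(top_fraction * n))
  ord <- order(-scores$adjusted[ok], scores$index[ok])
  sort(scores$index[ok][ord][seq_len(k)])
}

#' Consensus of an estimator over all background x matrix combinations
#'
#' Runs the estimator once per (background, matrix) combination — 3
#' backgrounds x 7 matrices = 21 runs by default, including combinations
#' the method is insensitive to — and intersects the identified column
#' sets, so only columns flagged under every combination survive.
#'
#' @param aln A [prot_aln()] alignment.
#' @param method Estimator name.
#' @param backgrounds Background names, default all three.
#' @param matrices Matrix names, default all seven.
#' @param top_fraction Identification fraction per run, default 0.05.
#' @param pseudocount Per-residue pseudo-frequency.
#' @return Sorted integer vector of consensus column indices.
#' @export
consensus_identified <- function(aln, method,
                                 backgrounds = BACKGROUND_NAMES,
                                 matrices = MATRIX_NAMES,
                                 top_fraction = 0.05,
                                 pseudocount = 1e-6) {
  if (aln$L < 1L) stop("empty alignment")
  consensus <- NULL
  for (bg in backgrounds) for (mat in matrices) {
    sc <- score_alignment(aln, method, background = bg, matrix = mat,
                          pseudocount = pseudocount)
    ids <- identified_columns(sc, top_fraction)
    consensus <- if (is.null(consensus)) ids else intersect(consensus, ids)
    if (!length(consensus)) return(integer())
  }
  sort(consensus)
}
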