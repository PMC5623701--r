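# Motif patterns in the PROSITE-like dialect used for conserved-motif
# tables: literal residues, bracketed alternation sets like [LM], and the
# wildcard 'x' (any residue, never a gap). Matching is exact; every
# (possibly overlapping) occurrence is reported.

#' Parse a motif pattern string
#'
#' @param pattern_string Pattern over uppercase residue letters, `x`
#'   wildcards and `[...]` alternation sets, e.g. `"Hx[ST]A"`.
#' @param name Optional motif name.
#' @return Object of class `motif_pattern`: list with `name`, `source`,
#'   `elements` (list of character vectors; a `motif_wildcard` sentinel
#'   marks a wildcard position) and
#'   `length` (number of positions).
#' @export
parse_motif <- function(pattern_string, name = NULL) {
  chars <- strsplit(pattern_string, "", fixed = TRUE)[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      elements[[length(elements) + 1L]] <- NULL_WILDCARD
      i <- i + 1L
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (!length(close))
        stop("unclosed '[' at offset ", i, " in pattern: ", pattern_string)
      close <- close[1]
      members <- chars[(i + 1L):(close - 1L)]
      if (close == i + 1L)
        stop("empty alternation set at offset ", i, " in pattern: ",
             pattern_string)
      if (!all(members %in% AA20))
        stop("illegal residue(s) in alternation at offset ", i, ": ",
             paste(setdiff(members, AA20), collapse = ", "))
      elements[[length(elements) + 1L]] <- unique(members)
      i <- close + 1L
    } else if (ch %in% AA20) {
      elements[[length(elements) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' at offset ", i, " in pattern: ",
           pattern_string)
    }
  }
  if (!length(elements)) stop("empty pattern")
  structure(list(name = name, source = pattern_string,
                 elements = elements, length = length(elements)),
            class = "motif_pattern")
}

# sentinel for wildcard positions (kept as a full residue set so matching
# code needs no special case, but printed back as 'x')
NULL_WILDCARD <- structure("*wildcard*", class = "motif_wildcard")

#' @export
print.motif_pattern <- function(x, ...) {
  cat("Motif", if (!is.null(x$name)) x$name else "", "(", x$length,
      "positions ):", x$source, "\n")
  invisible(x)
}

#' Render a parsed motif back to its source dialect
#' @param pattern A [parse_motif()] result.
#' @return The normalized pattern string.
#' @export
motif_to_string <- function(pattern) {
  paste(vapply(pattern$elements, function(el) {
    if (inherits(el, "motif_wildcard")) "x"
    else if (length(el) == 1L) el
    else paste0("[", paste(el, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Scan an ungapped sequence for motif matches
#'
#' Reports the 1-based start position of every (possibly overlapping)
#' exact match. A wildcard matches any of the 20 residues but never a gap
#' or `X`.
#'
#' @param pattern A [parse_motif()] result.
#' @param sequence Ungapped residue string.
#' @return Integer vector of match start positions (empty when none).
#' @export
scan_sequence <- function(pattern, sequence) {
  chars <- strsplit(normalize_residues(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  k <- pattern$length
  if (k > n) return(integer())
  ok_pos <- matrix(FALSE, nrow = n, ncol = k)
  for (e in seq_len(k)) {
    el <- pattern$elements[[e]]
    allowed <- if (inherits(el, "motif_wildcard")) AA20 else el
    ok_pos[, e] <- chars %in% allowed
  }
  starts <- integer()
  for (s in seq_len(n - k + 1L)) {
    if (all(ok_pos[cbind(s:(s + k - 1L), seq_len(k))]))
      starts <- c(starts, s)
  }
  starts
}

#' Read a motif file
#'
#' One pattern per line: `name<TAB>pattern`; `#` comments allowed.
#'
#' @param path Path to the motif file.
#' @return Named list of [parse_motif()] results.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t")
  pats <- lapply(toks, function(tk) parse_motif(tk[2], name = tk[1]))
  stats::setNames(pats, vapply(toks, `[`, "", 1L))
}

#' Per-group motif presence in an alignment
#'
#' For each (group, motif): the fraction of member sequences whose
#' degapped sequence carries at least one match, the alignment-index span
#' of the first match in the first matching sequence, and a
#' `group_exclusive` flag set when the motif occurs in exactly one group.
#'
#' @param aln A [prot_aln()] alignment.
#' @param partition A [group_partition()].
#' @param patterns List of [parse_motif()] results (or a single one).
#' @return data.frame: motif, group, fraction, span_start, span_end
#'   (alignment indices, `NA` when unmatched), group_exclusive.
#' @export
motif_presence <- function(aln, partition, patterns) {
  validate_partition(partition, aln)
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  if (is.null(names(patterns)))
    names(patterns) <- vapply(seq_along(patterns), function(i)
      if (!is.null(patterns[[i]]$name)) patterns[[i]]$name
      else paste0("motif", i), "")
  m <- as.matrix(aln)
  is_res <- m %in% AA20 & !(m == "X")
  dim(is_res) <- dim(m)
  out <- list()
  for (pn in names(patterns)) {
    pat <- patterns[[pn]]
    rows <- list()
    for (g in partition$groups) {
      ids <- group_ids(partition, g)
      hit <- logical(length(ids))
      span <- c(NA_integer_, NA_integer_)
      for (ii in seq_along(ids)) {
        ridx <- match(ids[ii], aln$ids)
        resmask <- is_res[ridx, ]
        degapped <- paste(m[ridx, resmask], collapse = "")
        starts <- scan_sequence(pat, degapped)
        hit[ii] <- length(starts) > 0L
        if (hit[ii] && is.na(span[1])) {
          res_cols <- which(resmask)
          span <- c(res_cols[starts[1]],
                    res_cols[starts[1] + pat$length - 1L])
        }
      }
      rows[[g]] <- data.frame(motif = pn, group = g,
                              fraction = mean(hit),
                              span_start = span[1], span_end = span[2],
                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$group_exclusive <- sum(tab$fraction > 0) == 1L & tab$fraction > 0
    out[[pn]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
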