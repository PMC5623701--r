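# Canonical 20-letter amino acid alphabet, alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"

#' Construct a protein multiple sequence alignment
#'
#' Creates a `prot_aln` object from named, equal-length residue strings.
#' Input is normalized: letters are upper-cased, the gap characters `.` and
#' `~` become `-`, and the non-canonical letters B, Z, J, U, O become `X`.
#' `X` is treated as a gap by every counting and scoring routine: the
#' package's statistics are defined over the 20 canonical amino acids only.
#'
#' @param seqs Named character vector of aligned residue strings.
#' @return An object of class `prot_aln` with elements `ids`, `seqs`
#'   (normalized strings) and `L` (column count). Columns are 1-based.
#' @export
prot_aln <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must have a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_residues(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- paste(ids, lens, sep = "=", collapse = ", ")
    stop("rows have unequal lengths: ", bad)
  }
  if (lens[1] < 1L) stop("alignment must have at least one column")
  bad_chars <- gsub(paste0("[", paste(AA20, collapse = ""), "X-]"), "", seqs)
  if (any(nzchar(bad_chars)))
    stop("illegal characters after normalization: ",
         paste(unique(unlist(strsplit(bad_chars[nzchar(bad_chars)], ""))),
               collapse = ", "))
  structure(list(ids = ids, seqs = seqs, L = unname(lens[1])),
            class = "prot_aln")
}

normalize_residues <- function(x) {
  x <- toupper(x)
  x <- chartr(".~", "--", x)
  chartr("BZJUO", "XXXXX", x)
}

#' @export
print.prot_aln <- function(x, ...) {
  cat("Protein alignment:", length(x$ids), "sequences x", x$L, "columns\n")
  show <- utils::head(x$ids, 5)
  for (id in show)
    cat(sprintf("  %-12s %s%s\n", id, substr(x$seqs[[id]], 1, 50),
                if (x$L > 50) "..." else ""))
  if (length(x$ids) > 5) cat("  ...", length(x$ids) - 5, "more\n")
  invisible(x)
}

#' @export
as.matrix.prot_aln <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' @export
dim.prot_aln <- function(x) c(length(x$ids), x$L)

#' Read a GCG MSF alignment
#'
#' Parses the interleaved GCG MSF layout: a header terminated by a `//`
#' separator followed by blocks of `name  residues` lines. Gap characters
#' `.` and `~` are emitted as `-`; the header's declared `MSF:` length, when
#' present, is checked against the concatenated blocks. MSF checksums are
#' parsed past but not verified.
#'
#' @param path Path to an MSF file.
#' @return A [prot_aln()] alignment with sequence order preserved.
#' @export
read_msf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sep <- grep("^\\s*//", lines)
  if (length(sep) == 0L)
    stop("not an MSF file: missing '//' separator in ", path)
  header <- lines[seq_len(sep[1] - 1L)]
  body <- lines[-seq_len(sep[1])]

  declared <- NA_integer_
  msf_line <- grep("MSF:\\s*[0-9]+", header, value = TRUE)
  if (length(msf_line))
    declared <- as.integer(sub(".*MSF:\\s*([0-9]+).*", "\\1", msf_line[1]))

  seqs <- character()
  for (ln in body) {
    if (grepl("^\\s*$", ln)) next
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 2L) next
    # Skip interleaved column-ruler lines (all-numeric tokens).
    if (all(grepl("^[0-9]+$", toks))) next
    id <- toks[1]
    chunk <- paste(toks[-1], collapse = "")
    if (grepl("[0-9]", chunk)) next   # name line with ruler numbers
    if (is.na(match(id, names(seqs)))) seqs[id] <- chunk
    else seqs[id] <- paste0(seqs[id], chunk)
  }
  if (!length(seqs)) stop("no sequence blocks found in ", path)

  # Duplicate ids in the header's Name: lines are a hard error.
  name_ids <- sub(".*Name:\\s+(\\S+).*", "\\1",
                  grep("Name:\\s+\\S+", header, value = TRUE))
  if (anyDuplicated(name_ids))
    stop("duplicate sequence ids in MSF header: ",
         paste(unique(name_ids[duplicated(name_ids)]), collapse = ", "))

  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("ragged MSF rows: ",
         paste(names(seqs), lens, sep = "=", collapse = ", "))
  if (!is.na(declared) && declared != lens[1])
    stop("MSF declared length ", declared,
         " disagrees with concatenated blocks (", lens[1], ")")
  prot_aln(seqs)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (equal-length) FASTA file.
#' @return A [prot_aln()] alignment.
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("FASTA records are not aligned; lengths: ",
         paste(names(seqs), lens, sep = "=", collapse = ", "))
  prot_aln(seqs)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A [prot_aln()] alignment.
#' @param path Output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Map an alignment column to a per-sequence residue number
#'
#' Converts a 1-based alignment index into the 1-based position of the
#' residue in the ungapped sequence, the convention used to report sites as
#' e.g. residue 25 at alignment index 142. The residue number is `NA` when
#' the cell holds a gap (or `X`).
#'
#' @param aln A [prot_aln()] alignment.
#' @param seq_id Sequence identifier.
#' @param alignment_index 1-based column index.
#' @return A list with `seq_id`, `alignment_index`, `residue` and
#'   `residue_number` (`NA` for a gap).
#' @export
map_residue <- function(aln, seq_id, alignment_index) {
  i <- match(seq_id, aln$ids)
  if (is.na(i)) stop("unknown sequence id: ", seq_id)
  if (alignment_index < 1L || alignment_index > aln$L)
    stop("alignment_index out of range [1, ", aln$L, "]: ", alignment_index)
  row <- strsplit(aln$seqs[[i]], "", fixed = TRUE)[[1]]
  res <- row[alignment_index]
  is_res <- !(row %in% c(GAP, "X"))
  num <- if (is_res[alignment_index])
    sum(is_res[seq_len(alignment_index)]) else NA_integer_
  list(seq_id = seq_id, alignment_index = as.integer(alignment_index),
       residue = res, residue_number = num)
}

#' Construct a sequence-to-group partition
#'
#' @param assignment Named character vector mapping sequence id to group
#'   label.
#' @param groups Optional ordered group labels; defaults to order of first
#'   appearance.
#' @return An object of class `group_partition`.
#' @export
group_partition <- function(assignment, groups = NULL) {
  if (!length(assignment)) stop("empty partition: no sequences assigned")
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be named by sequence id")
  if (any(!nzchar(assignment))) stop("group labels must be non-empty")
  if (anyDuplicated(names(assignment)))
    stop("sequence assigned twice: ",
         paste(unique(names(assignment)[duplicated(names(assignment))]),
               collapse = ", "))
  if (is.null(groups)) groups <- unique(unname(assignment))
  if (!all(assignment %in% groups))
    stop("assignment uses labels outside 'groups'")
  structure(list(assignment = assignment, groups = groups),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = x$groups))
  cat("Group partition:", length(x$assignment), "sequences in",
      length(x$groups), "groups\n")
  print(tab)
  invisible(x)
}

#' Read a two-column sequence-to-group table
#'
#' The file holds one `id<TAB or space>group` pair per line; `#` starts a
#' comment.
#'
#' @param path Path to the table.
#' @return A [group_partition()].
#' @export
read_groups <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty partition: file has no assignments")
  toks <- strsplit(lines, "[\t ]+")
  if (any(lengths(toks) < 2L))
    stop("malformed group line(s): ",
         paste(lines[lengths(toks) < 2L], collapse = "; "))
  ids <- vapply(toks, `[`, "", 1L)
  grp <- vapply(toks, `[`, "", 2L)
  group_partition(stats::setNames(grp, ids))
}

#' Write a group partition as a TSV table
#' @param partition A [group_partition()].
#' @param path Output path.
#' @export
write_groups <- function(partition, path) {
  utils::write.table(
    data.frame(id = names(partition$assignment),
               group = unname(partition$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a partition against an alignment
#'
#' Checks that every assigned id exists in the alignment and that every
#' group keeps at least one member.
#'
#' @param partition A [group_partition()].
#' @param aln A [prot_aln()] alignment.
#' @return The partition, invisibly, on success.
#' @export
validate_partition <- function(partition, aln) {
  orphans <- setdiff(names(partition$assignment), aln$ids)
  if (length(orphans))
    stop("partition references ids absent from the alignment: ",
         paste(orphans, collapse = ", "))
  sizes <- table(factor(partition$assignment, levels = partition$groups))
  if (any(sizes == 0L))
    stop("group(s) with no members: ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  invisible(partition)
}

# ids belonging to one group
group_ids <- function(partition, group) {
  names(partition$assignment)[partition$assignment == group]
}
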