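# Shared fixture builders. Everything is generated in code; no binary or
# downloaded data.

aln_from <- function(...) {
  prot_aln(c(...))
}

# A minimal valid interleaved MSF text for the given sequences, using '.'
# as the gap character (the dialect the reader must normalize).
msf_text <- function(seqs, declared = NULL) {
  if (is.null(declared)) declared <- nchar(seqs[[1]])
  gapped <- chartr("-", ".", seqs)
  c(sprintf("  test.msf  MSF: %d  Type: P  Check: 0 ..", declared),
    "",
    sprintf(" Name: %s  Len: %d  Check: 0  Weight: 1.0",
            names(seqs), nchar(seqs)),
    "",
    "//",
    "",
    paste(format(names(seqs), width = 12), gapped))
}

write_msf_fixture <- function(seqs, declared = NULL) {
  path <- withr::local_tempfile(fileext = ".msf",
                                .local_envir = parent.frame())
  writeLines(msf_text(seqs, declared), path)
  path
}

# random gapped alignment over the 20 residues
random_aln <- function(n_seq, L, gap_rate = 0.1, seed = 1) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- matrix(sample(aa, n_seq * L, replace = TRUE), n_seq, L)
  m[matrix(runif(n_seq * L) < gap_rate, n_seq, L)] <- "-"
  prot_aln(setNames(apply(m, 1, paste, collapse = ""),
                    sprintf("s%02d", seq_len(n_seq))))
}

# convert a motif dialect string to a base-R regex for oracle matching
motif_regex <- function(pattern_string) {
  out <- gsub("x", "[ACDEFGHIKLMNPQRSTVWY]", pattern_string, fixed = TRUE)
  out
}
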