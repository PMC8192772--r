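# Fixtures built in code at test time.

aln_from <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%02d", seq_along(seqs))
  coi_alignment(seqs)
}

# Write a small FASTA file and return its path.
write_fasta_fixture <- function(seqs, wrap = NULL) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "wt")
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    if (is.null(wrap)) writeLines(s, con)
    else writeLines(substring(s, seq(1, nchar(s), wrap),
                              pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s))),
                    con)
  }
  close(con)
  path
}

# Two 595 bp sequences differing at exactly `k` sites (the Table-2 JB
# geometry).
jb_pair <- function(k = 5, len = 595) {
  base <- strrep("A", len)
  alt <- strsplit(base, "")[[1]]
  alt[seq_len(k) * 7] <- "G"
  aln_from(a = base, b = paste(alt, collapse = ""))
}

# Alignment of n mutually distinct sequences (singleton haplotypes).
distinct_seqs <- function(n, len = 40) {
  seqs <- vapply(seq_len(n), function(i) {
    s <- rep("A", len); s[i] <- "T"; paste(s, collapse = "")
  }, character(1))
  aln_from(setNames(seqs, sprintf("d%02d", seq_len(n))))
}
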