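# shared helpers: random encoded columns and small alignment builders

# random encoded column over A,C,G,T,GAP with missing entries
rand_col <- function(n, p_missing = 0.15, states = c("A", "C", "G", "T", "GAP")) {
  st <- sample(states, n, replace = TRUE)
  st[stats::runif(n) < p_missing] <- NA
  st
}

# alignment matrix from a character vector of equal-length strings
aln_from_strings <- function(x, taxa = paste0("t", seq_along(x))) {
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(m) <- taxa
  as_alignment(m)
}

# the 8-taxon, 10-site worked alignment with conflicts 1-2, 2-3, 7-9
worked_alignment <- function() {
  aln_from_strings(c("TACGGGACGA", "TACGGGACGA", "TTCGGGACTA", "TTCGGGACTA",
                     "AAGGGGTCGA", "AAGGGGTCGA", "ATGGGGTCTA", "ATCGGGTCTA"))
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
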