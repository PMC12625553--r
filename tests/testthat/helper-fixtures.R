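# Shared fixtures and independent oracles for the test suite.

# Brute-force motif scan: test every window of pattern length.
oracle_scan <- function(residues, token) {
  seq <- strsplit(toupper(residues), "")[[1]]
  pat <- strsplit(toupper(sub("\\{.*\\}$", "", token)), "")[[1]]
  k <- length(pat)
  n <- length(seq)
  starts <- integer(0)
  if (n >= k) {
    for (s in seq_len(n - k + 1L)) {
      win <- seq[s:(s + k - 1L)]
      if (all(pat == "X" | pat == win)) starts <- c(starts, s)
    }
  }
  data.frame(start = starts,
             matched = vapply(starts, function(s)
               paste(seq[s:(s + k - 1L)], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

# Prefix-enumeration N/L oracle: walk descending lengths one by one.
oracle_nstat <- function(lengths, fraction) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  running <- 0
  for (i in seq_along(s)) {
    running <- running + s[i]
    if (running >= fraction * total) return(list(n = s[i], l = i))
  }
}

# One-row hit table with sensible defaults; override any field.
make_hit <- function(...) {
  row <- list(
    qseqid = "q1", sseqid = "s1", pident = 100, evalue = 1e-50,
    length = 100L, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L, bitscore = 200, qlen = 100L, sframe = 1L,
    qcov = 100, query_file = "q1", database = "db1",
    subject_residues = paste(rep("A", 100), collapse = ""),
    program = "tblastn")
  over <- list(...)
  row[names(over)] <- over
  row$qcov <- if ("qcov" %in% names(over)) over$qcov else
    compute_query_coverage(row$qstart, row$qend, row$qlen)
  as.data.frame(row, stringsAsFactors = FALSE)
}

hits_table <- function(...) do.call(rbind, list(...))

write_tmp_fasta <- function(dir, name, ids, seqs, descriptions = "") {
  path <- file.path(dir, name)
  write_fasta(data.frame(id = ids, description = descriptions,
                         residues = seqs, stringsAsFactors = FALSE), path)
  path
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

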