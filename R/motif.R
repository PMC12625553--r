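# Wildcard amino-acid motif mining over the aligned subject strings of
# BLAST hits. Patterns use one-letter residue codes with X as a wildcard
# (e.g. WXWXIP) and may be bound to one query file's results with a brace
# suffix (e.g. RVXXXQ{AT} scans only hits of query file AT.faa). Scanning
# always covers every hit, regardless of inclusion thresholds.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse wildcard motif tokens
#'
#' Each token is a run of one-letter amino-acid codes with `X` as a
#' wildcard, optionally followed by `{stem}` binding the pattern to the
#' results of one query file. Letters are case-normalized to uppercase.
#' Fixed positions must be standard residues; `X` always wildcards, so a
#' literal fixed X is unsupported.
#'
#' @param tokens Character vector of pattern tokens, e.g.
#'   `c("WXWXIP", "RVXXXQ{AT}")`.
#' @return List of `motif_pattern` objects (fields `raw`, `positions`,
#'   `binding`).
#' @export
parse_motif_spec <- function(tokens) {
  if (!length(tokens)) stop("no motif patterns given")
  lapply(tokens, function(tok) {
    if (grepl("\\{\\}", tok)) {
      stop("empty braces in motif '", tok, "'", call. = FALSE)
    }
    m <- regmatches(tok, regexec("^([A-Za-z]+)(\\{([^{}]+)\\})?$", tok))[[1]]
    if (!length(m) || !nzchar(m[2])) {
      stop("malformed motif '", tok,
           "': expected residue letters (X = wildcard), optionally ",
           "followed by {query_stem}", call. = FALSE)
    }
    positions <- strsplit(toupper(m[2]), "")[[1]]
    fixed <- positions[positions != "X"]
    if (length(bad <- setdiff(unique(fixed), AA_LETTERS))) {
      stop("motif '", tok, "' contains non-standard residue letter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    structure(list(raw = tok, positions = positions,
                   binding = if (nzchar(m[4] %||% "")) m[4] else NA_character_),
              class = "motif_pattern")
  })
}

motif_regex <- function(pattern) {
  paste(ifelse(pattern$positions == "X", "[A-Z]", pattern$positions),
        collapse = "")
}

#' Scan one amino-acid sequence for a motif
#'
#' Returns every occurrence, including overlapping ones, in ascending
#' start order. Matching is case-insensitive; wildcard positions match
#' any letter A-Z.
#'
#' @param residues Amino-acid string (gaps should be removed first; see
#'   [scan_hits()]).
#' @param pattern A `motif_pattern` (or a single token parsed on the fly).
#' @return Data.frame with columns `start` (1-based) and `matched`.
#' @examples
#' scan_sequence("AAAAA", "AXA") # starts 1, 2, 3
#' @export
scan_sequence <- function(residues, pattern) {
  if (is.character(pattern)) pattern <- parse_motif_spec(pattern)[[1]]
  seq <- toupper(residues)
  k <- length(pattern$positions)
  # lookahead makes gregexpr report overlapping occurrences
  rx <- paste0("(?=", motif_regex(pattern), ")")
  starts <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (starts[1] == -1L) {
    return(data.frame(start = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(starts)
  data.frame(start = starts,
             matched = substring(seq, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Pair motif patterns with the hits they should scan
#'
#' Unbound patterns pair with every hit; a pattern bound to a query stem
#' pairs only with hits from that query file. Hits are used regardless of
#' their threshold status. A binding matching no stem yields zero pairs
#' with a warning.
#'
#' @param patterns List from [parse_motif_spec()].
#' @param hits Hit table carrying a `query_file` column.
#' @return Data.frame with columns `pattern` (index into `patterns`) and
#'   `hit` (row index into `hits`).
#' @export
plan_scans <- function(patterns, hits) {
  pairs <- lapply(seq_along(patterns), function(pi) {
    b <- patterns[[pi]]$binding
    rows <- if (is.na(b)) seq_len(nrow(hits)) else which(hits$query_file == b)
    if (!is.na(b) && !length(rows)) {
      warning("motif '", patterns[[pi]]$raw, "' is bound to query stem '",
              b, "', which matches no hits", call. = FALSE)
    }
    if (length(rows)) data.frame(pattern = pi, hit = rows) else NULL
  })
  out <- do.call(rbind, pairs)
  if (is.null(out)) data.frame(pattern = integer(), hit = integer()) else out
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Scan BLAST hits for motifs
#'
#' De-gaps each hit's aligned subject string and scans it with every
#' applicable pattern (see [plan_scans()]). Match coordinates are 1-based
#' within the de-gapped subject alignment. Only amino-acid subjects are
#' meaningful: hits from `blastn` are refused.
#'
#' @param results A `blast_results` object or a hit table carrying
#'   `subject_residues`, `program` and `query_file` columns.
#' @param patterns Pattern tokens or list from [parse_motif_spec()].
#' @return A `motif_matches` data.frame: `pattern`, `query_file`,
#'   `database`, `sseqid`, `qseqid`, `start`, `matched`,
#'   `subject_degapped`.
#' @export
scan_hits <- function(results, patterns) {
  hits <- if (inherits(results, "blast_results")) results$all else results
  if (is.character(patterns)) patterns <- parse_motif_spec(patterns)
  if (!all(c("subject_residues", "program") %in% names(hits))) {
    stop("hit table lacks subject_residues/program columns; motif scanning ",
         "needs the in-memory results of run_queries()")
  }
  if (any(hits$program == "blastn")) {
    stop("motif scanning requires amino-acid subjects (blastp/tblastn); ",
         "refusing nucleotide-subject (blastn) results")
  }
  plan <- plan_scans(patterns, hits)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    h <- hits[plan$hit[i], ]
    subject <- degap(toupper(h$subject_residues))
    m <- scan_sequence(subject, patterns[[plan$pattern[i]]])
    if (!nrow(m)) return(NULL)
    data.frame(pattern = patterns[[plan$pattern[i]]]$raw,
               query_file = h$query_file, database = h$database,
               sseqid = h$sseqid, qseqid = h$qseqid,
               start = m$start, matched = m$matched,
               subject_degapped = subject, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pattern = character(), query_file = character(),
                      database = character(), sseqid = character(),
                      qseqid = character(), start = integer(),
                      matched = character(), subject_degapped = character(),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("motif_matches", class(out))
  out
}

safe_pattern_name <- function(raw) gsub("[^A-Za-z0-9_-]", "_", raw)

#' Export motif matches to FASTA, one file per pattern
#'
#' By default each record holds the full de-gapped subject alignment of
#' the hit containing the match; with `motif_only = TRUE` it holds just
#' the matched substring. Patterns with zero matches emit no file.
#'
#' @param matches A `motif_matches` table from [scan_hits()].
#' @param out_dir Output directory.
#' @param motif_only Export only the matched motif strings.
#' @return Character vector of written FASTA paths (named by pattern).
#' @export
export_motif_fasta <- function(matches, out_dir = ".", motif_only = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (pat in unique(matches$pattern)) {
    sub <- matches[matches$pattern == pat, , drop = FALSE]
    if (!nrow(sub)) next
    end <- sub$start + nchar(sub$matched) - 1L
    rec <- data.frame(
      id = sprintf("%s|%s|%d-%d", sub$database, sub$sseqid, sub$start, end),
      description = paste0("motif=", pat, " query=", sub$qseqid),
      residues = if (motif_only) sub$matched else sub$subject_degapped,
      stringsAsFactors = FALSE
    )
    path <- file.path(out_dir,
                      paste0("motif_", safe_pattern_name(pat), ".faa"))
    write_fasta(rec, path)
    paths[pat] <- path
  }
  paths
}

#' Write the motif match table as CSV
#'
#' @param matches A `motif_matches` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_motif_matches <- function(matches, path) {
  cols <- c("pattern", "database", "sseqid", "qseqid", "start", "matched")
  utils::write.csv(matches[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
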