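# BLAST+ orchestration: database construction, per-pairing program
# dispatch, parallel query execution and curation of the unified results
# tables (all_results.csv, all_filtered_results.csv, filtered_results.csv).
#
# The alignment itself is always delegated to the NCBI BLAST+ binaries
# (makeblastdb, blastn, blastp, tblastn) invoked as subprocesses with
# explicit argument lists.

# The 17 columns of the exported results tables, in order.
HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "evalue", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "bitscore",
                 "qlen", "sframe", "qcov", "query_file", "database")

# Tabular request sent to the search binaries: the standard 12 fields plus
# qlen, sframe and the aligned subject string (needed by the motif engine).
BLAST_OUTFMT <- paste("6 qseqid sseqid pident evalue length mismatch gapopen",
                      "qstart qend sstart send bitscore qlen sframe sseq")

BLAST_BINARIES <- c("makeblastdb", "blastn", "blastp", "tblastn")

#' Inclusion thresholds for hit filtering
#'
#' Defaults are the curated thresholds used throughout the query pipeline:
#' 90% identity, 75% query coverage and an E-value of 1e-5. All three
#' comparisons are inclusive at the boundary.
#'
#' @param min_identity Minimum percent identity, in \[0, 100\].
#' @param min_coverage Minimum query coverage percent, in \[0, 100\].
#' @param max_evalue Maximum expectation value (> 0).
#' @return A `threshold_set` list.
#' @export
threshold_set <- function(min_identity = 90, min_coverage = 75,
                          max_evalue = 1e-5) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100, max_evalue > 0)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 max_evalue = max_evalue), class = "threshold_set")
}

require_binary <- function(bin) {
  if (!nzchar(Sys.which(bin))) {
    stop(errorCondition(
      paste0("required BLAST+ binary not found on PATH: ", bin),
      class = "blastmine_env_error"))
  }
  invisible(bin)
}

#' Build BLAST databases from a FASTA collection
#'
#' One database per FASTA file; database type (`nucl`/`prot`) follows the
#' file extension. File names containing characters outside the allowed
#' set are either renamed first (`sanitize = TRUE`) or cause an error
#' listing the offenders. Stems must be unique across the collection.
#'
#' @param collection A `fasta_collection` (or path accepted by
#'   [resolve_inputs()]).
#' @param out_dir Directory receiving the database volumes.
#' @param threads Parallel makeblastdb invocations.
#' @param sanitize Rename non-compliant files in place before building.
#' @param quiet Suppress progress messages.
#' @return Data.frame with columns `name`, `db_type`, `prefix`, `source`.
#' @export
make_databases <- function(collection, out_dir = "blast_dbs", threads = 1L,
                           sanitize = FALSE, quiet = FALSE) {
  if (is.character(collection)) collection <- resolve_inputs(collection, quiet = quiet)
  stopifnot(inherits(collection, "fasta_collection"))
  entries <- collection$entries
  if (!nrow(entries)) stop("empty collection: nothing to build")
  require_binary("makeblastdb")

  names_now <- basename(entries$path)
  compliant <- names_now == sanitize_filename(names_now)
  if (any(!compliant)) {
    if (!sanitize) {
      stop("file name(s) incompatible with BLAST+ (rerun with sanitize, ",
           "or run sanitize_files() first): ",
           paste(names_now[!compliant], collapse = ", "), call. = FALSE)
    }
    new_names <- disambiguate_names(sanitize_filename(names_now))
    for (i in which(names_now != new_names)) {
      dest <- file.path(dirname(entries$path[i]), new_names[i])
      file.rename(entries$path[i], dest)
      entries$path[i] <- dest
    }
  }

  stems <- file_stem(entries$path)
  if (anyDuplicated(stems)) {
    stop("duplicate database stems: ",
         paste(unique(stems[duplicated(stems)]), collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_run(out_dir, "makedb",
          list(files = nrow(entries), threads = threads, sanitize = sanitize))

  build_one <- function(i) {
    db_type <- if (entries$molecule[i] == "protein") "prot" else "nucl"
    prefix <- file.path(out_dir, stems[i])
    out <- suppressWarnings(system2(
      "makeblastdb",
      c("-in", shQuote(entries$path[i]), "-dbtype", db_type,
        "-out", shQuote(prefix), "-title", shQuote(stems[i])),
      stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L) {
      stop("makeblastdb failed for ", basename(entries$path[i]), ": ",
           paste(utils::tail(out, 3L), collapse = " "))
    }
    data.frame(name = stems[i], db_type = db_type, prefix = prefix,
               source = entries$path[i], stringsAsFactors = FALSE)
  }
  res <- parallel::mclapply(seq_len(nrow(entries)), build_one,
                            mc.cores = max(1L, min(threads, nrow(entries))))
  err <- vapply(res, inherits, logical(1), what = c("try-error", "error"))
  if (any(err)) stop(conditionMessage(res[[which(err)[1L]]]))
  dbs <- do.call(rbind, res)
  bm_message("built ", nrow(dbs), " BLAST database(s) in ", out_dir, quiet = quiet)
  dbs
}

#' Discover BLAST databases under a directory
#'
#' Identifies database prefixes from the index volumes makeblastdb writes
#' (`.nin` for nucleotide, `.pin` for protein).
#'
#' @param dir Directory holding database volumes.
#' @return Data.frame with `name`, `db_type`, `prefix`.
#' @export
discover_databases <- function(dir) {
  if (!dir.exists(dir)) stop("database directory not found: ", dir)
  nin <- list.files(dir, pattern = "\\.nin$", full.names = TRUE)
  pin <- list.files(dir, pattern = "\\.pin$", full.names = TRUE)
  rows <- rbind(
    if (length(nin)) data.frame(prefix = sub("\\.nin$", "", nin), db_type = "nucl"),
    if (length(pin)) data.frame(prefix = sub("\\.pin$", "", pin), db_type = "prot")
  )
  if (is.null(rows) || !nrow(rows)) stop("no BLAST databases found under ", dir)
  rows$name <- basename(rows$prefix)
  rows[order(rows$name), c("name", "db_type", "prefix")]
}

#' Select the BLAST program for a query/database pairing
#'
#' Nucleotide database + amino-acid query = `tblastn`; protein database +
#' amino-acid query = `blastp`; nucleotide database + nucleotide query
#' (`nucleotide_query = TRUE`) = `blastn`. A protein database cannot take
#' a nucleotide query.
#'
#' @param db_type `"nucl"` or `"prot"`.
#' @param nucleotide_query Query is nucleotide rather than amino acid.
#' @return `"blastn"`, `"blastp"` or `"tblastn"`.
#' @export
select_program <- function(db_type, nucleotide_query = FALSE) {
  db_type <- match.arg(db_type, c("nucl", "prot"))
  if (nucleotide_query) {
    if (db_type == "prot") {
      stop("no supported program for a nucleotide query against a protein database")
    }
    return("blastn")
  }
  if (db_type == "nucl") "tblastn" else "blastp"
}

#' Query coverage from alignment coordinates
#'
#' `100 * (qend - qstart + 1) / qlen`, rounded to 2 decimals — the fraction
#' of the query spanned by the aligned region.
#'
#' @param qstart,qend 1-based inclusive query coordinates, `qstart <= qend`.
#' @param qlen Query length.
#' @return Percent coverage (vectorized).
#' @export
compute_query_coverage <- function(qstart, qend, qlen) {
  if (any(qstart < 1L | qstart > qend | qend > qlen)) {
    stop("require 1 <= qstart <= qend <= qlen")
  }
  round(100 * (qend - qstart + 1) / qlen, 2)
}

empty_hits <- function() {
  data.frame(
    qseqid = character(), sseqid = character(), pident = numeric(),
    evalue = numeric(), length = integer(), mismatch = integer(),
    gapopen = integer(), qstart = integer(), qend = integer(),
    sstart = integer(), send = integer(), bitscore = numeric(),
    qlen = integer(), sframe = integer(), qcov = numeric(),
    query_file = character(), database = character(),
    subject_residues = character(), program = character(),
    stringsAsFactors = FALSE
  )
}

parse_blast_tabular <- function(lines, query_file, database, program) {
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  mat <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  df <- data.frame(
    qseqid = mat[, 1], sseqid = mat[, 2],
    pident = as.numeric(mat[, 3]), evalue = as.numeric(mat[, 4]),
    length = as.integer(mat[, 5]), mismatch = as.integer(mat[, 6]),
    gapopen = as.integer(mat[, 7]), qstart = as.integer(mat[, 8]),
    qend = as.integer(mat[, 9]), sstart = as.integer(mat[, 10]),
    send = as.integer(mat[, 11]), bitscore = as.numeric(mat[, 12]),
    qlen = as.integer(mat[, 13]), sframe = as.integer(mat[, 14]),
    stringsAsFactors = FALSE
  )
  df$qcov <- compute_query_coverage(df$qstart, df$qend, df$qlen)
  df$query_file <- query_file
  df$database <- database
  df$subject_residues <- mat[, 15]
  df$program <- program
  df
}

# Deterministic table order: pairing, then significance.
canonical_hit_sort <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_file, hits$database, hits$evalue, -hits$bitscore,
             hits$sseqid, hits$sstart)
  hits[o, , drop = FALSE]
}

#' Filter hits against inclusion thresholds
#'
#' Retains exactly the hits with `pident >= min_identity`,
#' `qcov >= min_coverage` and `evalue <= max_evalue` (all inclusive).
#' Idempotent, and tightening any threshold never adds a row.
#'
#' @param hits Hit table (rows of the results schema).
#' @param thresholds A [threshold_set()].
#' @return The retained subset.
#' @export
filter_hits <- function(hits, thresholds = threshold_set()) {
  if (!nrow(hits)) return(hits)
  keep <- hits$pident >= thresholds$min_identity &
    hits$qcov >= thresholds$min_coverage &
    hits$evalue <= thresholds$max_evalue
  hits[keep, , drop = FALSE]
}

#' Strongest match per query-file x database pairing
#'
#' Exactly one hit per pairing that has any filtered hit: maximal
#' bitscore, ties broken by minimal evalue, then maximal pident, then
#' lexicographic sseqid.
#'
#' @param filtered Threshold-filtered hit table.
#' @return One-row-per-pairing subset.
#' @export
strongest_matches <- function(filtered) {
  if (!nrow(filtered)) return(filtered)
  key <- paste(filtered$query_file, filtered$database, sep = "\r")
  pick <- vapply(split(seq_len(nrow(filtered)), key), function(idx) {
    sub <- filtered[idx, , drop = FALSE]
    idx[order(-sub$bitscore, sub$evalue, -sub$pident, sub$sseqid)[1L]]
  }, integer(1))
  canonical_hit_sort(filtered[sort(pick), , drop = FALSE])
}

run_pairing <- function(query, db, nucleotide_query, align_dir) {
  program <- select_program(db$db_type, nucleotide_query)
  args <- c("-query", shQuote(query), "-db", shQuote(db$prefix),
            "-outfmt", shQuote(BLAST_OUTFMT))
  out <- suppressWarnings(system2(program, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop(program, " failed for ", file_stem(query), " vs ", db$name, ": ",
         paste(utils::tail(out, 2L), collapse = " "))
  }
  # stderr is interleaved when captured; tabular rows always have 15 fields
  tab <- out[vapply(strsplit(out, "\t", fixed = TRUE), length, integer(1)) == 15L]
  hits <- parse_blast_tabular(tab, file_stem(query), db$name, program)
  if (!is.null(align_dir)) {
    aln <- file.path(align_dir,
                     paste0(file_stem(query), "_vs_", db$name, ".txt"))
    suppressWarnings(system2(program, c(args[1:4], "-out", shQuote(aln)),
                             stdout = FALSE, stderr = FALSE))
  }
  hits
}

#' Run every query x database pairing and curate results tables
#'
#' Each query file is one task; tasks run in parallel up to `threads`,
#' databases within a task sequentially. The program per pairing comes
#' from [select_program()]. Results are concatenated, canonically sorted
#' (so tables are invariant to the thread count) and written as
#' `all_results.csv` (every hit, no thresholds applied),
#' `all_filtered_results.csv` (thresholded) and, when
#' `report_strongest = TRUE`, `filtered_results.csv` (strongest match per
#' pairing). Human-readable pairwise alignment files are written per
#' pairing unless `write_alignments = FALSE`. A failing pairing is
#' reported by name without aborting the others.
#'
#' @param queries Character vector of query FASTA paths (or a
#'   `fasta_collection`).
#' @param dbs Database table from [make_databases()] /
#'   [discover_databases()].
#' @param thresholds A [threshold_set()].
#' @param threads Parallel query tasks.
#' @param out_dir Output directory for tables, alignments and the run log
#'   (`NULL`: nothing written, tables returned only).
#' @param nucleotide_query Queries are nucleotide (use blastn).
#' @param write_alignments Also write pairwise alignment text files.
#' @param report_strongest Also write `filtered_results.csv`.
#' @param quiet Suppress progress messages.
#' @return A `blast_results` list: `all`, `filtered`, `strongest` hit
#'   tables (in-memory rows also carry `subject_residues` and `program`)
#'   and `failures` (character vector naming failed pairings).
#' @export
run_queries <- function(queries, dbs, thresholds = threshold_set(),
                        threads = 1L, out_dir = NULL,
                        nucleotide_query = FALSE, write_alignments = TRUE,
                        report_strongest = FALSE, quiet = FALSE) {
  if (inherits(queries, "fasta_collection")) queries <- queries$entries$path
  if (!length(queries)) stop("no query files given")
  if (is.null(dbs) || !nrow(dbs)) stop("no databases given")
  for (p in unique(vapply(dbs$db_type, select_program, character(1),
                          nucleotide_query = nucleotide_query))) {
    require_binary(p)
  }
  align_dir <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (write_alignments) {
      align_dir <- file.path(out_dir, "alignments")
      dir.create(align_dir, showWarnings = FALSE)
    }
    log_run(out_dir, "query",
            list(queries = length(queries), databases = nrow(dbs),
                 threads = threads, identity = thresholds$min_identity,
                 coverage = thresholds$min_coverage,
                 evalue = thresholds$max_evalue))
  }

  run_task <- function(q) {
    hits <- list()
    failures <- character()
    for (i in seq_len(nrow(dbs))) {
      res <- tryCatch(run_pairing(q, dbs[i, ], nucleotide_query, align_dir),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures,
                      paste0(file_stem(q), " vs ", dbs$name[i], ": ",
                             conditionMessage(res)))
      } else {
        hits[[length(hits) + 1L]] <- res
      }
    }
    list(hits = if (length(hits)) do.call(rbind, hits) else empty_hits(),
         failures = failures)
  }
  tasks <- parallel::mclapply(queries, run_task,
                              mc.cores = max(1L, min(threads, length(queries))))
  bad <- vapply(tasks, inherits, logical(1), what = c("try-error", "error"))
  if (any(bad)) stop("query task crashed: ",
                     conditionMessage(tasks[[which(bad)[1L]]]))

  all_hits <- canonical_hit_sort(
    do.call(rbind, c(lapply(tasks, `[[`, "hits"), list(empty_hits()))))
  rownames(all_hits) <- NULL
  failures <- unlist(lapply(tasks, `[[`, "failures"))
  if (length(failures)) {
    warning("failed pairing(s): ", paste(failures, collapse = "; "),
            call. = FALSE)
  }
  filtered <- filter_hits(all_hits, thresholds)
  strongest <- strongest_matches(filtered)
  results <- structure(list(all = all_hits, filtered = filtered,
                            strongest = strongest, failures = failures,
                            thresholds = thresholds),
                       class = "blast_results")
  if (!is.null(out_dir)) {
    write_results(all_hits, file.path(out_dir, "all_results.csv"))
    write_results(filtered, file.path(out_dir, "all_filtered_results.csv"))
    if (report_strongest) {
      write_results(strongest, file.path(out_dir, "filtered_results.csv"))
    }
  }
  bm_message(nrow(all_hits), " hit(s) across ",
             length(queries) * nrow(dbs), " pairing(s); ",
             nrow(filtered), " pass thresholds", quiet = quiet)
  results
}

#' @export
print.blast_results <- function(x, ...) {
  cat("blast_results:", nrow(x$all), "hit(s),", nrow(x$filtered),
      "filtered,", nrow(x$strongest), "strongest\n")
  if (length(x$failures)) cat("failed pairings:", length(x$failures), "\n")
  invisible(x)
}

#' Write a hit table as RFC-4180 CSV
#'
#' Emits exactly the 17 canonical result columns (internal columns such as
#' `subject_residues` and `program` are dropped). `qcov` is written with 2
#' decimals.
#'
#' @param hits Hit table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(hits, path) {
  out <- hits[, HIT_COLUMNS, drop = FALSE]
  out$qcov <- sprintf("%.2f", out$qcov)
  if (!nrow(out)) out$qcov <- character()
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a results CSV (any of the three schemas)
#'
#' @param path Path to `all_results.csv`, `all_filtered_results.csv` or
#'   `filtered_results.csv`.
#' @return Hit table data.frame.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sseqid", "sstart", "send", "database"), names(df))
  if (length(missing)) {
    stop("not a results table (missing columns: ",
         paste(missing, collapse = ", "), "): ", path)
  }
  df
}
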