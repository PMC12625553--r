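# Extraction of aligned regions (with optional flanking padding) or whole
# contigs from the source FASTA files referenced by a results table.
#
# Coordinates follow the BLAST convention: 1-based inclusive, with
# minus-strand subject hits encoded by sstart > send (blastn/tblastn).
# Padding is oriented: pad_up extends the 5' side of the hit in hit
# orientation, and minus-strand output is reverse-complemented so the
# extracted region reads in gene orientation.

#' Locate the source FASTA for a database name
#'
#' Returns the unique file in `fasta_dir` whose stem equals
#' `database_name` under any canonical FASTA extension (optionally
#' gzipped).
#'
#' @param database_name Database name (sanitized source stem).
#' @param fasta_dir Directory holding the source FASTA files.
#' @return Path to the matching file.
#' @export
locate_source_fasta <- function(database_name, fasta_dir) {
  if (!dir.exists(fasta_dir)) stop("FASTA directory not found: ", fasta_dir)
  files <- list.files(fasta_dir, full.names = TRUE)
  files <- files[has_fasta_extension(files)]
  hits <- files[file_stem(files) == database_name]
  if (!length(hits)) {
    stop("no FASTA file with stem '", database_name, "' in ", fasta_dir)
  }
  if (length(hits) > 1L) {
    stop("ambiguous source for database '", database_name, "': ",
         paste(basename(hits), collapse = ", "))
  }
  hits
}

#' Extract the aligned region of one hit, with padding and clamping
#'
#' Plus-strand hits (`sstart <= send`) yield the slice
#' `[sstart - pad_up, send + pad_down]` clamped to the contig;
#' minus-strand hits (`sstart > send`) yield the reverse complement of
#' the clamped plus-strand slice `[send - pad_down, sstart + pad_up]`,
#' so the output reads in hit orientation with `pad_up` on its 5' side.
#'
#' @param hit One results-table row (list or one-row data.frame with
#'   `sseqid`, `sstart`, `send`, `database`).
#' @param contigs Named character vector (or record table from
#'   [read_fasta()]) mapping contig id to residues.
#' @param pad_up,pad_down Flanking residues on the 5'/3' side of the hit
#'   (bp for nucleotide subjects, residues for protein subjects).
#' @return An `extracted_region` list: `database`, `contig`, `requested`
#'   and `applied` intervals (1-based inclusive, plus-strand frame),
#'   `strand` (`"+"`/`"-"`), `residues`.
#' @export
extract_hit <- function(hit, contigs, pad_up = 0L, pad_down = 0L) {
  if (pad_up < 0L || pad_down < 0L) stop("padding must be >= 0")
  if (is.data.frame(contigs)) {
    contigs <- stats::setNames(contigs$residues, contigs$id)
  }
  id <- as.character(hit$sseqid)
  if (!id %in% names(contigs)) {
    stop("contig '", id, "' not found in source FASTA for database '",
         hit$database, "'")
  }
  seq <- contigs[[id]]
  len <- nchar(seq)
  sstart <- as.integer(hit$sstart)
  send <- as.integer(hit$send)
  if (is.na(sstart) || is.na(send) || sstart < 1L || send < 1L ||
      sstart > len || send > len) {
    stop("malformed subject coordinates (", sstart, ", ", send,
         ") for contig '", id, "' of length ", len)
  }
  minus <- sstart > send
  requested <- if (minus) c(send - pad_down, sstart + pad_up)
               else c(sstart - pad_up, send + pad_down)
  applied <- c(max(1L, requested[1]), min(len, requested[2]))
  residues <- substring(seq, applied[1], applied[2])
  if (minus) residues <- rev_comp(residues)
  structure(list(database = as.character(hit$database), contig = id,
                 requested = requested, applied = applied,
                 strand = if (minus) "-" else "+", residues = residues),
            class = "extracted_region")
}

#' Extract the whole contig a hit landed on
#'
#' @param hit One results-table row (needs `sseqid`, `database`).
#' @param contigs Contig map as in [extract_hit()].
#' @return A one-row record table (`id`, `description`, `residues`).
#' @export
extract_contig <- function(hit, contigs) {
  if (is.data.frame(contigs)) {
    desc <- stats::setNames(contigs$description, contigs$id)
    contigs <- stats::setNames(contigs$residues, contigs$id)
  } else {
    desc <- stats::setNames(rep("", length(contigs)), names(contigs))
  }
  id <- as.character(hit$sseqid)
  if (!id %in% names(contigs)) {
    stop("contig '", id, "' not found in source FASTA for database '",
         hit$database, "'")
  }
  data.frame(id = id, description = desc[[id]], residues = contigs[[id]],
             stringsAsFactors = FALSE)
}

region_header <- function(r) {
  sprintf("%s|%s|%d-%d|%s", r$database, r$contig, r$applied[1], r$applied[2],
          r$strand)
}

region_description <- function(r) {
  clamped <- !identical(r$requested, r$applied)
  paste0("requested=", r$requested[1], "-", r$requested[2],
         if (clamped) " clamped" else "")
}

load_results_table <- function(results) {
  if (is.character(results)) read_results(results) else results
}

#' Extract every hit of a results table to multi-FASTA
#'
#' Accepts any of the three results tables (all, filtered, strongest).
#' Hits are processed in canonical table order, grouped by database so
#' each source FASTA is read once.
#'
#' @param results Results CSV path or hit table.
#' @param fasta_dir Directory with the source FASTA files used to build
#'   the databases.
#' @param pad_up,pad_down Oriented flanking padding (see [extract_hit()]).
#' @param out Output multi-FASTA path (`NULL`: no file, table returned
#'   only).
#' @return Data.frame describing each extracted region (one row per hit).
#' @export
extract_regions <- function(results, fasta_dir, pad_up = 0L, pad_down = 0L,
                            out = NULL) {
  hits <- canonical_hit_sort(load_results_table(results))
  if (!nrow(hits)) stop("results table holds no hits")
  if (!is.null(out)) log_run(dirname(out), "extract",
                             list(hits = nrow(hits), up = pad_up, down = pad_down))
  recs <- list()
  meta <- list()
  for (db in unique(hits$database)) {
    contigs <- read_fasta(locate_source_fasta(db, fasta_dir))
    cmap <- stats::setNames(contigs$residues, contigs$id)
    sub <- hits[hits$database == db, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      r <- extract_hit(sub[i, ], cmap, pad_up, pad_down)
      recs[[length(recs) + 1L]] <- data.frame(
        id = region_header(r), description = region_description(r),
        residues = r$residues, stringsAsFactors = FALSE)
      meta[[length(meta) + 1L]] <- data.frame(
        database = r$database, contig = r$contig,
        requested_start = r$requested[1], requested_end = r$requested[2],
        applied_start = r$applied[1], applied_end = r$applied[2],
        strand = r$strand, residues = r$residues, stringsAsFactors = FALSE)
    }
  }
  fasta <- do.call(rbind, recs)
  if (!is.null(out)) write_fasta(fasta, out)
  do.call(rbind, meta)
}

#' Extract the contigs referenced by a results table
#'
#' One multi-FASTA per database; a contig referenced by several hits is
#' written once per output file.
#'
#' @param results Results CSV path or hit table.
#' @param fasta_dir Directory with the source FASTA files.
#' @param out_dir Output directory (one `<database>_contigs.fasta` each).
#' @return Named character vector of written paths.
#' @export
extract_contigs <- function(results, fasta_dir, out_dir = ".") {
  hits <- canonical_hit_sort(load_results_table(results))
  if (!nrow(hits)) stop("results table holds no hits")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_run(out_dir, "extract-contig", list(hits = nrow(hits)))
  paths <- character(0)
  for (db in unique(hits$database)) {
    contigs <- read_fasta(locate_source_fasta(db, fasta_dir))
    wanted <- unique(hits$sseqid[hits$database == db])
    missing <- setdiff(wanted, contigs$id)
    if (length(missing)) {
      stop("contig '", missing[1], "' not found in source FASTA for ",
           "database '", db, "'")
    }
    rec <- contigs[contigs$id %in% wanted, , drop = FALSE]
    path <- file.path(out_dir, paste0(db, "_contigs.fasta"))
    write_fasta(rec, path)
    paths[db] <- path
  }
  paths
}
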