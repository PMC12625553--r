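# FASTA input resolution, sanitization, splitting and header de-duplication.
#
# All downstream modules (database construction, metrics, extraction) consume
# the `fasta_collection` produced by resolve_inputs(), which normalises the
# three accepted input shapes -- a single file (optionally gzipped), a
# directory, or a compressed archive -- into a flat list of validated FASTA
# files plus an optional temporary workspace.

# Canonical FASTA extensions; .faa is the sole amino-acid extension.
FASTA_EXTENSIONS <- c("fasta", "fna", "faa", "fas", "fa", "ffn")

ARCHIVE_PATTERN <- "\\.(zip|tar|tar\\.gz|tgz)$"

#' Molecule type implied by a FASTA file name
#'
#' Canonical nucleotide extensions (`.fasta`, `.fna`, `.fas`, `.fa`, `.ffn`)
#' map to `"nucleotide"`; the amino-acid extension `.faa` maps to
#' `"protein"`. A trailing `.gz` is ignored.
#'
#' @param name File name or path.
#' @return `"nucleotide"` or `"protein"`.
#' @examples
#' detect_molecule_type("q.faa")  # protein
#' detect_molecule_type("g.ffn")  # nucleotide
#' @export
detect_molecule_type <- function(name) {
  vapply(name, function(n) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", n, ignore.case = TRUE)))
    if (!ext %in% FASTA_EXTENSIONS) {
      stop("unrecognized FASTA extension '.", ext, "' in '", basename(n),
           "'; canonical extensions are: ",
           paste0(".", FASTA_EXTENSIONS, collapse = ", "), call. = FALSE)
    }
    if (ext == "faa") "protein" else "nucleotide"
  }, character(1), USE.NAMES = FALSE)
}

#' Sanitize a file name for BLAST+ compatibility
#'
#' Replaces every character outside `[A-Za-z0-9_-]` in the stem with an
#' underscore, collapses runs of underscores, trims leading/trailing
#' underscores, and keeps exactly one extension period. The transformation
#' is idempotent.
#'
#' @param name File name (must have an extension).
#' @return Sanitized file name.
#' @examples
#' sanitize_filename("E. coli (K-12).fna") # "E_coli_K-12.fna"
#' @export
sanitize_filename <- function(name) {
  vapply(name, function(n) {
    n <- basename(n)
    ext <- tools::file_ext(n)
    if (!nzchar(ext)) stop("'", n, "' has no recognizable extension", call. = FALSE)
    stem <- sub(paste0("\\.", ext, "$"), "", n)
    clean <- gsub("[^A-Za-z0-9_-]", "_", stem)
    clean <- gsub("_+", "_", clean)
    clean <- gsub("^_+|_+$", "", clean)
    if (!nzchar(clean)) stop("empty stem after sanitizing '", n, "'", call. = FALSE)
    paste0(clean, ".", ext)
  }, character(1), USE.NAMES = FALSE)
}

# Resolve name collisions by appending _1, _2, ... before the extension.
disambiguate_names <- function(names) {
  out <- character(length(names))
  seen <- character(0)
  for (i in seq_along(names)) {
    cand <- names[i]
    if (cand %in% seen) {
      ext <- tools::file_ext(cand)
      stem <- sub(paste0("\\.", ext, "$"), "", cand)
      k <- 1L
      while (paste0(stem, "_", k, ".", ext) %in% seen) k <- k + 1L
      cand <- paste0(stem, "_", k, ".", ext)
    }
    seen <- c(seen, cand)
    out[i] <- cand
  }
  out
}

#' Read a FASTA file into a record table
#'
#' @param path FASTA file (plain or gzip-compressed).
#' @param molecule Optional override of the molecule type; defaults to the
#'   type implied by the file extension.
#' @return A data.frame with columns `id` (first whitespace-delimited word
#'   of the header), `description` (remainder), `residues` (uppercase) and
#'   `molecule`.
#' @export
read_fasta <- function(path, molecule = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- names(set)[Biostrings::width(set) == 0L]
    stop("record(s) with empty sequence in ", basename(path), ": ",
         paste(bad, collapse = ", "))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(
    id = id,
    description = description,
    residues = toupper(as.character(set)),
    molecule = molecule %||% detect_molecule_type(path),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a record table to FASTA
#'
#' Inverse of [read_fasta()]: every `(id, description, residues)` triple is
#' preserved round-trip.
#'
#' @param records Data.frame with `id`, `description`, `residues` columns.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    seq <- records$residues[i]
    chunks <- substring(seq, seq(1L, nchar(seq), width),
                        pmin(seq(1L, nchar(seq), width) + width - 1L, nchar(seq)))
    writeLines(c(paste0(">", header), chunks), con)
  }
  invisible(path)
}

list_candidate_files <- function(dir) {
  list.files(dir, recursive = TRUE, full.names = TRUE, all.files = FALSE)
}

has_fasta_extension <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path, ignore.case = TRUE)))
  ext %in% FASTA_EXTENSIONS
}

unpack_archive <- function(archive, dest) {
  ok <- tryCatch({
    if (grepl("\\.zip$", archive, ignore.case = TRUE)) {
      utils::unzip(archive, exdir = dest)
    } else {
      utils::untar(archive, exdir = dest)
    }
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("unreadable or corrupt archive: ", archive)
  invisible(dest)
}

stage_gunzip <- function(path, dest) {
  out <- file.path(dest, sub("\\.gz$", "", basename(path), ignore.case = TRUE))
  inc <- gzfile(path, "rb")
  on.exit(close(inc), add = TRUE)
  ouc <- file(out, "wb")
  on.exit(close(ouc), add = TRUE)
  repeat {
    chunk <- readBin(inc, "raw", n = 1024L * 1024L)
    if (length(chunk) == 0L) break
    writeBin(chunk, ouc)
  }
  out
}

#' Resolve heterogeneous FASTA inputs into a validated collection
#'
#' Accepts a single FASTA file (plain or gzipped), a directory (searched
#' recursively), or a compressed archive (`.zip`, `.tar`, `.tar.gz`,
#' `.tgz`). Archive members and gzipped files are staged into a temporary
#' workspace; non-FASTA files are skipped with a notice; every retained
#' file is validated by parsing.
#'
#' @param path_spec Path to a file, directory or archive.
#' @param keep_temp Keep the temporary workspace after
#'   [cleanup_collection()] is called.
#' @param quiet Suppress progress notices.
#' @return A `fasta_collection`: list with `entries` (data.frame of `path`,
#'   `molecule`, `n_records`), `workspace` (path or `NA`) and
#'   `keep_workspace`.
#' @export
resolve_inputs <- function(path_spec, keep_temp = FALSE, quiet = FALSE) {
  if (length(path_spec) != 1L || !file.exists(path_spec)) {
    stop("input path does not exist: ", path_spec)
  }
  workspace <- NULL
  ensure_ws <- function() {
    if (is.null(workspace)) {
      workspace <<- tempfile("blastmine_ws_")
      dir.create(workspace)
    }
    workspace
  }

  from_archive <- FALSE
  if (dir.exists(path_spec)) {
    candidates <- list_candidate_files(path_spec)
  } else if (grepl(ARCHIVE_PATTERN, path_spec, ignore.case = TRUE)) {
    from_archive <- TRUE
    unpack_archive(path_spec, ensure_ws())
    candidates <- list_candidate_files(workspace)
  } else {
    candidates <- path_spec
  }

  is_fa <- has_fasta_extension(candidates)
  skipped <- candidates[!is_fa]
  if (length(skipped)) {
    bm_message("skipping ", length(skipped), " non-FASTA file(s): ",
               paste(basename(utils::head(skipped, 5L)), collapse = ", "),
               if (length(skipped) > 5L) ", ..." else "", quiet = quiet)
  }
  files <- candidates[is_fa]
  if (!length(files)) {
    if (from_archive) stop("archive contains no FASTA files: ", path_spec)
    stop("no FASTA files found under ", path_spec)
  }

  staged <- vapply(files, function(f) {
    if (is_gzip_name(f)) stage_gunzip(f, ensure_ws()) else f
  }, character(1), USE.NAMES = FALSE)

  entries <- list()
  for (f in staged) {
    rec <- tryCatch(read_fasta(f), error = function(e) e)
    if (inherits(rec, "error")) {
      warning("skipping invalid FASTA '", basename(f), "': ",
              conditionMessage(rec), call. = FALSE)
      next
    }
    entries[[length(entries) + 1L]] <- data.frame(
      path = f, molecule = detect_molecule_type(f), n_records = nrow(rec),
      stringsAsFactors = FALSE
    )
  }
  if (!length(entries)) stop("no valid FASTA files under ", path_spec)
  structure(
    list(entries = do.call(rbind, entries),
         workspace = workspace %||% NA_character_,
         keep_workspace = isTRUE(keep_temp)),
    class = "fasta_collection"
  )
}

#' @export
print.fasta_collection <- function(x, ...) {
  cat("fasta_collection:", nrow(x$entries), "file(s),",
      sum(x$entries$n_records), "record(s)\n")
  if (!is.na(x$workspace)) {
    cat("workspace:", x$workspace,
        if (x$keep_workspace) "(kept)" else "(temporary)", "\n")
  }
  invisible(x)
}

#' Remove a collection's temporary workspace
#'
#' The workspace is deleted unless the collection was resolved with
#' `keep_temp = TRUE`.
#'
#' @param collection A `fasta_collection`.
#' @return `TRUE` if a workspace was removed.
#' @export
cleanup_collection <- function(collection) {
  stopifnot(inherits(collection, "fasta_collection"))
  if (!is.na(collection$workspace) && !collection$keep_workspace &&
      dir.exists(collection$workspace)) {
    unlink(collection$workspace, recursive = TRUE)
    return(invisible(TRUE))
  }
  invisible(FALSE)
}

#' Sanitize FASTA file names in a directory
#'
#' Applies [sanitize_filename()] to every matching file, either renaming in
#' place or copying to `outdir`. Collisions after sanitization receive
#' `_1`, `_2`, ... suffixes.
#'
#' @param input Directory (or single file) to process.
#' @param outdir Optional output directory; when given, originals are left
#'   untouched and sanitized copies are created.
#' @param extensions Extensions to act on; the token `"fasta"` expands to
#'   all six canonical FASTA extensions.
#' @return A `sanitization_report` data.frame with columns `old`, `new`
#'   and attribute `mode` (`"in_place"` or `"copy_to_directory"`).
#' @export
sanitize_files <- function(input, outdir = NULL, extensions = "fasta") {
  exts <- if (identical(extensions, "fasta")) FASTA_EXTENSIONS else tolower(extensions)
  files <- if (dir.exists(input)) {
    fs <- list_candidate_files(input)
    fs[tolower(tools::file_ext(fs)) %in% exts]
  } else input
  if (!length(files)) stop("no files with extension(s) ",
                           paste(exts, collapse = ", "), " under ", input)
  new_names <- disambiguate_names(sanitize_filename(basename(files)))
  mode <- if (is.null(outdir)) "in_place" else "copy_to_directory"
  dest <- character(length(files))
  for (i in seq_along(files)) {
    if (mode == "in_place") {
      dest[i] <- file.path(dirname(files[i]), new_names[i])
      if (dest[i] != files[i]) file.rename(files[i], dest[i])
    } else {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      dest[i] <- file.path(outdir, new_names[i])
      file.copy(files[i], dest[i], overwrite = FALSE)
    }
  }
  report <- data.frame(old = files, new = dest, stringsAsFactors = FALSE)
  attr(report, "mode") <- mode
  class(report) <- c("sanitization_report", class(report))
  report
}

#' Split a multi-FASTA file into batches
#'
#' Partitions records, in their original order, into files of `batch_size`
#' records each (the last file may hold fewer). Concatenating the outputs
#' round-trips to the input records.
#'
#' @param file Input FASTA path.
#' @param batch_size Records per output file (default 1: single-record
#'   files).
#' @param output_dir Where to write the parts.
#' @return Character vector of output paths.
#' @export
split_fasta <- function(file, batch_size = 1L, output_dir = dirname(file)) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  records <- read_fasta(file)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  stem <- file_stem(file)
  ext <- tools::file_ext(sub("\\.gz$", "", file, ignore.case = TRUE))
  n_parts <- ceiling(nrow(records) / batch_size)
  paths <- character(n_parts)
  for (i in seq_len(n_parts)) {
    idx <- ((i - 1L) * batch_size + 1L):min(i * batch_size, nrow(records))
    paths[i] <- file.path(output_dir, sprintf("%s_part%d.%s", stem, i, ext))
    write_fasta(records[idx, , drop = FALSE], paths[i])
  }
  paths
}

BASE62 <- c(0:9, LETTERS, letters)

# 5-character tag from the MD5 digest of (residues + full original header):
# the first five digest bytes are mapped through the base-62 alphabet.
deterministic_tag <- function(residues, header) {
  hex <- digest::digest(paste0(residues, header), algo = "md5", serialize = FALSE)
  bytes <- strtoi(substring(hex, seq(1L, 9L, 2L), seq(2L, 10L, 2L)), 16L)
  paste(BASE62[bytes %% 62L + 1L], collapse = "")
}

random_tag <- function() paste(sample(BASE62, 5L, replace = TRUE), collapse = "")

#' Guarantee collision-free FASTA headers
#'
#' Rewrites every record id to `<original id>_<source file stem>_<tag>`
#' where the tag is a 5-character alphanumeric barcode. With
#' `deterministic = TRUE` the barcode derives from the MD5 digest of the
#' record's residues plus its full original header, so reruns produce
#' byte-identical output; otherwise tags are drawn at random (optionally
#' seeded). Residual collisions (e.g. byte-identical duplicate records in
#' deterministic mode) receive a numeric suffix so output ids are always
#' pairwise distinct.
#'
#' @param x A `fasta_collection` or character vector of FASTA paths.
#' @param deterministic Use MD5-derived tags.
#' @param seed Optional RNG seed for random tags.
#' @param output_dir Write rewritten files here (default: in place).
#' @return A `fasta_collection` over the rewritten files.
#' @export
assign_unique_headers <- function(x, deterministic = FALSE, seed = NULL,
                                  output_dir = NULL) {
  paths <- if (inherits(x, "fasta_collection")) x$entries$path else x
  if (!length(paths)) stop("empty collection")
  if (!is.null(seed)) set.seed(seed)
  used <- new.env(parent = emptyenv())
  out_paths <- character(length(paths))
  for (i in seq_along(paths)) {
    rec <- read_fasta(paths[i])
    stem <- file_stem(paths[i])
    header <- ifelse(nzchar(rec$description),
                     paste(rec$id, rec$description), rec$id)
    new_id <- character(nrow(rec))
    for (j in seq_len(nrow(rec))) {
      tag <- if (deterministic) deterministic_tag(rec$residues[j], header[j])
             else random_tag()
      cand <- paste(rec$id[j], stem, tag, sep = "_")
      if (!deterministic) {
        tries <- 0L
        while (!is.null(used[[cand]]) && tries < 25L) {
          cand <- paste(rec$id[j], stem, random_tag(), sep = "_")
          tries <- tries + 1L
        }
      }
      if (!is.null(used[[cand]])) {
        k <- 1L
        while (!is.null(used[[paste0(cand, "_", k)]])) k <- k + 1L
        cand <- paste0(cand, "_", k)
      }
      used[[cand]] <- TRUE
      new_id[j] <- cand
    }
    rec$id <- new_id
    out <- if (is.null(output_dir)) paths[i] else {
      if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
      file.path(output_dir, basename(paths[i]))
    }
    write_fasta(rec, out)
    out_paths[i] <- out
  }
  entries <- do.call(rbind, lapply(out_paths, function(p) {
    data.frame(path = p, molecule = detect_molecule_type(p),
               n_records = nrow(read_fasta(p)), stringsAsFactors = FALSE)
  }))
  structure(list(entries = entries, workspace = NA_character_,
                 keep_workspace = FALSE),
            class = "fasta_collection")
}
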