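# Harvest assembly metadata from GenBank flat files and NCBI-style JSON
# assembly reports into CSV/TSV/JSON tables. Missing values are always the
# literal string "not_specified" -- never an empty cell.

DEFAULT_METADATA_FIELDS <- c("accession", "organism", "host",
                             "isolation_source", "collection_region")

NOT_SPECIFIED <- "not_specified"

# Pull every /qualifier="value" (with continuation lines) from the source
# feature of a GenBank flat file, plus accession/organism from the header.
parse_genbank_metadata <- function(lines) {
  out <- list()
  acc <- grep("^VERSION\\s+", lines, value = TRUE)
  if (!length(acc)) acc <- grep("^ACCESSION\\s+", lines, value = TRUE)
  if (length(acc)) out$accession <- strsplit(trimws(sub("^\\S+\\s+", "", acc[1])), "\\s+")[[1]][1]
  org <- grep("^\\s{0,4}ORGANISM\\s+", lines, value = TRUE)
  if (length(org)) out$organism <- trimws(sub("^\\s*ORGANISM\\s+", "", org[1]))

  feat <- which(grepl("^FEATURES", lines))
  if (length(feat)) {
    block <- lines[(feat[1] + 1L):length(lines)]
    stop_at <- which(grepl("^(ORIGIN|CONTIG|//)", block))
    if (length(stop_at)) block <- block[seq_len(stop_at[1] - 1L)]
    # restrict to the source feature
    src <- which(grepl("^\\s{1,10}source\\s", block))
    if (length(src)) {
      after <- block[(src[1] + 1L):length(block)]
      next_feat <- which(grepl("^\\s{1,10}\\S+\\s{2,}", after) &
                           !grepl("^\\s{10,}", after))
      if (length(next_feat)) after <- after[seq_len(next_feat[1] - 1L)]
      # join continuation lines onto their qualifier
      joined <- character(0)
      for (ln in trimws(after)) {
        if (startsWith(ln, "/")) joined <- c(joined, ln)
        else if (length(joined)) joined[length(joined)] <- paste(joined[length(joined)], ln)
      }
      for (q in joined) {
        m <- regmatches(q, regexec('^/([A-Za-z_]+)="?([^"]*)"?$', q))[[1]]
        if (length(m) == 3L && nzchar(m[3])) out[[m[2]]] <- m[3]
      }
    }
  }
  out
}

# NCBI datasets assembly data-report shape (camelCase keys), with tolerant
# fallbacks for flat key/value objects.
parse_json_metadata <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # datasets reports wrap records in a "reports" array; take the first
  if (!is.null(j$reports)) j <- as.list(as.data.frame(j$reports)[1, ])
  out <- list()
  grab <- function(...) {
    for (k in c(...)) {
      v <- tryCatch(j[[k]], error = function(e) NULL)
      if (!is.null(v) && length(v) && nzchar(as.character(v)[1])) {
        return(as.character(v)[1])
      }
    }
    NULL
  }
  out$accession <- grab("accession", "assemblyAccession", "currentAccession")
  org <- j$organism
  if (is.list(org)) {
    out$organism <- as.character(org$organismName %||% org$organism_name %||% "")
  } else {
    out$organism <- grab("organismName", "organism_name", "organism")
  }
  if (!nzchar(out$organism %||% "")) out$organism <- NULL
  # biosample attributes: list of {name, value}
  attrs <- tryCatch(j$assemblyInfo$biosample$attributes,
                    error = function(e) NULL)
  if (is.null(attrs)) attrs <- tryCatch(j$biosample$attributes,
                                        error = function(e) NULL)
  if (!is.null(attrs)) {
    if (is.data.frame(attrs)) {
      for (i in seq_len(nrow(attrs))) out[[attrs$name[i]]] <- attrs$value[i]
    } else if (is.list(attrs)) {
      for (a in attrs) if (!is.null(a$name)) out[[a$name]] <- a$value
    }
  }
  # flat fallbacks
  for (k in c("host", "isolation_source", "geo_loc_name", "country")) {
    if (is.null(out[[k]]) && !is.null(j[[k]])) out[[k]] <- as.character(j[[k]])
  }
  out
}

is_genbank_file <- function(path) {
  head <- readLines(path, n = 5L, warn = FALSE)
  any(grepl("^LOCUS\\s", head))
}

# Map raw qualifier names onto the reported field vocabulary:
# collection_region <- geo_loc_name, falling back to the retired /country.
normalize_metadata <- function(raw) {
  raw$collection_region <- raw$geo_loc_name %||% raw$country %||%
    raw$collection_region
  raw
}

#' Harvest assembly metadata from GenBank/JSON files
#'
#' Each input file yields one record. GenBank flat files are mined for
#' ACCESSION/VERSION, SOURCE/ORGANISM and the source-feature qualifiers
#' (`/host`, `/isolation_source`, `/geo_loc_name` with `/country`
#' fallback, ...); JSON files are read as NCBI-style assembly data
#' reports. Files are typed by content (LOCUS line vs JSON), not
#' extension. Missing values are filled with `"not_specified"`.
#'
#' @param paths A file, vector of files, or a directory.
#' @param fields Fields to report, in output order; defaults to
#'   accession, organism, host, isolation_source, collection_region.
#' @param all_fields Report the union of every field found across the
#'   batch (ordered by first appearance after the defaults).
#' @return Data.frame with one row per parseable input file plus a
#'   `file` column.
#' @export
harvest_metadata <- function(paths, fields = DEFAULT_METADATA_FIELDS,
                             all_fields = FALSE) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
    if (!length(paths)) stop("empty directory")
  }
  records <- list()
  for (p in paths) {
    rec <- tryCatch({
      if (is_genbank_file(p)) {
        normalize_metadata(parse_genbank_metadata(readLines(p, warn = FALSE)))
      } else {
        normalize_metadata(parse_json_metadata(p))
      }
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      warning("skipping unparseable metadata file '", basename(p), "': ",
              conditionMessage(rec), call. = FALSE)
      next
    }
    rec$file <- basename(p)
    records[[length(records) + 1L]] <- rec
  }
  if (!length(records)) stop("no parseable metadata files among inputs")
  if (all_fields) {
    extra <- setdiff(unique(unlist(lapply(records, names))),
                     c(DEFAULT_METADATA_FIELDS, "file", "geo_loc_name", "country"))
    fields <- c(DEFAULT_METADATA_FIELDS, extra)
  }
  rows <- lapply(records, function(r) {
    vals <- vapply(fields, function(f) as.character(r[[f]] %||% NOT_SPECIFIED),
                   character(1))
    as.data.frame(c(list(file = r$file), as.list(vals)),
                  stringsAsFactors = FALSE, optional = TRUE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("file", fields)
  rownames(out) <- NULL
  out
}

#' Write a metadata table as CSV, TSV or JSON
#'
#' CSV and TSV emissions are cell-for-cell identical; JSON round-trips to
#' the same record list via [jsonlite::fromJSON()].
#'
#' @param records Data.frame from [harvest_metadata()].
#' @param out Output path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @return `out`, invisibly.
#' @export
write_metadata <- function(records, out, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  switch(format,
    csv = utils::write.csv(records, out, row.names = FALSE),
    tsv = utils::write.table(records, out, sep = "\t", row.names = FALSE,
                             quote = TRUE),
    json = jsonlite::write_json(records, out, dataframe = "rows",
                                auto_unbox = TRUE, pretty = TRUE)
  )
  invisible(out)
}
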