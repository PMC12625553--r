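# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
bm_message <- function(..., quiet = FALSE) {
  if (!isTRUE(quiet)) message(...)
  invisible(NULL)
}

# Append a timestamped line to the run log of an output directory. Every
# pipeline command (makedb, query, extract, ...) records its inputs and
# parameters so a run can be reconstructed later.
log_run <- function(dir, command, params = list()) {
  if (is.null(dir) || !nzchar(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kv <- if (length(params)) {
    paste(names(params), vapply(params, function(x) paste(format(x), collapse = ","),
                                character(1)), sep = "=", collapse = " ")
  } else ""
  line <- sprintf("%s %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), command, kv)
  cat(line, "\n", file = file.path(dir, "blastmine.log"), append = TRUE, sep = "")
  invisible(line)
}

# File stem: basename without a trailing .gz and without the final extension.
file_stem <- function(path) {
  b <- basename(path)
  b <- sub("\\.gz$", "", b, ignore.case = TRUE)
  sub("\\.[^.]*$", "", b)
}

is_gzip_name <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

#' Reverse complement of a nucleotide sequence
#'
#' Thin wrapper over [Biostrings::reverseComplement()] accepting and
#' returning plain character strings. IUPAC ambiguity codes and gap
#' characters are handled by Biostrings.
#'
#' @param x A character vector of nucleotide sequences.
#' @return A character vector of the same length.
#' @examples
#' rev_comp("ACGTN") # "NACGT"
#' @export
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
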