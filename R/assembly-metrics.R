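# Per-file assembly statistics: size, contig counts, GC%, N counts,
# N50/N90 and L50/L90 under the standard cumulative-prefix rule.

#' N and L statistics of a contig length list
#'
#' With lengths sorted descending, N is the length at which the running sum
#' first reaches `fraction` of the total, and L is the number of contigs
#' consumed to reach it. `fraction = 0.5` gives N50/L50, `0.9` gives
#' N90/L90.
#'
#' @param lengths Positive contig lengths (bp).
#' @param fraction Proportion in (0, 1).
#' @return List with elements `n` (bp) and `l` (contig count).
#' @examples
#' n_statistic(c(40, 30, 20, 10), 0.5) # n = 30, l = 2
#' @export
n_statistic <- function(lengths, fraction = 0.5) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  idx <- which(cum >= fraction * cum[length(cum)])[1L]
  list(n = s[idx], l = idx)
}

#' Assembly metrics for a set of contigs
#'
#' GC% uses all residues (including N and other ambiguity codes) as the
#' denominator; N content is reported separately. Counting is
#' case-insensitive and the result does not depend on record order.
#'
#' @param records Record table from [read_fasta()] (columns `id`,
#'   `residues`).
#' @return An `assembly_metrics` list: `genome_size`, `contig_count`,
#'   `gc_percent`, `n_count`, `n50`, `n90`, `l50`, `l90`, `longest`,
#'   `shortest`, `lengths` (descending), `length_distribution`
#'   (min/Q1/median/mean/Q3/max).
#' @export
compute_metrics <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no records to summarize")
  seqs <- Biostrings::BStringSet(toupper(records$residues))
  lens <- Biostrings::width(seqs)
  freq <- Biostrings::letterFrequency(seqs, letters = c("G", "C", "N"))
  total <- sum(as.numeric(lens))
  n50 <- n_statistic(lens, 0.5)
  n90 <- n_statistic(lens, 0.9)
  q <- stats::quantile(lens, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  structure(list(
    genome_size = total,
    contig_count = length(lens),
    gc_percent = 100 * sum(as.numeric(freq[, "G"]) + as.numeric(freq[, "C"])) / total,
    n_count = sum(freq[, "N"]),
    n50 = n50$n, n90 = n90$n, l50 = n50$l, l90 = n90$l,
    longest = max(lens), shortest = min(lens),
    lengths = sort(lens, decreasing = TRUE),
    length_distribution = c(min = q[1], q1 = q[2], median = q[3],
                            mean = mean(lens), q3 = q[4], max = q[5])
  ), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(
    "assembly: %s bp in %d contig(s)\nGC %.2f%%  N count %d\nN50 %d (L50 %d)  N90 %d (L90 %d)\nlongest %d  shortest %d\n",
    format(x$genome_size, big.mark = ","), x$contig_count, x$gc_percent,
    x$n_count, x$n50, x$l50, x$n90, x$l90, x$longest, x$shortest))
  invisible(x)
}

#' Assembly metrics for every FASTA file in an input
#'
#' Resolves `path_spec` like [resolve_inputs()] and computes
#' [compute_metrics()] per file. The `lengths` column joins the descending
#' contig lengths with `"|"`.
#'
#' @param path_spec File, directory or archive of FASTA files.
#' @param output Optional CSV path.
#' @return Data.frame with one row per FASTA file.
#' @export
fasta_metrics <- function(path_spec, output = NULL) {
  coll <- resolve_inputs(path_spec, quiet = TRUE)
  on.exit(cleanup_collection(coll))
  rows <- lapply(seq_len(nrow(coll$entries)), function(i) {
    p <- coll$entries$path[i]
    m <- compute_metrics(read_fasta(p))
    data.frame(
      file = basename(p),
      genome_size = m$genome_size, contig_count = m$contig_count,
      gc_percent = round(m$gc_percent, 2), n_count = m$n_count,
      n50 = m$n50, n90 = m$n90, l50 = m$l50, l90 = m$l90,
      longest = m$longest, shortest = m$shortest,
      min = m$length_distribution[["min"]],
      q1 = m$length_distribution[["q1"]],
      median = m$length_distribution[["median"]],
      mean = round(m$length_distribution[["mean"]], 2),
      q3 = m$length_distribution[["q3"]],
      max = m$length_distribution[["max"]],
      lengths = paste(m$lengths, collapse = "|"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(output)) utils::write.csv(out, output, row.names = FALSE)
  out
}
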