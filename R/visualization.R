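# Percent-identity heatmaps for multi-database queries and per-motif
# sequence logos (position frequencies scaled by information content).

#' Percent-identity matrix of filtered hits
#'
#' Cell (query, database) holds the maximum pident among that pairing's
#' filtered hits; pairings without a hit stay `NA` and are rendered in a
#' reserved "no hit" color. A heatmap is only meaningful for queries
#' against more than one database; with a single database `NULL` is
#' returned.
#'
#' @param filtered Threshold-filtered hit table.
#' @param queries Row order (query-file stems); default: those present.
#' @param dbs Column order (database names); default: those present.
#' @return Numeric matrix (rows = queries, columns = databases), or
#'   `NULL` when fewer than 2 databases are involved.
#' @export
build_identity_matrix <- function(filtered, queries = NULL, dbs = NULL) {
  queries <- queries %||% sort(unique(filtered$query_file))
  dbs <- dbs %||% sort(unique(filtered$database))
  if (length(dbs) < 2L) {
    message("heatmap skipped: queries ran against fewer than 2 databases")
    return(NULL)
  }
  mat <- matrix(NA_real_, nrow = length(queries), ncol = length(dbs),
                dimnames = list(queries, dbs))
  if (nrow(filtered)) {
    agg <- stats::aggregate(pident ~ query_file + database, data = filtered,
                            FUN = max)
    keep <- agg$query_file %in% queries & agg$database %in% dbs
    agg <- agg[keep, , drop = FALSE]
    mat[cbind(agg$query_file, agg$database)] <- agg$pident
  }
  mat
}

#' Heatmap of a percent-identity matrix
#'
#' @param mat Matrix from [build_identity_matrix()].
#' @return A ggplot object.
#' @export
plot_identity_heatmap <- function(mat) {
  df <- expand.grid(query = rownames(mat), database = colnames(mat),
                    stringsAsFactors = FALSE)
  df$pident <- as.vector(mat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$database, y = .data$query,
                                   fill = .data$pident)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), na.value = "grey85",
                                  name = "% identity") +
    ggplot2::labs(x = "database", y = "query") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Position frequencies and information content of motif matches
#'
#' Builds the per-position residue frequency profile of the matched
#' strings of one pattern, plus the information content per position,
#' `R = log2(20) - H` bits, where H is the Shannon entropy of the column
#' distribution. Frequencies at each position sum to 1; information lies
#' in `[0, log2(20)]`, attaining the upper bound exactly for an
#' all-identical column.
#'
#' @param matched Character vector of matched strings (equal length), or
#'   a `motif_matches` table filtered to one pattern.
#' @param pattern Pattern label (taken from the table when omitted).
#' @return A `motif_profile` list: `pattern`, `n`, `frequencies`
#'   (residue x position matrix), `information` (bits per position), or
#'   `NULL` when there are no matches.
#' @export
build_motif_profile <- function(matched, pattern = NULL) {
  if (is.data.frame(matched)) {
    pattern <- pattern %||% unique(matched$pattern)
    if (length(pattern) != 1L) {
      stop("profile needs matches of exactly one pattern")
    }
    matched <- matched$matched[matched$pattern == pattern]
  }
  if (!length(matched)) return(NULL)
  k <- unique(nchar(matched))
  if (length(k) != 1L) stop("matched strings must share the pattern length")
  chars <- do.call(rbind, strsplit(toupper(matched), ""))
  letters_seen <- sort(unique(as.vector(chars)))
  freq <- vapply(seq_len(k), function(pos) {
    tab <- table(factor(chars[, pos], levels = letters_seen))
    as.numeric(tab) / length(matched)
  }, numeric(length(letters_seen)))
  freq <- matrix(freq, nrow = length(letters_seen), ncol = k,
                 dimnames = list(letters_seen, NULL))
  info <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    max(0, min(log2(20), log2(20) + sum(p * log2(p))))
  })
  structure(list(pattern = pattern %||% "motif", n = length(matched),
                 frequencies = freq, information = info),
            class = "motif_profile")
}

#' Sequence logo of a motif profile
#'
#' Letters are stacked per position with heights proportional to
#' frequency scaled by the position's information content (bits).
#'
#' @param profile A `motif_profile` from [build_motif_profile()].
#' @return A ggplot object.
#' @export
plot_motif_logo <- function(profile) {
  stopifnot(inherits(profile, "motif_profile"))
  freq <- profile$frequencies
  rows <- list()
  for (pos in seq_len(ncol(freq))) {
    p <- freq[, pos]
    p <- p[p > 0]
    p <- sort(p)  # tallest letter on top
    h <- p * profile$information[pos]
    top <- cumsum(h)
    rows[[pos]] <- data.frame(position = pos, letter = names(p),
                              ymin = top - h, ymax = top,
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$position - 0.45,
                                    xmax = .data$position + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$letter),
                       alpha = 0.25, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(x = .data$position,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$letter,
                                    color = .data$letter,
                                    size = .data$ymax - .data$ymin),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 9)) +
    ggplot2::scale_y_continuous(limits = c(0, log2(20)),
                                name = "information (bits)") +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(freq)),
                                name = "position") +
    ggplot2::ggtitle(profile$pattern) +
    ggplot2::theme_minimal()
}

#' Render a figure to PNG (300 dpi) or PDF
#'
#' @param plot A ggplot object.
#' @param out_path Output path; the extension is adjusted to match the
#'   requested format.
#' @param pdf Write PDF instead of the default 300-dpi PNG.
#' @param width,height Figure size in inches.
#' @return The written path.
#' @export
render_figure <- function(plot, out_path, pdf = FALSE, width = 7, height = 5) {
  ext <- if (pdf) "pdf" else "png"
  out_path <- paste0(sub("\\.(png|pdf)$", "", out_path, ignore.case = TRUE),
                     ".", ext)
  if (pdf) {
    ggplot2::ggsave(out_path, plot, width = width, height = height,
                    device = "pdf")
  } else {
    ggplot2::ggsave(out_path, plot, width = width, height = height,
                    dpi = 300, device = "png")
  }
  out_path
}

#' Render the standard query visualizations
#'
#' Writes the percent-identity heatmap (when >= 2 databases were
#' queried) and one sequence logo per motif pattern with matches.
#'
#' @param results A `blast_results` object.
#' @param matches Optional `motif_matches` table from [scan_hits()].
#' @param out_dir Output directory.
#' @param pdf Emit PDF instead of 300-dpi PNG.
#' @return Character vector of written figure paths.
#' @export
render_query_figures <- function(results, matches = NULL, out_dir = ".",
                                 pdf = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  mat <- build_identity_matrix(results$filtered,
                               queries = sort(unique(results$all$query_file)),
                               dbs = sort(unique(results$all$database)))
  if (!is.null(mat)) {
    paths <- c(paths, render_figure(plot_identity_heatmap(mat),
                                    file.path(out_dir, "identity_heatmap"),
                                    pdf = pdf))
  }
  if (!is.null(matches) && nrow(matches)) {
    for (pat in unique(matches$pattern)) {
      prof <- build_motif_profile(matches, pattern = pat)
      if (is.null(prof)) next
      paths <- c(paths, render_figure(
        plot_motif_logo(prof),
        file.path(out_dir, paste0("logo_", safe_pattern_name(pat))),
        pdf = pdf, width = max(3, 0.6 * ncol(prof$frequencies)), height = 3))
    }
  }
  paths
}
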