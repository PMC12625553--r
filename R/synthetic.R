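# Synthetic genome/query generator used by the test-suite and worked
# examples. Plants known gene sequences (optionally reverse-complemented)
# at recorded coordinates inside random-background genomes, so database
# construction, querying, filtering, extraction and visualization can be
# verified against ground truth.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# One fixed codon per residue, so a reverse-translated gene is recovered
# exactly by a translated search.
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

reverse_translate <- function(protein) {
  paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = "")
}

#' Simulate genomes with planted query genes
#'
#' Generates `n_genomes` multi-contig nucleotide genomes of uniform random
#' background and plants every gene into every genome at a recorded
#' position; genes listed in `revcomp_genes` are planted as their reverse
#' complement (minus strand). Query files are written one gene per file:
#' nucleotide queries verbatim, or protein queries (reverse-translated
#' with a fixed codon table before planting) when
#' `query_molecule = "protein"`.
#'
#' @param out_dir Directory receiving `genomes/` and `queries/`.
#' @param n_genomes,n_contigs,contig_length Genome shape (contig length in
#'   bp).
#' @param n_genes Number of planted genes (one query file each).
#' @param gene_length Planted gene length in bp (for protein queries the
#'   protein has `gene_length/3` residues).
#' @param revcomp_genes Indices of genes planted on the minus strand.
#' @param query_molecule `"nucleotide"` (blastn searches) or `"protein"`
#'   (tblastn searches).
#' @param seed Optional RNG seed for full reproducibility.
#' @return List with `genome_dir`, `query_dir`, `genomes`, `queries`
#'   (paths) and `manifest`: one row per planted copy with plus-strand
#'   coordinates (`start`, `end`, 1-based inclusive), `strand` and the
#'   planted sequence.
#' @export
simulate_genome_set <- function(out_dir, n_genomes = 4L, n_contigs = 3L,
                                contig_length = 2000L, n_genes = 3L,
                                gene_length = 300L, revcomp_genes = 2L,
                                query_molecule = c("nucleotide", "protein"),
                                seed = NULL) {
  query_molecule <- match.arg(query_molecule)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes <= n_contigs,
            contig_length > gene_length + 2L)
  genome_dir <- file.path(out_dir, "genomes")
  query_dir <- file.path(out_dir, "queries")
  dir.create(genome_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(query_dir, recursive = TRUE, showWarnings = FALSE)

  genes <- character(n_genes)
  queries <- character(n_genes)
  for (g in seq_len(n_genes)) {
    if (query_molecule == "protein") {
      prot <- random_protein(max(30L, gene_length %/% 3L))
      genes[g] <- reverse_translate(prot)
      queries[g] <- file.path(query_dir, sprintf("gene%d.faa", g))
      write_fasta(data.frame(id = sprintf("gene%d", g), description = "",
                             residues = prot), queries[g])
    } else {
      genes[g] <- random_dna(gene_length)
      queries[g] <- file.path(query_dir, sprintf("gene%d.fna", g))
      write_fasta(data.frame(id = sprintf("gene%d", g), description = "",
                             residues = genes[g]), queries[g])
    }
  }

  manifest <- list()
  genome_paths <- character(n_genomes)
  for (i in seq_len(n_genomes)) {
    contigs <- vapply(seq_len(n_contigs), function(j) random_dna(contig_length),
                      character(1))
    for (g in seq_len(n_genes)) {
      ctg <- g  # one gene per contig keeps planted copies non-overlapping
      glen <- nchar(genes[g])
      start <- sample.int(contig_length - glen - 1L, 1L) + 1L
      minus <- g %in% revcomp_genes
      insert <- if (minus) rev_comp(genes[g]) else genes[g]
      substr(contigs[ctg], start, start + glen - 1L) <- insert
      manifest[[length(manifest) + 1L]] <- data.frame(
        genome = sprintf("genome%d", i), contig = sprintf("contig%d", ctg),
        gene = sprintf("gene%d", g), start = start, end = start + glen - 1L,
        strand = if (minus) "-" else "+", planted = genes[g],
        stringsAsFactors = FALSE)
    }
    genome_paths[i] <- file.path(genome_dir, sprintf("genome%d.fna", i))
    write_fasta(data.frame(id = sprintf("contig%d", seq_len(n_contigs)),
                           description = "", residues = contigs),
                genome_paths[i])
  }
  list(genome_dir = genome_dir, query_dir = query_dir,
       genomes = genome_paths, queries = queries,
       manifest = do.call(rbind, manifest))
}
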