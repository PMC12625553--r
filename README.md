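# blastmine

Population-scale BLAST+ orchestration, wildcard motif mining and
sequence curation for R.

Comparative screens — pangenome surveys, biosynthetic gene cluster
(BGC) discovery, resistance-gene mining — need the same loop over and
over: build a BLAST database per assembly, run every query against
every database with the right program, and merge hundreds of raw
outputs into tables someone can actually filter. blastmine automates
that loop for collections of any size. The alignment itself is always
delegated to the NCBI BLAST+ binaries (`makeblastdb`, `blastn`,
`blastp`, `tblastn`); the package owns everything around them:

* **Input handling** — FASTA files (plain/gzip), directories, or
  `.zip`/`.tar`/`.tar.gz`/`.tgz` archives; BLAST-safe filename
  sanitization; multi-FASTA splitting; collision-free header barcodes
  (random or deterministic MD5-derived).
* **Search orchestration** — automatic `nucl`/`prot` database typing
  from extensions, per-pairing program dispatch (nucleotide database +
  amino-acid query = tblastn; protein database + amino-acid query =
  blastp; `--nucleotide-query` = blastn), parallel execution with one
  query file per task, and three curated tables: `all_results.csv`
  (every hit), `all_filtered_results.csv` (hits passing thresholds) and
  `filtered_results.csv` (strongest match per query x database).
  Default thresholds: **90% identity, 75% query coverage, E <= 1e-5**,
  inclusive, with qcov = 100 (qend - qstart + 1) / qlen.
* **Motif mining** — amino-acid patterns with `X` wildcards
  (`WXWXIP`), optionally bound to one query file (`RVXXXQ{AT}`),
  scanned across *all* hits regardless of thresholds, with overlapping
  occurrences reported and per-pattern FASTA export.
* **Extraction** — aligned regions with oriented up/downstream padding
  (minus-strand hits reverse-complemented so genes read forward), or
  whole contigs for genome-browser inspection.
* **Utilities** — assembly metrics (N50/N90, L50/L90, GC%, N count,
  length distribution), GenBank/JSON metadata harvesting with
  `not_specified` fill.
* **Visualization** — percent-identity heatmaps (max pident per
  pairing, 300-dpi PNG or PDF) and per-motif sequence logos
  (information content R = log2(20) - H bits per column).

## Worked example

Plant three known 300-bp genes (one reverse-complemented) into four
synthetic 3-contig genomes, then run the full loop:

```r
library(blastmine)

sim <- simulate_genome_set("demo", seed = 20)       # genomes/ + queries/
dbs <- make_databases(resolve_inputs(sim$genome_dir), out_dir = "demo/dbs")
res <- run_queries(sim$queries, dbs, out_dir = "demo/results",
                   nucleotide_query = TRUE, report_strongest = TRUE)
res
#> blast_results: 12 hit(s), 12 filtered, 12 strongest

head(res$strongest[, c("qseqid","database","pident","qcov","evalue","bitscore")], 4)
#>  qseqid database pident qcov    evalue bitscore
#>   gene1  genome1    100  100 1.34e-161      555
#>   gene1  genome2    100  100 1.34e-161      555
#>   gene1  genome3    100  100 1.34e-161      555
#>   gene1  genome4    100  100 1.34e-161      555
```

Every planted copy is recovered as a filtered self-hit at 100%
identity and coverage — 12 hits for 3 queries x 4 genomes — and the
heatmap matrix holds the per-pairing maxima:

```r
build_identity_matrix(res$filtered)
#>       genome1 genome2 genome3 genome4
#> gene1     100     100     100     100
#> gene2     100     100     100     100
#> gene3     100     100     100     100
```

Motif scanning reports every occurrence with its position in the
de-gapped subject; here the ketoreductase stereochemistry motif inside
its module context:

```r
scan_sequence("HAAATLDDGSSFASAFGAPGLGGYAP", "SSXXXXXXXXXXXXYXX")
#>  start           matched
#>     10 SSFASAFGAPGLGGYAP
```

Assembly statistics per input file:

```r
fasta_metrics(sim$genome_dir)[1, c("file","genome_size","contig_count",
                                   "gc_percent","n50","l50")]
#>         file genome_size contig_count gc_percent  n50 l50
#>  genome1.fna        6000            3      49.65 2000   2
```

Extraction recovers the planted genes plus true flanks
(`extract_regions("demo/results/all_filtered_results.csv",
sim$genome_dir, pad_up = 50, pad_down = 30)`).

## Command line

A thin Rscript entry point exposes the same functions as subcommands:

```sh
exec/blastmine makedb --input genomes/ --output-dir dbs
exec/blastmine query --databases dbs --queries queries/ \
    --report-strongest-matches --motif "RVXXXQ{AT} GHXXGE" --visualize
exec/blastmine extract --results results/filtered_results.csv \
    --fasta-directory genomes/ --up 50 --down 30
exec/blastmine fasta-metrics --input genomes/ --output metrics.csv
exec/blastmine module-health
```

Exit codes: 0 success, 1 usage error, 2 environment error (missing
binaries), 3 partial failure.

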