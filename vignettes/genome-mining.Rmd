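---
title: "Population-scale BLAST mining with blastmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-scale BLAST mining with blastmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastmine)
```

## The problem

Exploratory comparative genomics — pangenome screens, biosynthetic gene
cluster (BGC) discovery, resistance-gene surveys — routinely asks one
question at scale: *where, across hundreds or thousands of assemblies,
does this sequence (or this short functional motif) occur?* NCBI BLAST+
answers the per-pair question well, but population-scale use means
scripting database construction per assembly, dispatching the right
program per query/database combination, and stitching hundreds of output
files back into something a human can filter and sort. blastmine
automates exactly that layer: it never re-implements the alignment
itself (every search is a subprocess call to `makeblastdb`, `blastn`,
`blastp` or `tblastn`), but owns everything around it — input handling,
program dispatch, parallel execution, results curation, motif mining,
region extraction and visualization.

## The pipeline model

A run is a cross product: every query FASTA file against every database.
Program choice per pairing is mechanical:

| database | query       | program  |
|----------|-------------|----------|
| `nucl`   | amino acid  | tblastn  |
| `prot`   | amino acid  | blastp   |
| `nucl`   | nucleotide (`nucleotide_query = TRUE`) | blastn |

A protein database cannot take a nucleotide query; that pairing is an
error rather than a silent fallback.

Three tables are curated from the raw tabular output:

* `all_results.csv` — every hit, no inclusion criteria applied;
* `all_filtered_results.csv` — hits passing the thresholds;
* `filtered_results.csv` — the single strongest match per
  query-file × database pairing (on request).

All three carry the same 17 columns: the 12 standard tabular fields,
`qlen`, `sframe`, the computed query coverage `qcov`, and the
provenance columns `query_file` and `database`.

### Thresholds

The default inclusion thresholds are **90% identity, 75% query coverage
and E ≤ 1e-5**, all inclusive at the boundary (a hit at exactly
90/75/1e-5 is retained). Identity and E-value come from BLAST; coverage
is computed as

$$\mathrm{qcov} = 100 \times \frac{q_{end} - q_{start} + 1}{q_{len}}$$

i.e. the *query-span* convention, rounded to two decimals. Coverage
could alternatively be defined over the alignment length including
gaps; we use the query span because it is what a 75% default
meaningfully constrains (how much of the gene you searched for was
found), and we state the formula rather than leave it implicit. These
defaults are deliberately strict — they suit finding orthologs of a
known gene across a population. For divergent homolog screens, relax
them per run (`threshold_set(80, 70, 1e-5)` was the kind of setting
used for the copper-dependent halogenase case that motivates the motif
tooling).

### Strongest match

Within a pairing's filtered hits, the strongest match is selected by
maximal bitscore, with ties broken by minimal evalue, then maximal
pident, then lexicographic subject id. The chain is total, so the
selection — and therefore `filtered_results.csv` — is deterministic.

### Parallelism and determinism

One query *file* is one task; tasks run in parallel (`threads`),
databases within a task sequentially. Because hits are concatenated and
then canonically sorted — by (query_file, database, ascending evalue,
descending bitscore, sseqid, sstart) — the emitted tables are
byte-identical for any thread count. The test suite asserts this on a
5-genome × 3-query fixture.

Numeric columns are parsed into R doubles/integers and re-serialized
with standard CSV formatting (`qcov` fixed at two decimals); we do not
preserve the BLAST text byte-for-byte, since every downstream consumer
of these tables is value-oriented.

## Input handling

`resolve_inputs()` accepts a single FASTA file (plain or gzipped), a
directory (searched recursively) or a `.zip`/`.tar`/`.tar.gz`/`.tgz`
archive. Archive members and gzipped files are staged into a temporary
workspace that is removed by `cleanup_collection()` unless
`keep_temp = TRUE`. Non-FASTA files inside directories and archives are
skipped with a notice rather than an error — batch inputs in the wild
almost always contain READMEs and checksum files, and failing the whole
run on them would be hostile; an archive containing *no* FASTA at all
is still an error. Molecule type is read from the extension: `.faa` is
amino acid; `.fasta`, `.fna`, `.fas`, `.fa`, `.ffn` are nucleotide.

File names feeding `makeblastdb` must stay within `[A-Za-z0-9_-]` plus
one extension period. `sanitize_filename()` maps every other character
to `_`, collapses runs, and is idempotent; batch collisions after
sanitization get `_1`, `_2`, … suffixes before the extension — the
collision rule is ours, chosen so that batch sanitization is
deterministic. Files delivered inside archives are only ever sanitized
on their extracted workspace copies.

`assign_unique_headers()` guarantees collision-free record ids across a
collection by rewriting each id to
`<original>_<file stem>_<5-char tag>`. Deterministic tags take the MD5
digest of (residues + full original header) and map its first five
bytes through a base-62 alphabet — the digest input is fixed by the
design, the byte-to-alphabet encoding is our choice. Residual
collisions (byte-identical duplicate records) receive a numeric suffix,
so uniqueness is unconditional; the suite checks it on 10,000 colliding
headers.

## Motif mining

Motifs are written in one-letter amino-acid code with `X` as a
wildcard (`WXWXIP`), optionally bound to one query file's results with
a brace suffix (`RVXXXQ{AT}` scans only hits whose query file stem is
`AT`). Scanning always covers **all** hits regardless of threshold
status — weak hits are often exactly where a conserved catalytic motif
still identifies a divergent family member.

Semantics, each a deliberate choice:

* subject strings are de-gapped before scanning, so an alignment gap
  cannot break a genuine motif; reported coordinates are 1-based within
  the de-gapped subject alignment (not the full subject sequence);
* **all** occurrences are reported, overlapping included — iterative
  motifs such as the paired `HXXHC` copper-binding sites are the use
  case, and leftmost-only semantics would hide the second site when
  sites abut;
* matching is case-insensitive; `X` matches any letter A–Z (ambiguity
  codes included); fixed positions require equality and must be
  standard residues. A *literal* fixed X is consequently not
  expressible — a documented limitation;
* only amino-acid subjects are scannable: blastp and tblastn hits are
  accepted, blastn hits raise an error rather than silently matching
  nucleotides.

The scanner is verified against a brute-force every-window oracle on
1,000 random sequence/pattern cases, and against the published
acyltransferase/ketosynthase/ketoreductase motif matches of the
erythromycin PKS modules (`RVXXXQ` → RVDVVQ/RVEVVQ, `TAXSSX` → TACSSS,
`SSXXXXXXXXXXXXYXX` → SSFASAFGAPGLGGYAP, …).

Gapped or strongly degenerate motifs are out of scope; profile/HMM
methods are the right tool there.

## Extraction

`extract_regions()` slices the aligned region of each hit out of the
source FASTA, using BLAST's 1-based inclusive coordinates, with
minus-strand subject hits encoded by `sstart > send`. Padding is
*oriented*: `pad_up` always extends the 5′ side of the hit **in hit
orientation**, and minus-strand output is reverse-complemented so an
extracted gene reads forward. The upstream/downstream frame for
minus-strand hits is not fixed by the table format itself, so we
declare this convention rather than inherit one. Out-of-bounds
padding is clamped silently to the contig, but the header records both
requested and applied intervals so clamping is visible.
`extract_contigs()` instead writes each referenced contig once per
database — the whole-contig view for genome-browser inspection of
metagenome assemblies too large to open whole.

Protein-database (blastp) hits extract in residue units; there is no
strand on a protein subject, so no reverse complement arises.

## Assembly metrics

`fasta_metrics()` reports genome size, contig count, GC%, N count,
N50/N90, L50/L90, extremes, a six-number length distribution
(min/Q1/median/mean/Q3/max — "length distribution" is not standardized,
six numbers is our choice) and the descending `|`-joined length list.
N/L statistics use the standard cumulative rule: with lengths sorted
descending, N*f* is the length at which the running sum first reaches
*f* × total, L*f* the number of contigs consumed. GC% uses *all*
residues (N and ambiguity codes included) as denominator, with N count
reported separately — the alternative (ACGT-only denominator) inflates
GC in N-rich drafts and would double-count the information already in
`n_count`.

## Metadata

`harvest_metadata()` mines GenBank flat files (ACCESSION/VERSION,
SOURCE/ORGANISM and the source-feature qualifiers) and NCBI-style JSON
assembly reports into one record per file, with `collection_region`
mapped from `/geo_loc_name` and falling back to the retired `/country`
qualifier. Files are typed by content (LOCUS line vs JSON), not
extension. Every missing value is the literal `not_specified` — never
an empty cell — so downstream grouping code needs no NA handling. The
JSON key map targets the `datasets` assembly data-report shape
(`accession`, `organism.organismName`,
`assemblyInfo.biosample.attributes[{name,value}]`), with flat
key/value fallbacks.

## Visualization

For runs against more than one database, the identity heatmap shows
max pident per query × database among *filtered* hits (multiple HSPs
aggregate by maximum — the cell answers "how good is the best
evidence", and filtered hits keep the figure consistent with the
tables a user acts on); pairings with no hit render in a reserved
grey distinct from the 0–100 colormap. With a single database the
heatmap is skipped.

Per-motif sequence logos are built from the matched strings: column
frequencies (summing to 1) scaled by information content
$R = \log_2 20 - H$ bits, where $H$ is the column's Shannon entropy
over a 20-letter alphabet with raw frequencies and no small-sample
correction — an all-identical column attains exactly
$\log_2 20 \approx 4.32$ bits, and wildcard-heavy columns show low
information. Logos are drawn directly with ggplot2 as
information-scaled stacked letter columns. Figures default to 300-dpi
PNG; `pdf = TRUE` switches to PDF.

## Synthetic fixtures and what they show

`simulate_genome_set()` builds multi-contig genomes of uniform random
background and plants every query gene at recorded coordinates, one
gene per contig, optionally reverse-complemented; protein queries are
reverse-translated with a fixed one-codon-per-residue table before
planting so a translated search recovers them exactly. Defaults (4
genomes × 3 contigs of 2 kb, 3 genes of 300 bp, one minus-strand)
are sized so the full makedb → query → extract → visualize loop runs
in seconds while still exercising both strands, multi-contig lookup and
every table. The tests and the acceptance script use these sizes.

The generator emulates none of real data's texture: no repeats, no
homology short of identity, no indels, no base-composition structure,
no fragmented or contaminated assemblies. Passing tests therefore
demonstrate *plumbing correctness* — coordinates, orientation, program
dispatch, threshold boundaries, determinism — not retrieval sensitivity
on diverged sequences, which is governed by BLAST itself and by the
thresholds a user chooses.

## Numerical and degenerate-input choices

* Threshold comparisons are inclusive; qcov is rounded to 2 decimals
  *before* comparison, so a 74.995 span passes as 75.00.
* Empty hit sets propagate as header-only CSVs, never as errors.
* A FASTA record with an empty sequence is rejected; blank lines and
  wrapped or single-line records are accepted.
* N-statistic ties (equal lengths) are resolved by the descending sort's
  stable order; the result is order-independent anyway.
* `n_statistic` requires a fraction strictly inside (0, 1); sums are
  accumulated in doubles to avoid integer overflow on large genomes.
* One failing pairing warns with the pairing named, never aborts the
  others; the CLI then exits 3 with partial results written.

## Known limitations

* Alignment sensitivity and E-value behavior are BLAST's; nothing here
  re-scores alignments.
* Motif search is exact-match with wildcards; no gaps, no PSSMs.
* Metadata parsing targets the common GenBank/JSON shapes described
  above; exotic dialects may need the `--all` union view.
* `sframe` is passed through exactly as the binaries print it
  (current BLAST+ prints 1 for blastp hits rather than omitting the
  field).
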