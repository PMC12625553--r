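# BLAST orchestration: program dispatch, coverage, filtering, strongest
# matches, database construction and the full query pipeline.

test_that("program selection covers the dispatch table", {
  expect_equal(select_program("nucl", nucleotide_query = FALSE), "tblastn")
  expect_equal(select_program("prot", nucleotide_query = FALSE), "blastp")
  expect_equal(select_program("nucl", nucleotide_query = TRUE), "blastn")
  expect_error(select_program("prot", nucleotide_query = TRUE),
               "no supported program")
})

test_that("query coverage is the query-span percentage, 2 decimals", {
  expect_equal(compute_query_coverage(1L, 100L, 100L), 100)
  expect_equal(compute_query_coverage(11L, 85L, 100L), 75)
  expect_equal(compute_query_coverage(26L, 100L, 100L), 75)
  expect_equal(compute_query_coverage(1L, 2L, 3L), 66.67)
  expect_error(compute_query_coverage(0L, 10L, 10L), "qstart")
  expect_error(compute_query_coverage(5L, 4L, 10L), "qstart")
})

test_that("default thresholds are inclusive at every boundary", {
  t <- threshold_set()
  expect_equal(t$min_identity, 90)
  expect_equal(t$min_coverage, 75)
  expect_equal(t$max_evalue, 1e-5)
  at_boundary <- make_hit(pident = 90.0, qstart = 26L, qend = 100L,
                          evalue = 1e-5)
  expect_equal(at_boundary$qcov, 75)
  expect_equal(nrow(filter_hits(at_boundary, t)), 1L)
  expect_equal(nrow(filter_hits(make_hit(pident = 89.99, evalue = 1e-30), t)), 0L)
  expect_equal(nrow(filter_hits(make_hit(qstart = 27L, qend = 100L), t)), 0L)
  expect_equal(nrow(filter_hits(make_hit(evalue = 1.01e-5), t)), 0L)
  expect_equal(nrow(filter_hits(empty_hits <- make_hit()[0, ], t)), 0L)
})

test_that("filtering is idempotent and monotone under threshold tightening", {
  set.seed(21)
  hits <- do.call(rbind, lapply(1:200, function(i) {
    qe <- sample(30:100, 1)
    make_hit(pident = runif(1, 60, 100), evalue = 10^runif(1, -80, 1),
             qstart = 1L, qend = as.integer(qe), qlen = 100L,
             bitscore = runif(1, 30, 500),
             query_file = sample(c("qa", "qb"), 1),
             database = sample(c("d1", "d2", "d3"), 1))
  }))
  t0 <- threshold_set(80, 50, 1e-3)
  f1 <- filter_hits(hits, t0)
  expect_identical(filter_hits(f1, t0), f1)
  expect_true(all(f1$pident >= 80 & f1$qcov >= 50 & f1$evalue <= 1e-3))
  for (t_tight in list(threshold_set(90, 50, 1e-3),
                       threshold_set(80, 75, 1e-3),
                       threshold_set(80, 50, 1e-6))) {
    f2 <- filter_hits(hits, t_tight)
    expect_lte(nrow(f2), nrow(f1))
    expect_true(all(interaction(f2$evalue, f2$bitscore, f2$sstart) %in%
                      interaction(f1$evalue, f1$bitscore, f1$sstart)))
  }
})

test_that("strongest match keeps one best hit per pairing with the tie-break chain", {
  pair <- rbind(make_hit(bitscore = 500, sseqid = "a"),
                make_hit(bitscore = 400, sseqid = "b"))
  expect_equal(strongest_matches(pair)$sseqid, "a")

  ties <- rbind(make_hit(bitscore = 400, evalue = 1e-50, sseqid = "a"),
                make_hit(bitscore = 400, evalue = 1e-40, sseqid = "b"))
  expect_equal(strongest_matches(ties)$evalue, 1e-50)

  ties2 <- rbind(make_hit(bitscore = 400, evalue = 1e-40, pident = 95, sseqid = "b"),
                 make_hit(bitscore = 400, evalue = 1e-40, pident = 99, sseqid = "a"))
  expect_equal(strongest_matches(ties2)$pident, 99)

  two_dbs <- rbind(make_hit(database = "d1"), make_hit(database = "d2"))
  expect_equal(nrow(strongest_matches(two_dbs)), 2L)

  # cardinality property over a random table
  set.seed(33)
  big <- do.call(rbind, lapply(1:300, function(i) {
    make_hit(bitscore = sample(100:500, 1), evalue = 10^-sample(5:60, 1),
             pident = runif(1, 90, 100),
             query_file = sample(paste0("q", 1:4), 1),
             database = sample(paste0("d", 1:5), 1),
             sseqid = sample(letters, 1))
  }))
  s <- strongest_matches(big)
  expect_lte(max(table(paste(s$query_file, s$database))), 1L)
  expect_setequal(unique(paste(s$query_file, s$database)),
                  unique(paste(big$query_file, big$database)))
})

test_that("make_databases rejects non-compliant names unless asked to sanitize", {
  dir <- withr::local_tempdir()
  write_tmp_fasta(dir, "my genome.fna", "c1",
                  paste(rep("ACGT", 100), collapse = ""))
  coll <- resolve_inputs(dir, quiet = TRUE)
  expect_error(make_databases(coll, out_dir = withr::local_tempdir()),
               "incompatible")
  dbs <- make_databases(coll, out_dir = withr::local_tempdir(),
                        sanitize = TRUE, quiet = TRUE)
  expect_equal(dbs$name, "my_genome")
  expect_equal(dbs$db_type, "nucl")
})

test_that("database type is set per file and stems must be unique", {
  dir <- withr::local_tempdir()
  set.seed(2)
  for (i in 1:3) {
    write_tmp_fasta(dir, sprintf("n%d.fna", i), "c1",
                    paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""))
  }
  write_tmp_fasta(dir, "p1.faa", "r1", random_aa_string(120))
  dbs <- make_databases(resolve_inputs(dir, quiet = TRUE),
                        out_dir = withr::local_tempdir(), quiet = TRUE)
  expect_equal(sum(dbs$db_type == "nucl"), 3L)
  expect_equal(dbs$db_type[dbs$name == "p1"], "prot")
  found <- discover_databases(dirname(dbs$prefix[1]))
  expect_setequal(found$name, dbs$name)
  expect_equal(found$db_type[found$name == "p1"], "prot")
})

test_that("the query pipeline yields canonical tables invariant to thread count", {
  root <- withr::local_tempdir()
  sim <- simulate_genome_set(root, n_genomes = 5, n_contigs = 3,
                             contig_length = 1500, n_genes = 3,
                             gene_length = 240, revcomp_genes = 2, seed = 91)
  dbs <- make_databases(resolve_inputs(sim$genome_dir, quiet = TRUE),
                        out_dir = file.path(root, "dbs"), quiet = TRUE)
  out1 <- file.path(root, "r1")
  out4 <- file.path(root, "r4")
  r1 <- run_queries(sim$queries, dbs, threads = 1, out_dir = out1,
                    nucleotide_query = TRUE, write_alignments = FALSE,
                    report_strongest = TRUE, quiet = TRUE)
  r4 <- run_queries(sim$queries, dbs, threads = 4, out_dir = out4,
                    nucleotide_query = TRUE, write_alignments = FALSE,
                    report_strongest = TRUE, quiet = TRUE)
  for (f in c("all_results.csv", "all_filtered_results.csv",
              "filtered_results.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out4, f)))
  }
  # table columns exactly as specified
  header <- strsplit(readLines(file.path(out1, "all_results.csv"), 1L), ",")[[1]]
  expect_identical(gsub('"', "", header),
                   c("qseqid", "sseqid", "pident", "evalue", "length",
                     "mismatch", "gapopen", "qstart", "qend", "sstart",
                     "send", "bitscore", "qlen", "sframe", "qcov",
                     "query_file", "database"))
  # planted self-hits: one filtered 100/100 hit per query x database pairing
  expect_equal(nrow(r1$filtered), 15L)
  expect_true(all(r1$filtered$pident == 100 & r1$filtered$qcov == 100))
  # containment invariants
  key <- function(h) paste(h$query_file, h$database, h$sseqid, h$sstart)
  expect_true(all(key(r1$filtered) %in% key(r1$all)))
  expect_true(all(key(r1$strongest) %in% key(r1$filtered)))
  expect_identical(r1$all[names(r4$all)], r4$all)
})

test_that("a query with no hits yields header-only tables", {
  root <- withr::local_tempdir()
  set.seed(55)
  gdir <- file.path(root, "g")
  dir.create(gdir)
  write_tmp_fasta(gdir, "genome.fna", "c1",
                  paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = ""))
  qdir <- file.path(root, "q")
  dir.create(qdir)
  q <- write_tmp_fasta(qdir, "orphan.fna", "q1",
                       paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  dbs <- make_databases(resolve_inputs(gdir, quiet = TRUE),
                        out_dir = file.path(root, "dbs"), quiet = TRUE)
  out <- file.path(root, "res")
  r <- run_queries(q, dbs, out_dir = out, nucleotide_query = TRUE,
                   write_alignments = FALSE, quiet = TRUE)
  expect_equal(nrow(r$all), 0L)
  expect_length(readLines(file.path(out, "all_results.csv")), 1L)
  expect_length(readLines(file.path(out, "all_filtered_results.csv")), 1L)
})

test_that("alignment files are written per pairing unless suppressed", {
  root <- withr::local_tempdir()
  sim <- simulate_genome_set(root, n_genomes = 2, n_contigs = 2,
                             contig_length = 900, n_genes = 1,
                             gene_length = 200, revcomp_genes = integer(0),
                             seed = 12)
  dbs <- make_databases(resolve_inputs(sim$genome_dir, quiet = TRUE),
                        out_dir = file.path(root, "dbs"), quiet = TRUE)
  out <- file.path(root, "res")
  run_queries(sim$queries, dbs, out_dir = out, nucleotide_query = TRUE,
              quiet = TRUE)
  aln <- list.files(file.path(out, "alignments"))
  expect_setequal(aln, c("gene1_vs_genome1.txt", "gene1_vs_genome2.txt"))
})
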