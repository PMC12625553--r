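# FASTA input resolution, sanitization, splitting, unique headers.

test_that("molecule type follows the canonical extension", {
  expect_equal(detect_molecule_type("q.faa"), "protein")
  for (ext in c("fasta", "fna", "fas", "fa", "ffn")) {
    expect_equal(detect_molecule_type(paste0("g.", ext)), "nucleotide")
  }
  expect_equal(detect_molecule_type("g.fna.gz"), "nucleotide")
  expect_error(detect_molecule_type("g.txt"), "canonical extensions")
})

test_that("filename sanitization applies the allowed charset and is idempotent", {
  expect_equal(sanitize_filename("E. coli (K-12).fna"), "E_coli_K-12.fna")
  expect_equal(sanitize_filename("genome1.fna"), "genome1.fna")
  expect_equal(sanitize_filename("a  b..c (d).fasta"), "a_b_c_d.fasta")
  expect_error(sanitize_filename("no_extension"), "extension")
  expect_error(sanitize_filename("(((.fna"), "empty stem")
  set.seed(11)
  specials <- strsplit(" ().,;:!@#$%^&*+=[]'", "")[[1]]
  for (i in 1:100) {
    stem <- paste(sample(c(LETTERS, letters, 0:9, specials), 12, replace = TRUE),
                  collapse = "")
    name <- tryCatch(sanitize_filename(paste0(stem, ".fna")),
                     error = function(e) NULL)
    if (is.null(name)) next # all-special stems legitimately error
    expect_equal(sanitize_filename(name), name)
    expect_match(name, "^[A-Za-z0-9_-]+\\.fna$")
  }
})

test_that("sanitize_files resolves collisions with numeric suffixes", {
  dir <- withr::local_tempdir()
  write_tmp_fasta(dir, "strain A.fna", "c1", "ACGT")
  write_tmp_fasta(dir, "strain.A.fna", "c1", "ACGT")
  report <- sanitize_files(dir)
  expect_setequal(basename(report$new), c("strain_A.fna", "strain_A_1.fna"))
  expect_false(anyDuplicated(report$new) > 0)
  expect_true(all(file.exists(report$new)))
})

test_that("sanitize_files can copy instead of rename", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  p <- write_tmp_fasta(dir, "my genome.fna", "c1", "ACGT")
  report <- sanitize_files(dir, outdir = out)
  expect_true(file.exists(p)) # original untouched
  expect_equal(basename(report$new), "my_genome.fna")
  expect_equal(attr(report, "mode"), "copy_to_directory")
})

test_that("directories resolve to their FASTA members, ignoring the rest", {
  dir <- withr::local_tempdir()
  for (i in 1:3) write_tmp_fasta(dir, sprintf("g%d.fna", i), "c1", "ACGTACGT")
  writeLines("not fasta", file.path(dir, "notes.txt"))
  coll <- resolve_inputs(dir, quiet = TRUE)
  expect_equal(nrow(coll$entries), 3L)
  expect_true(all(coll$entries$molecule == "nucleotide"))
})

test_that("archives resolve to the same record multiset as the unpacked directory", {
  dir <- withr::local_tempdir()
  write_tmp_fasta(dir, "a.fasta", c("r1", "r2"), c("ACGT", "GGCC"))
  write_tmp_fasta(dir, "b.fasta", "r3", "TTAA")
  tarball <- file.path(withr::local_tempdir(), "input.tar.gz")
  withr::with_dir(dir, utils::tar(tarball, files = ".", compression = "gzip"))

  coll_dir <- resolve_inputs(dir, quiet = TRUE)
  coll_tar <- resolve_inputs(tarball, quiet = TRUE)
  expect_equal(nrow(coll_tar$entries), 2L)
  recs <- function(coll) {
    r <- do.call(rbind, lapply(coll$entries$path, read_fasta))
    r[order(r$id), c("id", "residues")]
  }
  expect_equal(recs(coll_tar), recs(coll_dir), ignore_attr = TRUE)
  # archive members are staged in a removable workspace
  expect_false(is.na(coll_tar$workspace))
  ws <- coll_tar$workspace
  cleanup_collection(coll_tar)
  expect_false(dir.exists(ws))
})

test_that("keep_temp preserves the workspace", {
  dir <- withr::local_tempdir()
  write_tmp_fasta(dir, "a.fasta", "r1", "ACGT")
  tarball <- file.path(withr::local_tempdir(), "in.tar")
  withr::with_dir(dir, utils::tar(tarball, files = "a.fasta"))
  coll <- resolve_inputs(tarball, keep_temp = TRUE, quiet = TRUE)
  ws <- coll$workspace
  cleanup_collection(coll)
  expect_true(dir.exists(ws))
  unlink(ws, recursive = TRUE)
})

test_that("gzipped FASTA decompresses to content identical to the plain file", {
  dir <- withr::local_tempdir()
  plain <- write_tmp_fasta(dir, "genome.fna", c("c1", "c2"),
                           c("ACGTACGTNN", "GGCCTTAA"))
  gz <- file.path(dir, "genome2.fna.gz")
  con <- gzfile(gz, "wb")
  writeBin(readBin(plain, "raw", file.size(plain)), con)
  close(con)
  coll <- resolve_inputs(gz, quiet = TRUE)
  expect_equal(read_fasta(coll$entries$path[1])[, c("id", "residues")],
               read_fasta(plain)[, c("id", "residues")])
  cleanup_collection(coll)
})

test_that("degenerate inputs are rejected", {
  expect_error(resolve_inputs(tempfile("nope_")), "does not exist")
  dir <- withr::local_tempdir()
  writeLines("junk", file.path(dir, "x.txt"))
  tarball <- file.path(withr::local_tempdir(), "empty.tgz")
  withr::with_dir(dir, utils::tar(tarball, files = ".", compression = "gzip"))
  expect_error(resolve_inputs(tarball, quiet = TRUE), "no FASTA")
  # record with an empty sequence is rejected
  p <- file.path(dir, "bad.fna")
  writeLines(c(">ok", "ACGT", ">empty", "", ">ok2", "GG"), p)
  expect_error(read_fasta(p), "empty sequence")
})

test_that("FASTA write/read round-trips every (id, description, residues) triple", {
  dir <- withr::local_tempdir()
  set.seed(3)
  recs <- data.frame(
    id = c("plain", "with_desc", "long_seq"),
    description = c("", "some description here", "x y"),
    residues = c("ACGT", random_aa_string(10),
                 paste(rep("ACGTN", 50), collapse = "")),
    stringsAsFactors = FALSE)
  p <- file.path(dir, "rt.fna")
  write_fasta(recs, p)
  back <- read_fasta(p)
  expect_equal(back[, c("id", "description", "residues")], recs,
               ignore_attr = TRUE)
})

test_that("split_fasta partitions records in order and round-trips", {
  dir <- withr::local_tempdir()
  seqs <- vapply(1:10, function(i) random_aa_string(20), character(1))
  p <- write_tmp_fasta(dir, "multi.faa", sprintf("r%02d", 1:10), seqs)

  singles <- split_fasta(p, 1, file.path(dir, "s1"))
  expect_length(singles, 10L)
  expect_true(all(vapply(singles, function(f) nrow(read_fasta(f)),
                         integer(1)) == 1L))

  parts <- split_fasta(p, 4, file.path(dir, "s4"))
  expect_length(parts, 3L)
  expect_equal(vapply(parts, function(f) nrow(read_fasta(f)), integer(1)),
               c(4L, 4L, 2L), ignore_attr = TRUE)
  joined <- do.call(rbind, lapply(parts, read_fasta))
  expect_equal(joined$id, sprintf("r%02d", 1:10))
  expect_equal(joined$residues, seqs)

  one <- split_fasta(write_tmp_fasta(dir, "one.faa", "r1", "MKV"), 5,
                     file.path(dir, "s5"))
  expect_length(one, 1L)
  expect_error(split_fasta(p, 0), "batch_size")
})

test_that("unique headers follow id_stem_tag format and deterministic mode is stable", {
  dir <- withr::local_tempdir()
  p <- write_tmp_fasta(dir, "genome1a.faa", c("hypothetical", "hypothetical"),
                       c("MKVA", "MKLL"))
  out1 <- withr::local_tempdir()
  coll <- assign_unique_headers(p, deterministic = TRUE, output_dir = out1)
  ids <- read_fasta(coll$entries$path[1])$id
  expect_match(ids, "^hypothetical_genome1a_[0-9A-Za-z]{5}$")
  expect_false(anyDuplicated(ids) > 0)
  # identical headers, different residues -> distinct tags
  expect_length(unique(sub(".*_", "", ids)), 2L)
  # reruns are byte-identical
  out2 <- withr::local_tempdir()
  assign_unique_headers(p, deterministic = TRUE, output_dir = out2)
  expect_identical(readLines(file.path(out1, "genome1a.faa")),
                   readLines(file.path(out2, "genome1a.faa")))
})

test_that("output ids stay globally unique across 10,000 colliding headers", {
  dir <- withr::local_tempdir()
  set.seed(42)
  n <- 10000L
  seqs <- vapply(seq_len(n), function(i) random_aa_string(12), character(1))
  p <- write_tmp_fasta(dir, "collide.faa", rep("hypothetical", n), seqs)
  out <- withr::local_tempdir()
  coll <- assign_unique_headers(p, deterministic = TRUE, output_dir = out)
  ids <- read_fasta(coll$entries$path[1])$id
  expect_length(unique(ids), n)
  # random mode with a seed is also collision-free and reproducible
  coll_r <- assign_unique_headers(p, seed = 7, output_dir = withr::local_tempdir())
  ids_r <- read_fasta(coll_r$entries$path[1])$id
  expect_length(unique(ids_r), n)
})
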