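test_that("FASTA reading preserves records, order and lengths", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 first protein", "MKV", ">p2", "ACDEFGHIKLMNPQRSTVWY",
               ">p3 short", paste(rep("A", 149), collapse = "")), path)
  prot <- read_fasta(path)
  expect_equal(prot$id, c("p1", "p2", "p3"))
  expect_equal(prot$length, c(3L, 20L, 149L))
  expect_equal(prot$length, nchar(prot$sequence))
  # length-149 records are read here; filtering happens downstream
  expect_true("p3" %in% prot$id)
})

test_that("FASTA reading rejects duplicate ids and empty sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">a", "MKW"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(c(">a", "MKV", ">empty", ""), path)
  expect_error(read_fasta(path), "empty")
})

test_that("synthetic proteome FASTA round-trips through write and read", {
  dir <- withr::local_tempdir()
  gp <- generate_proteome(proteome_plan(c(SR_B = 25L, TSR_noTM = 25L),
                                        rng_seed = 31), dir)
  prot <- read_fasta(gp$fasta)
  expect_equal(nrow(prot), 50L)
  out <- file.path(dir, "rt.fasta")
  write_fasta(prot, out)
  again <- read_fasta(out)
  expect_identical(again$id, prot$id)
  expect_identical(again$sequence, prot$sequence)
})

test_that("domtblout parsing maps fields and applies no filtering", {
  path <- withr::local_tempfile()
  hits_in <- rbind(make_hit("p1", "CD36", 40, 380, 1e-30, 210.5),
                   make_hit("p1", "Lectin_C", 400, 500, 2e-4, 12.0))
  write_domtbl(hits_in, path)
  hits <- parse_domain_hits(path)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$protein_id, c("p1", "p1"))
  expect_equal(hits$domain_name, c("CD36", "Lectin_C"))
  expect_equal(hits$i_evalue, c(1e-30, 2e-4))
  expect_equal(hits$start, c(40L, 400L))
  expect_equal(hits$end, c(380L, 500L))
  # a comment-only file parses to an empty table
  writeLines(c("# one", "# two"), path)
  expect_equal(nrow(parse_domain_hits(path)), 0L)
})

test_that("domtblout parsing reports line numbers for malformed rows", {
  path <- withr::local_tempfile()
  writeLines(c("# header", "too few fields"), path)
  expect_error(parse_domain_hits(path), "line 2")
  good <- capture.output(write_domtbl(make_hit("p", "D", 5, 60), path))
  lines <- readLines(path)
  lines[2] <- sub("5 60 5 60", "-5 60 -5 60", lines[2], fixed = TRUE)
  writeLines(lines, path)
  expect_error(parse_domain_hits(path), "coordinate")
})

test_that("generated domain tables parse back to exactly the planted hits", {
  dir <- withr::local_tempdir()
  gp <- generate_proteome(proteome_plan(
    c(SR_B = 5L, ADAMTS_like = 5L), noise_domain_rate = 0, rng_seed = 7), dir)
  hits <- parse_domain_hits(gp$domtbl)
  # SR_B plants one CD36 per protein; ADAMTS-like plants 4 domains
  expect_equal(nrow(hits), 5L * 1L + 5L * 4L)
  expect_true(all(hits$i_evalue <= 1e-5))
  expect_setequal(unique(hits$protein_id), gp$truth$protein_id)
})

test_that("TM parsing handles the long dialect and sorts within protein", {
  path <- withr::local_tempfile()
  writeLines(c("p1\tTMHMM2.0\tinside\t1\t6",
               "p1\tTMHMM2.0\tTMhelix\t390\t412",
               "p1\tTMHMM2.0\tTMhelix\t7\t29",
               "p2\tTMHMM2.0\toutside\t1\t200"), path)
  tm <- parse_tm_regions(path)
  expect_equal(nrow(tm), 2L)
  expect_equal(tm$start, c(7L, 390L))
  expect_equal(tm$end, c(29L, 412L))
  # a protein with no helix rows contributes no regions
  expect_false("p2" %in% tm$protein_id)
})

test_that("TM parsing handles the one-line summary dialect", {
  path <- withr::local_tempfile()
  writeLines(c(paste0("p1\tlen=500\tExpAA=44.3\tFirst60=0.0\tPredHel=2\t",
                      "Topology=o5-27i390-412o"),
               "p2\tlen=300\tExpAA=0.0\tFirst60=0.0\tPredHel=0\tTopology=o"),
             path)
  tm <- parse_tm_regions(path)
  expect_equal(tm$protein_id, c("p1", "p1"))
  expect_equal(tm$start, c(5L, 390L))
  expect_equal(tm$end, c(27L, 412L))
})

test_that("TM parsing rejects unknown dialects naming the offending line", {
  path <- withr::local_tempfile()
  writeLines(c("p1 something else entirely"), path)
  expect_error(parse_tm_regions(path), "something else entirely")
})

test_that("generated TM files parse to the planted helix coordinates", {
  dir <- withr::local_tempdir()
  gp <- generate_proteome(proteome_plan(c(SR_B = 10L), rng_seed = 13), dir)
  tm <- parse_tm_regions(gp$tmhmm)
  # two planted helices per SR-B protein
  expect_equal(nrow(tm), 20L)
  expect_equal(as.integer(table(tm$protein_id)), rep(2L, 10L))
})

test_that("annotation filtering applies the E-value and Metazoa rules", {
  cfg <- pipeline_config()
  rec <- data.frame(
    protein_id = c("a", "b", "c", "d"),
    subject_id = c("s1", "s2", "s3", "s4"),
    description = "x",
    evalue = c(1e-12, 1e-8, 1e-30, 1e-40),
    taxon_group = c("metazoa", "metazoa", "non_metazoa", "unknown"),
    stringsAsFactors = FALSE)
  kept <- suppressMessages(filter_annotations(rec, cfg))
  # 1e-12 metazoan kept; 1e-8 fails the 1e-10 threshold; non-metazoan and
  # unmapped records are dropped
  expect_equal(kept$protein_id, "a")
  expect_message(filter_annotations(rec, cfg), "without taxonomy")
  # idempotence
  expect_identical(suppressMessages(filter_annotations(kept, cfg)), kept)
})

test_that("annotation filtering keeps exactly the planted survivors", {
  set.seed(41)
  n <- 100L
  pass <- sample(n, 40L)
  rec <- data.frame(
    protein_id = sprintf("q%03d", seq_len(n)),
    subject_id = sprintf("s%03d", seq_len(n)),
    description = "x",
    evalue = 10^runif(n, -9, -6),
    taxon_group = "non_metazoa",
    stringsAsFactors = FALSE)
  rec$evalue[pass] <- 10^runif(40, -40, -11)
  rec$taxon_group[pass] <- "metazoa"
  kept <- filter_annotations(rec, pipeline_config())
  expect_equal(nrow(kept), 40L)
  expect_setequal(kept$protein_id, rec$protein_id[pass])
})

test_that("best-hit selection keeps the lowest E-value per protein", {
  rec <- data.frame(
    protein_id = c("a", "a", "a"),
    subject_id = c("s1", "s2", "s3"),
    description = c("weak", "best", "mid"),
    evalue = c(1e-12, 1e-40, 1e-20),
    taxon_group = "metazoa", stringsAsFactors = FALSE)
  best <- filter_annotations(rec, pipeline_config())
  expect_equal(best$description, "best")
  all_kept <- filter_annotations(rec, pipeline_config(),
                                 best_hit_only = FALSE)
  expect_equal(nrow(all_kept), 3L)
})

test_that("tabular homology files round-trip through the reader", {
  dir <- withr::local_tempdir()
  gp <- generate_proteome(proteome_plan(c(SR_B = 8L), rng_seed = 19), dir)
  ann <- read_blast_annotations(gp$blast, gp$taxmap)
  expect_equal(nrow(ann), 8L)
  expect_true(all(ann$taxon_group == "metazoa"))
  kept <- filter_annotations(ann, pipeline_config())
  expect_equal(nrow(kept), 8L)
})

test_that("annotations for proteins missing from the FASTA are a hard error", {
  prot <- data.frame(id = "p1", sequence = "MKV", length = 3L)
  hits <- make_hit("ghost", "CD36", 1, 3)
  expect_error(check_protein_coverage(prot, hits = hits), "ghost")
  expect_true(check_protein_coverage(prot, hits = make_hit("p1", "X", 1, 2)))
})
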