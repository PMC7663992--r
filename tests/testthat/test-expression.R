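make_cm <- function(counts) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  count_matrix(counts)
}

test_that("the low-count filter keeps genes with 100 reads in two samples", {
  m <- make_cm(rbind(a = c(99, 99, 200),    # only one sample at >= 100
                     b = c(100, 100, 0),    # boundary: exactly two at 100
                     c = c(500, 300, 250),
                     d = c(0, 0, 0)))
  kept <- filter_low_counts(m, pipeline_config())
  expect_setequal(rownames(kept$counts), c("b", "c"))
})

test_that("the low-count filter equals a direct per-gene scan", {
  set.seed(21)
  counts <- matrix(rnbinom(500 * 4, mu = 120, size = 5), ncol = 4)
  m <- make_cm(counts)
  kept <- filter_low_counts(m, pipeline_config())
  oracle <- vapply(seq_len(nrow(counts)),
                   function(g) sum(counts[g, ] >= 100) >= 2, logical(1))
  expect_equal(rownames(kept$counts), rownames(m$counts)[oracle])
})

test_that("TMM factors are exactly one for identical and scaled columns", {
  set.seed(5)
  base <- rnbinom(300, mu = 300, size = 5) + 1
  identical_cols <- make_cm(cbind(base, base))
  expect_equal(unname(tmm_factors(identical_cols)), c(1, 1))
  # a pure depth difference is absorbed by library size: M-values all zero
  doubled <- make_cm(cbind(base, 2 * base))
  expect_equal(unname(tmm_factors(doubled)), c(1, 1))
})

test_that("TMM factors match the established implementation within 2%", {
  skip_if_not_installed("edgeR")
  set.seed(61)
  n <- 2000L
  mu <- rlnorm(n, log(150), 1)
  counts <- cbind(
    s1 = rnbinom(n, mu = mu, size = 10),
    s2 = rnbinom(n, mu = mu, size = 10),
    s3 = rnbinom(n, mu = mu * 1.5, size = 10)
  )
  # 5% of genes strongly up-shifted in s3 to give TMM something to trim
  up <- sample(n, n * 0.05)
  counts[up, "s3"] <- counts[up, "s3"] * 8L
  rownames(counts) <- sprintf("g%04d", seq_len(n))
  m <- make_cm(counts)
  ref <- colnames(counts)[1]
  got <- tmm_factors(m, reference_sample = ref)
  want <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = 1)
  expect_true(all(abs(got / want - 1) < 0.02))
  # and the factors multiply to one on the geometric scale
  expect_equal(exp(mean(log(got))), 1, tolerance = 1e-12)
})

test_that("an all-zero sample is a hard error for TMM", {
  m <- make_cm(cbind(c(5, 10, 2), c(0, 0, 0)))
  expect_error(tmm_factors(m), "all-zero")
})

test_that("log2 fold changes follow the analytic ratio of group means", {
  counts <- cbind(fed = c(400, 100, 1000), starved_d4 = c(100, 100, 1000))
  rownames(counts) <- c("up4x", "flat", "flat2")
  m <- make_cm(counts)
  m$lib_sizes <- c(1e6, 1e6)  # equalize depth to isolate the ratio
  design <- comparison_design(c(fed = "fed", starved_d4 = "starved_d4"),
                              "fed_vs_starvation")
  l2fc <- log2_fold_change(m, design, prior_count = 0)
  expect_equal(unname(l2fc["up4x", ]), 2)
  expect_equal(unname(l2fc["flat", ]), 0)
})

test_that("log2 fold changes match a direct-formula oracle", {
  set.seed(303)
  counts <- matrix(rnbinom(200 * 5, mu = 500, size = 5), ncol = 5,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   c("fed", "s4", "s7", "s30", "extra")))
  m <- normalize_tmm(make_cm(counts[, 1:4]))
  design <- comparison_design(
    c(fed = "fed", s4 = "starved_d4", s7 = "starved_d7", s30 = "starved_d30"),
    "fed_vs_starvation")
  prior <- 0.5
  l2fc <- log2_fold_change(m, design, prior)
  eff <- m$lib_sizes * m$norm_factors
  cpm_direct <- t(t(m$counts) / eff) * 1e6
  for (cmp in c("starved_d4", "starved_d7", "starved_d30")) {
    b <- c(starved_d4 = "s4", starved_d7 = "s7", starved_d30 = "s30")[[cmp]]
    want <- log2((cpm_direct[, "fed"] + prior) / (cpm_direct[, b] + prior))
    expect_equal(unname(l2fc[, cmp]), unname(want), tolerance = 1e-10)
  }
})

test_that("empty or overlapping design groups are rejected", {
  expect_error(comparison_design(c(s1 = "starved_d4"), "fed_vs_starvation"),
               "fed")
  expect_error(comparison_design(c(a = "fed"), "fed_vs_starvation"),
               "no starvation")
  expect_error(comparison_design(c(a = "aposymbiotic", b = "fed5"),
                                 "staged_juvenile"), "fed7")
})

test_that("candidate selection demands the threshold in every comparison", {
  cfg <- pipeline_config()
  design <- comparison_design(
    c(fed = "fed", s4 = "starved_d4", s7 = "starved_d7"),
    "fed_vs_starvation")
  l2fc <- rbind(pass = c(2.41, 1.43),      # published SR-B profile
                fail_one = c(2.5, 0.8),
                fail_all = c(-0.2, 0.4))
  colnames(l2fc) <- c("starved_d4", "starved_d7")
  expect_equal(select_candidates(l2fc, design, cfg), "pass")
  # a missing comparison is an error naming it
  expect_error(select_candidates(l2fc[, 1, drop = FALSE], design, cfg),
               "starved_d7")
})

test_that("staged selection takes the initial-phase upregulated set", {
  cfg <- pipeline_config()
  samples <- stats::setNames(
    rep(c("aposymbiotic", "fed5", "fed7", "fed10"), each = 3),
    paste0(rep(c("apo", "f5", "f7", "f10"), each = 3), "_r", 1:3))
  design <- comparison_design(samples, "staged_juvenile")
  l2fc <- rbind(initial_up = c(2.02, -2.12, 1.33),   # published SR-B profile
                stable_only = c(0.3, 0.2, 3.0),
                initial_down = c(-1.5, 0.0, 0.2))
  colnames(l2fc) <- c("initial", "transient", "stable")
  sel <- select_candidates(l2fc, design, cfg)
  expect_equal(as.character(sel), "initial_up")
  reg <- attr(sel, "stage_regulation")
  expect_equal(unname(reg["initial_up", ]), c("up", "down", "up"))
  expect_equal(unname(reg["initial_down", "initial"]), "down")
  expect_equal(unname(reg["stable_only", "initial"]), "ns")
})

test_that("selection is monotone in the threshold", {
  set.seed(17)
  design <- comparison_design(
    c(fed = "fed", s4 = "starved_d4", s7 = "starved_d7"),
    "fed_vs_starvation")
  l2fc <- matrix(rnorm(600, 1, 1.2), ncol = 2,
                 dimnames = list(sprintf("g%03d", 1:300),
                                 c("starved_d4", "starved_d7")))
  sets <- lapply(c(0.5, 1, 1.5, 2), function(thr)
    select_candidates(l2fc, design, pipeline_config(l2fc_threshold = thr)))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("the candidate report joins category, arrangement and annotation", {
  assignments <- data.frame(
    protein_id = c("gene_b", "gene_a"),
    category = c("SR_B", "C_type_lectin"),
    matched_rule = "r",
    arrangement_string = c("TM + CD36 + TM", "CTLD + CTLD + TM"),
    stringsAsFactors = FALSE)
  annotations <- data.frame(protein_id = "gene_b",
                            description = "Scavenger receptor class B member 1",
                            stringsAsFactors = FALSE)
  l2fc <- matrix(c(2.41, 1.2, 9, 1.43, 2.28, 9), ncol = 2,
                 dimnames = list(c("gene_b", "gene_a", "gene_c"),
                                 c("starved_d4", "starved_d7")))
  rep <- report_candidates(c("gene_b", "gene_a"), assignments, annotations,
                           l2fc)
  cand <- rep$candidates
  expect_equal(nrow(cand), 2L)
  # sorted by category precedence: SR_B before C_type_lectin
  expect_equal(cand$gene_id, c("gene_b", "gene_a"))
  expect_equal(cand$arrangement[1], "TM + CD36 + TM")
  expect_equal(cand$annotation[1], "Scavenger receptor class B member 1")
  expect_equal(cand$starved_d4, c(2.41, 1.2))
  # unassigned genes are still reported, as unclassified
  rep2 <- report_candidates("gene_c", assignments, annotations, l2fc)
  expect_equal(rep2$candidates$category, "unclassified")
  # empty selection gives a header-only table; the full table is intact
  rep3 <- report_candidates(character(0), assignments, annotations, l2fc)
  expect_equal(nrow(rep3$candidates), 0L)
  expect_equal(nrow(rep3$full), 3L)
})

test_that("count matrices round-trip through TSV", {
  dir <- withr::local_tempdir()
  gc <- generate_counts(counts_plan(n_genes = 50, n_planted_up = 5,
                                    rng_seed = 13), dir)
  again <- read_counts(gc$paths$counts)
  expect_equal(again$counts, gc$matrix$counts)
  design <- read_design(gc$paths$design, "fed_vs_starvation")
  expect_equal(names(design$comparisons), c("starved_d4", "starved_d7"))
})
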