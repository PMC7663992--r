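# Element layouts realizing each receptor category's defining arrangement.
# Names are the Pfam family names the vocabulary maps; "TM" marks a helix.
.CATEGORY_TEMPLATES <- list(
  SR_A = c("TM", "Collagen", "SRCR"),
  SR_B = c("TM", "CD36", "TM"),
  SR_E_like = c("TM", "Lectin_C"),
  SR_I = c("TM", "SRCR", "SRCR"),
  C_type_lectin = c("Lectin_C", "Lectin_C", "TM"),
  SRCR_member = c("SRCR"),
  TSP_COMP = c("EGF", "TSP_3", "TSP_C"),
  ADAMTS_like = c("TSP_1", "TSP_1", "I-set", "PLAC"),
  semaphorin_plexin = c("Sema", "PSI"),
  TSR_withTM = c("TSP_1", "TSP_1", "TM"),
  TSR_noTM = rep("TSP_1", 6L),
  TSR_other = c("VWA", "TSP_1", "VWA"),
  unclassified = c("Pkinase")
)

.ELEMENT_LENGTHS <- c(
  TM = 23L, CD36 = 140L, Collagen = 60L, SRCR = 90L, Lectin_C = 110L,
  TSP_1 = 50L, TSP_3 = 35L, TSP_C = 120L, EGF = 40L, Sema = 150L,
  PSI = 45L, "I-set" = 85L, PLAC = 35L, VWA = 170L, Pkinase = 230L
)

.random_aa <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

#' Plan a synthetic proteome
#'
#' @param category_counts Named integer vector: receptor category -> number
#'   of proteins to plant (names from [receptor_categories()]).
#' @param noise_domain_rate Mean number (Poisson) of sub-threshold distractor
#'   domain hits planted per protein, with independent E-values above the
#'   1e-5 filter; a correct pipeline ignores them.
#' @param length_range Allowed protein length range (aa).
#' @param rng_seed Seed; generation is a pure function of (plan, seed).
#' @return A list of class `proteome_plan`.
#' @export
proteome_plan <- function(category_counts = c(SR_B = 10L, SR_E_like = 5L),
                          noise_domain_rate = 0.2,
                          length_range = c(200L, 900L),
                          rng_seed = 1L) {
  bad <- setdiff(names(category_counts), receptor_categories())
  if (length(bad))
    stop("unknown categories in plan: ", paste(bad, collapse = ", "))
  if (any(category_counts < 0)) stop("category counts must be >= 0")
  structure(list(category_counts = category_counts,
                 noise_domain_rate = as.numeric(noise_domain_rate),
                 length_range = as.integer(length_range),
                 rng_seed = as.integer(rng_seed)),
            class = "proteome_plan")
}

# Lay out a template's elements left to right with fixed gaps.
.layout_elements <- function(template, length_range) {
  lens <- .ELEMENT_LENGTHS[template]
  gap <- 12L
  starts <- 8L + c(0L, cumsum(lens[-length(lens)] + gap))
  ends <- starts + lens - 1L
  need <- ends[length(ends)] + 10L
  if (need > length_range[2])
    stop("infeasible plan: arrangement needs ", need,
         " aa but maximum protein length is ", length_range[2])
  plen <- sample(seq(max(need, length_range[1]), length_range[2]), 1L)
  list(names = template, starts = unname(starts), ends = unname(ends),
       protein_length = plen)
}

#' Generate a synthetic annotated proteome
#'
#' Emits everything the annotation stage consumes — a protein FASTA, a
#' per-domain table in the HMMER `domtblout` dialect, TMHMM long-format
#' helix predictions, a 12-column tabular homology file with its two-column
#' taxonomy map — plus a truth table recording each protein's planted
#' category. Real domain hits get independent E-values sampled below the
#' 1e-5 filter; distractor hits (at `noise_domain_rate` per protein) get
#' E-values between 1e-4 and 1e-2 and may carry rule-relevant family names,
#' so they change nothing downstream iff the E-value filter works.
#' Sequences are uniform random amino acids: the pipeline never re-detects
#' domains from sequence, only the annotation files drive it.
#'
#' @param plan A [proteome_plan()].
#' @param dir Output directory (created if needed).
#' @return List with paths (`fasta`, `domtbl`, `tmhmm`, `blast`, `taxmap`,
#'   `truth`) and the `truth` data.frame (protein_id, category,
#'   arrangement).
#' @export
generate_proteome <- function(plan, dir) {
  set.seed(plan$rng_seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- plan$category_counts[plan$category_counts > 0]
  distractor_pool <- c("Lectin_C", "TSP_1", "SRCR", "DUF4537", "zf-C2H2")

  fasta <- character(0)
  dom_rows <- character(0)
  tm_rows <- character(0)
  blast_rows <- character(0)
  truth <- list()
  k <- 0L
  for (cat in names(counts)) {
    template <- .CATEGORY_TEMPLATES[[cat]]
    for (r in seq_len(counts[[cat]])) {
      k <- k + 1L
      id <- sprintf("SYN%05d", k)
      lay <- .layout_elements(template, plan$length_range)
      seq <- .random_aa(lay$protein_length)
      fasta <- c(fasta, paste0(">", id, " planted=", cat), seq)
      labels <- character(0)
      for (e in seq_along(lay$names)) {
        nm <- lay$names[e]
        if (nm == "TM") {
          tm_rows <- c(tm_rows, sprintf("%s\tTMHMM2.0\tTMhelix\t%d\t%d",
                                        id, lay$starts[e], lay$ends[e]))
          labels <- c(labels, "TM")
        } else {
          iev <- 10^stats::runif(1, -30, -6)
          dom_rows <- c(dom_rows,
                        .domtbl_row(nm, id, lay$protein_length,
                                    lay$starts[e], lay$ends[e], iev,
                                    stats::runif(1, 60, 300)))
          mapped <- map_domain_vocabulary(nm, default_domain_vocabulary())
          labels <- c(labels, mapped$label)
        }
      }
      n_noise <- stats::rpois(1, plan$noise_domain_rate)
      for (d in seq_len(n_noise)) {
        nm <- sample(distractor_pool, 1L)
        dlen <- 40L
        dstart <- sample(seq_len(lay$protein_length - dlen), 1L)
        dom_rows <- c(dom_rows,
                      .domtbl_row(nm, id, lay$protein_length, dstart,
                                  dstart + dlen - 1L,
                                  10^stats::runif(1, -4, -2),
                                  stats::runif(1, 5, 20)))
      }
      blast_rows <- c(blast_rows, sprintf(
        "%s\tSP_%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.1e\t%.1f\t%s",
        id, cat, stats::runif(1, 40, 95), 150L, 10L, 2L, 1L, 150L, 1L, 150L,
        10^stats::runif(1, -40, -12), stats::runif(1, 80, 400),
        paste0("synthetic ", gsub("_", "-", cat), " homolog")))
      truth[[k]] <- data.frame(protein_id = id, category = cat,
                               arrangement = paste(labels, collapse = " + "),
                               stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  paths <- list(fasta = file.path(dir, "proteome.fasta"),
                domtbl = file.path(dir, "domains.domtblout"),
                tmhmm = file.path(dir, "tmhmm.txt"),
                blast = file.path(dir, "homology.tsv"),
                taxmap = file.path(dir, "taxmap.tsv"),
                truth_path = file.path(dir, "proteome_truth.tsv"))
  writeLines(fasta, paths$fasta)
  writeLines(c("# synthetic per-domain table (domtblout dialect)", dom_rows),
             paths$domtbl)
  writeLines(tm_rows, paths$tmhmm)
  writeLines(blast_rows, paths$blast)
  writeLines(sprintf("SP_%s\tmetazoa", names(counts)), paths$taxmap)
  utils::write.table(truth, paths$truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(truth = truth))
}

.domtbl_row <- function(domain, protein, qlen, start, end, iev, score) {
  tlen <- end - start + 1L
  sprintf(paste("%s PF%05d.1 %d %s - %d %.1e %.1f 0.1 1 1 %.1e %.1e %.1f 0.1",
                "1 %d %d %d %d %d 0.90 synthetic"),
          domain, sum(utf8ToInt(domain)) %% 16384L, tlen,
          protein, qlen, iev / 100, score + 2, iev / 10, iev, score,
          tlen, start, end, start, end)
}

#' Generate an aligned set of TSP1 segments with planted motifs
#'
#' Builds `n` equal-length (55 aa) pseudo-aligned TSP1 segments over a
#' uniform amino-acid background, planting at fixed columns: the
#' tryptophan GAG-binding tract `WXXWXXW` (W at columns 3/6/9), the exact
#' `CSVTCG` motif (columns 15-20), `GVQTRXR` (columns 25-31), a relaxed
#' `RXR` tract (columns 35-37) and six conserved cysteine columns (15, 19 —
#' inside CSVTCG — plus 40, 44, 48, 52), matching the canonical repeat's
#' six-cysteine consensus.
#'
#' @param n Number of segments (>= 1).
#' @param planted Named logical vector switching each planted feature:
#'   `gag`, `csvtcg`, `gvqtrxr`, `rxr`, `cysteines`.
#' @param rng_seed Seed.
#' @return List with `segments` (character vector) and `truth` (list of
#'   planted column indices per feature).
#' @export
generate_tsp1_set <- function(n,
                              planted = c(gag = TRUE, csvtcg = TRUE,
                                          gvqtrxr = TRUE, rxr = TRUE,
                                          cysteines = TRUE),
                              rng_seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(rng_seed)
  len <- 55L
  truth <- list(gag = c(3L, 6L, 9L), csvtcg = 15:20, gvqtrxr = 25:31,
                rxr = 35:37, cysteines = c(15L, 19L, 40L, 44L, 48L, 52L))
  segments <- vapply(seq_len(n), function(i) {
    s <- sample(AA20, len, replace = TRUE)
    if (isTRUE(planted["gag"])) s[c(3, 6, 9)] <- "W"
    if (isTRUE(planted["csvtcg"])) s[15:20] <- c("C", "S", "V", "T", "C", "G")
    if (isTRUE(planted["gvqtrxr"]))
      s[25:31] <- c("G", "V", "Q", "T", "R", s[30], "R")
    if (isTRUE(planted["rxr"])) { s[35] <- "R"; s[37] <- "R" }
    if (isTRUE(planted["cysteines"])) s[c(40, 44, 48, 52)] <- "C"
    # keep background columns cysteine-free so the planted six stay the
    # only C-majority columns
    bg <- setdiff(seq_len(len), unlist(truth))
    s[bg][s[bg] == "C"] <- "A"
    paste(s, collapse = "")
  }, character(1))
  list(segments = segments, truth = truth)
}

#' Plan a synthetic count matrix
#'
#' Defaults emulate the expression inputs of the study designs: roughly a
#' thousand receptor-scale genes, per-sample depth near one million mapped
#' reads, negative-binomial dispersion 0.1 (biological CV ~0.32), log-normal
#' baseline abundances, and 20 genes planted upregulated in the fed (or
#' initial-phase) condition with a log2 effect of 2.
#'
#' @param n_genes Number of genes.
#' @param n_planted_up Number of genes upregulated in the fed condition.
#' @param design `"fed_vs_starvation"` (unreplicated) or
#'   `"staged_juvenile"` (triplicates).
#' @param n_starvation Number of starvation conditions (fed_vs_starvation).
#' @param n_replicates Replicates per condition (staged_juvenile).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline abundance.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param effect_log2 Planted log2 effect size.
#' @param depth Target per-sample library size.
#' @param rng_seed Seed.
#' @return A list of class `counts_plan`.
#' @export
counts_plan <- function(n_genes = 1000L, n_planted_up = 20L,
                        design = c("fed_vs_starvation", "staged_juvenile"),
                        n_starvation = 2L, n_replicates = 3L,
                        baseline_meanlog = log(200), baseline_sdlog = 1,
                        dispersion = 0.1, effect_log2 = 2, depth = 1e6,
                        rng_seed = 1L) {
  design <- match.arg(design)
  if (n_planted_up > n_genes) stop("n_planted_up must be <= n_genes")
  stopifnot(n_genes > 0, dispersion > 0, depth > 0, n_starvation >= 1,
            n_replicates >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_planted_up = as.integer(n_planted_up),
                 design = design, n_starvation = as.integer(n_starvation),
                 n_replicates = as.integer(n_replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion, effect_log2 = effect_log2,
                 depth = depth, rng_seed = as.integer(rng_seed)),
            class = "counts_plan")
}

#' Generate a count matrix with planted differential expression
#'
#' Draws counts negative-binomially around per-gene baselines scaled to the
#' planned per-sample depth. Planted genes are up-shifted by `2^effect_log2`
#' in the `fed` samples (fed_vs_starvation) or the `fed5` samples (the
#' initial-phase numerator of the staged design).
#'
#' @param plan A [counts_plan()].
#' @param dir Optional output directory; if given, writes `counts.tsv`,
#'   `design.tsv` and `counts_truth.tsv`.
#' @return List with `matrix` (a [count_matrix()]), `design` (a
#'   [comparison_design()]), `planted` (character vector of planted gene
#'   ids) and, if `dir` was given, the file `paths`.
#' @export
generate_counts <- function(plan, dir = NULL) {
  set.seed(plan$rng_seed)
  if (plan$design == "fed_vs_starvation") {
    starv_days <- c(4L, 7L, 30L, 60L)[seq_len(plan$n_starvation)]
    samples <- c("fed", paste0("starved_d", starv_days))
    conditions <- stats::setNames(samples, samples)
    up_samples <- "fed"
  } else {
    conds <- c("aposymbiotic", "fed5", "fed7", "fed10")
    samples <- as.vector(t(outer(conds, seq_len(plan$n_replicates),
                                 function(c, r) paste0(c, "_r", r))))
    conditions <- stats::setNames(rep(conds, each = plan$n_replicates),
                                  samples)
    up_samples <- samples[conditions == "fed5"]
  }
  gene_ids <- sprintf("g%05d", seq_len(plan$n_genes))
  baseline <- stats::rlnorm(plan$n_genes, plan$baseline_meanlog,
                            plan$baseline_sdlog)
  names(baseline) <- gene_ids
  # plant DE among expressed genes (baseline at or above the median): genes
  # below the low-count filter's floor could never be selected regardless of
  # their true effect, so planting there would probe the filter, not the rule
  eligible <- gene_ids[baseline >= stats::median(baseline)]
  planted <- if (plan$n_planted_up > 0)
    sample(eligible, plan$n_planted_up) else character(0)
  counts <- matrix(0L, nrow = plan$n_genes, ncol = length(samples),
                   dimnames = list(gene_ids, samples))
  for (s in samples) {
    mu <- baseline
    if (s %in% up_samples && length(planted))
      mu[planted] <- mu[planted] * 2^plan$effect_log2
    mu <- mu / sum(mu) * plan$depth
    counts[, s] <- stats::rnbinom(plan$n_genes, size = 1 / plan$dispersion,
                                  mu = mu)
  }
  m <- count_matrix(counts)
  design <- comparison_design(conditions, plan$design)
  out <- list(matrix = m, design = design, planted = sort(planted))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(counts = file.path(dir, "counts.tsv"),
                  design = file.path(dir, "design.tsv"),
                  truth = file.path(dir, "counts_truth.tsv"))
    write_counts(m, paths$counts)
    utils::write.table(
      data.frame(sample = names(conditions), condition = unname(conditions)),
      paths$design, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = out$planted),
                       paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Reported candidate genes shipped with the package
#'
#' The per-gene log2-fold-change values, receptor categories, domain
#' arrangements and annotations of the published candidate tables for the
#' three *Elysia* species, as shipped in `inst/extdata`. These serve as
#' worked-example inputs: embedding them among generated decoys and
#' re-running the selection rule must reproduce the published candidate
#' counts.
#'
#' @return A data.frame with columns `species`, `receptor_class`,
#'   `category`, `arrangement`, `gene_id`, `annotation`, `l2fc_1..l2fc_3`
#'   (`NA` where a species has only two comparisons).
#' @export
reported_candidates <- function() {
  utils::read.table(system.file("extdata", "reported_candidates.tsv",
                                package = "kleptorecept"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Reported per-class gene totals shipped with the package
#'
#' For each species and receptor class (SR / TSR): how many genes entered
#' the expression comparison and how many were selected, with the species'
#' design type and number of comparisons.
#'
#' @return A data.frame with columns `species`, `receptor_class`,
#'   `n_genes`, `n_selected`, `species_design`, `n_comparisons`.
#' @export
reported_gene_totals <- function() {
  utils::read.table(system.file("extdata", "reported_gene_totals.tsv",
                                package = "kleptorecept"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Embed reported L2FC values among generated decoy genes
#'
#' Builds a genes-by-comparisons log2-fold-change table containing the
#' given reported rows plus `n_genes - nrow(reported)` decoy genes. Decoys
#' emulate the genes the study reports as *not* selected: their values are
#' drawn from a null spread (`N(0, decoy_sd)`), and any decoy that would
#' satisfy the selection rule of the design is redrawn, since a passing
#' decoy would contradict the reported outcome it emulates.
#'
#' @param reported Numeric matrix (genes x comparisons, rownames = gene
#'   ids) of reported L2FC values.
#' @param n_genes Total number of genes in the returned table.
#' @param species_design `"fed_vs_starvation"` or `"staged_juvenile"`.
#' @param decoy_sd Null spread of decoy L2FC values.
#' @param l2fc_threshold Selection threshold the decoys must fail.
#' @param rng_seed Seed.
#' @return Numeric matrix, `n_genes` x `ncol(reported)`, reported rows
#'   first, with the reported column names.
#' @export
embed_reported_l2fc <- function(reported, n_genes,
                                species_design = c("fed_vs_starvation",
                                                   "staged_juvenile"),
                                decoy_sd = 0.5, l2fc_threshold = 1,
                                rng_seed = 1L) {
  species_design <- match.arg(species_design)
  reported <- as.matrix(reported)
  n_decoys <- n_genes - nrow(reported)
  if (n_decoys < 0) stop("n_genes smaller than the number of reported rows")
  set.seed(rng_seed)
  k <- ncol(reported)
  passes <- function(x) {
    if (species_design == "fed_vs_starvation") all(x > l2fc_threshold)
    else x[1] > l2fc_threshold  # staged: selection looks at the initial phase
  }
  decoys <- matrix(NA_real_, nrow = n_decoys, ncol = k)
  for (i in seq_len(n_decoys)) {
    repeat {
      x <- stats::rnorm(k, 0, decoy_sd)
      if (!passes(x)) break
    }
    decoys[i, ] <- x
  }
  out <- rbind(reported, decoys)
  rownames(out) <- c(rownames(reported),
                     if (n_decoys) sprintf("decoy%04d", seq_len(n_decoys)))
  colnames(out) <- colnames(reported)
  out
}
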