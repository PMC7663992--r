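#' Construct a count matrix object
#'
#' A light container for a raw read-count matrix: integer counts (genes x
#' samples), per-sample library sizes (always the column sums) and
#' per-sample normalization factors (1 until [tmm_factors()] is applied).
#'
#' @param counts Numeric matrix of non-negative counts with gene row names
#'   and sample column names.
#' @param norm_factors Optional per-sample normalization factors.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (length(norm_factors) != ncol(counts) || any(norm_factors <= 0))
    stop("norm_factors must be positive, one per sample")
  structure(list(counts = counts,
                 lib_sizes = colSums(counts),
                 norm_factors = as.numeric(norm_factors)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n  library sizes: ",
      paste(format(x$lib_sizes, big.mark = ","), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample names and gene ids in the first column.
#'
#' @param path Path to a genes-by-samples TSV.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(as.matrix(tab))
}

#' Write a count matrix to TSV
#'
#' @param m A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  tab <- data.frame(gene_id = rownames(m$counts), m$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define the between-condition comparisons of one species design
#'
#' Two designs are supported, mirroring the two experimental layouts the
#' pipeline targets.
#' `fed_vs_starvation`: unreplicated adult samples, one condition named
#' `"fed"` and one or more starvation conditions; each starvation condition
#' yields one comparison, fed (group A) versus that condition (group B).
#' `staged_juvenile`: replicated juvenile samples in four conditions —
#' `aposymbiotic`, `fed5`, `fed7`, `fed10` — yielding the staged
#' comparisons `initial` (fed5 vs aposymbiotic), `transient` (fed7 vs fed5)
#' and `stable` (fed10 vs fed7).
#'
#' @param sample_conditions Named character vector: sample id -> condition.
#' @param species_design `"fed_vs_starvation"` or `"staged_juvenile"`.
#' @return An object of class `comparison_design`: list with
#'   `species_design`, `sample_conditions` and `comparisons` (named list of
#'   `group_a` / `group_b` sample sets).
#' @export
comparison_design <- function(sample_conditions,
                              species_design = c("fed_vs_starvation",
                                                 "staged_juvenile")) {
  species_design <- match.arg(species_design)
  conds <- split(names(sample_conditions), unname(sample_conditions))
  if (species_design == "fed_vs_starvation") {
    if (!"fed" %in% names(conds))
      stop("fed_vs_starvation design needs a condition named 'fed'")
    starved <- setdiff(names(conds), "fed")
    if (!length(starved)) stop("no starvation condition in design")
    comparisons <- lapply(starved, function(s)
      list(group_a = conds$fed, group_b = conds[[s]]))
    names(comparisons) <- starved
  } else {
    need <- c("aposymbiotic", "fed5", "fed7", "fed10")
    missing <- setdiff(need, names(conds))
    if (length(missing))
      stop("staged_juvenile design needs condition(s): ",
           paste(missing, collapse = ", "))
    comparisons <- list(
      initial = list(group_a = conds$fed5, group_b = conds$aposymbiotic),
      transient = list(group_a = conds$fed7, group_b = conds$fed5),
      stable = list(group_a = conds$fed10, group_b = conds$fed7)
    )
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    if (!length(cmp$group_a) || !length(cmp$group_b))
      stop("comparison ", nm, " has an empty group")
    if (length(intersect(cmp$group_a, cmp$group_b)))
      stop("comparison ", nm, " has overlapping groups")
  }
  structure(list(species_design = species_design,
                 sample_conditions = sample_conditions,
                 comparisons = comparisons),
            class = "comparison_design")
}

#' Read a sample design from TSV
#'
#' Two-column TSV with header `sample` and `condition`.
#'
#' @param path Path to the design file.
#' @param species_design Passed to [comparison_design()].
#' @return A `comparison_design`.
#' @export
read_design <- function(path, species_design) {
  if (!file.exists(path)) stop("design file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(tab)))
    stop("design file must have columns 'sample' and 'condition'")
  comparison_design(stats::setNames(tab$condition, tab$sample),
                    species_design)
}

#' Remove low-count genes
#'
#' A gene is kept iff at least `config$min_samples_at_count` samples
#' (default 2) have a raw count of at least `config$min_raw_count`
#' (default 100).
#'
#' @param m A `count_matrix` of raw counts.
#' @param config A [pipeline_config()].
#' @return The filtered `count_matrix` (library sizes recomputed on the
#'   retained genes; normalization factors reset to 1).
#' @export
filter_low_counts <- function(m, config = pipeline_config()) {
  keep <- rowSums(m$counts >= config$min_raw_count) >=
    config$min_samples_at_count
  count_matrix(m$counts[keep, , drop = FALSE])
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample TMM scaling factors: for each sample against the
#' reference, genes with a zero count in either sample are excluded, the
#' per-gene log2 count-ratio (M) and average log2 abundance (A) are doubly
#' trimmed (30% of M at each tail, 5% of A), and the factor is two to the
#' power of the precision-weighted mean of the surviving M values, the
#' weights being first-order delta-method variances. Factors are rescaled
#' to geometric mean 1, so they modulate — not replace — library sizes.
#' The automatic reference is the sample whose 75th count-fraction
#' percentile is closest to the mean across samples.
#'
#' @param m A `count_matrix`.
#' @param reference_sample Optional sample name to use as reference.
#' @param logratio_trim Fraction of M values trimmed at each tail (0.30).
#' @param abundance_trim Fraction of A values trimmed at each tail (0.05).
#' @return Named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(m, reference_sample = NULL,
                        logratio_trim = 0.30, abundance_trim = 0.05) {
  y <- m$counts
  if (ncol(y) < 2L) stop("TMM needs at least two samples")
  if (any(m$lib_sizes == 0)) stop("sample(s) with all-zero counts: ",
                                  paste(colnames(y)[m$lib_sizes == 0],
                                        collapse = ", "))
  N <- m$lib_sizes
  if (is.null(reference_sample)) {
    f75 <- apply(y, 2L, function(col) stats::quantile(col / sum(col), 0.75))
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(reference_sample, colnames(y))
    if (is.na(ref)) stop("reference sample not found: ", reference_sample)
  }
  yr <- y[, ref]
  Nr <- N[ref]
  factors <- vapply(seq_len(ncol(y)), function(k) {
    if (k == ref) return(1)
    yk <- y[, k]
    use <- yk > 0 & yr > 0
    if (!any(use)) return(1)
    pk <- yk[use] / N[k]
    pr <- yr[use] / Nr
    M <- log2(pk / pr)
    A <- (log2(pk) + log2(pr)) / 2
    w <- (N[k] - yk[use]) / (N[k] * yk[use]) + (Nr - yr[use]) / (Nr * yr[use])
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
    if (!is.finite(f)) f <- 0
    2^f
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(y))
}

#' Apply TMM normalization to a count matrix
#'
#' @param m A `count_matrix`.
#' @param ... Passed to [tmm_factors()].
#' @return `m` with `norm_factors` set.
#' @export
normalize_tmm <- function(m, ...) {
  m$norm_factors <- unname(tmm_factors(m, ...))
  m
}

#' Counts per million over effective library sizes
#'
#' @param m A `count_matrix` (normalize first with [normalize_tmm()] to use
#'   effective library sizes).
#' @return Matrix of CPM values, `counts / (lib_size * norm_factor) * 1e6`.
#' @export
cpm <- function(m) {
  eff <- m$lib_sizes * m$norm_factors
  sweep(m$counts, 2L, eff, "/") * 1e6
}

#' Per-gene log2 fold changes for every comparison of a design
#'
#' For each comparison, `log2((mean CPM of group A + prior) /
#' (mean CPM of group B + prior))`; with unreplicated groups the mean is
#' the single sample's CPM. Group means are taken after normalization.
#' The prior keeps ratios finite when one group has zero counts.
#'
#' @param m A normalized, filtered `count_matrix`.
#' @param design A `comparison_design`.
#' @param prior_count CPM-scale pseudo-offset (default 0.5).
#' @return Numeric matrix, genes x comparisons (columns named as the
#'   design's comparisons).
#' @export
log2_fold_change <- function(m, design, prior_count = 0.5) {
  x <- cpm(m)
  out <- vapply(design$comparisons, function(cmp) {
    a <- x[, cmp$group_a, drop = FALSE]
    b <- x[, cmp$group_b, drop = FALSE]
    log2((rowMeans(a) + prior_count) / (rowMeans(b) + prior_count))
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), names(design$comparisons)))
  out
}

#' Select candidate recognition genes from log2 fold changes
#'
#' Implements the threshold-only significance rule (|L2FC| > 1 by default;
#' no p-values are computed). For a `fed_vs_starvation` design a gene is a
#' candidate iff its L2FC exceeds the threshold in *every* fed-vs-starved
#' comparison. For a `staged_juvenile` design a gene is a candidate iff it
#' is upregulated (L2FC above threshold) in the `initial` comparison; the
#' per-stage up/down calls for all stages are returned alongside.
#'
#' @param l2fc Genes x comparisons matrix from [log2_fold_change()].
#' @param design A `comparison_design`.
#' @param config A [pipeline_config()] (uses `l2fc_threshold`).
#' @return Character vector of selected gene ids, with attribute
#'   `stage_regulation` (genes x stages character matrix of
#'   "up"/"down"/"ns") for staged designs.
#' @export
select_candidates <- function(l2fc, design, config = pipeline_config()) {
  missing <- setdiff(names(design$comparisons), colnames(l2fc))
  if (length(missing))
    stop("missing comparison column(s): ", paste(missing, collapse = ", "))
  thr <- config$l2fc_threshold
  if (design$species_design == "fed_vs_starvation") {
    cols <- l2fc[, names(design$comparisons), drop = FALSE]
    sel <- rownames(l2fc)[rowSums(cols > thr) == ncol(cols)]
    return(sel)
  }
  reg <- ifelse(l2fc > thr, "up", ifelse(l2fc < -thr, "down", "ns"))
  sel <- rownames(l2fc)[reg[, "initial"] == "up"]
  attr(sel, "stage_regulation") <- reg
  sel
}

#' Assemble the candidate-gene report table
#'
#' Joins selected genes to their receptor category, domain arrangement and
#' homology annotation, with one L2FC column per comparison — the layout of
#' a published candidate table. Genes without a receptor assignment are
#' reported as `unclassified`. The full per-gene L2FC table is returned
#' alongside for heat-map plotting.
#'
#' @param selected Character vector of gene ids from [select_candidates()].
#' @param assignments Assignment data frame from [classify_all()] (gene ids
#'   are matched against `protein_id`).
#' @param annotations Annotation data frame (needs `protein_id` and
#'   `description`), or NULL.
#' @param l2fc Genes x comparisons L2FC matrix.
#' @return A list with `candidates` (data.frame: category, arrangement,
#'   gene_id, annotation, one column per comparison; sorted by category then
#'   gene id) and `full` (the complete L2FC table as a data.frame).
#' @export
report_candidates <- function(selected, assignments, annotations, l2fc) {
  full <- data.frame(gene_id = rownames(l2fc), l2fc, check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (!length(selected)) {
    cand <- data.frame(category = character(), arrangement = character(),
                       gene_id = character(), annotation = character(),
                       stringsAsFactors = FALSE)
    for (nm in colnames(l2fc)) cand[[nm]] <- numeric(0)
    return(list(candidates = cand, full = full))
  }
  i <- match(selected, assignments$protein_id)
  category <- ifelse(is.na(i), "unclassified", assignments$category[i])
  arrangement <- ifelse(is.na(i), "", assignments$arrangement_string[i])
  ann <- rep("", length(selected))
  if (!is.null(annotations) && nrow(annotations)) {
    j <- match(selected, annotations$protein_id)
    ann <- ifelse(is.na(j), "", annotations$description[j])
  }
  cand <- data.frame(category = category, arrangement = arrangement,
                     gene_id = selected, annotation = ann,
                     stringsAsFactors = FALSE)
  cand <- cbind(cand, as.data.frame(l2fc[selected, , drop = FALSE],
                                    check.names = FALSE))
  ord <- order(factor(cand$category, levels = receptor_categories()),
               cand$gene_id)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, full = full)
}
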