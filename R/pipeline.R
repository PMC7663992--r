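.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the receptor-discovery pipeline end to end
#'
#' Stage order: parse the annotation artifacts, apply the homology filters,
#' build per-protein domain architectures, classify them into receptor
#' categories, scan TSP1 segments for motifs and build the logo matrix
#' (when all segments share one length), then — if expression inputs are
#' configured — filter and TMM-normalize the counts, compute per-comparison
#' log2 fold changes and select candidate genes. Any stage failure aborts
#' with an error naming the stage. Outputs are deterministic functions of
#' the inputs and configuration.
#'
#' @param inputs Named list of input paths: `fasta`, `domtbl`, `tmhmm`
#'   (required); `blast` + `taxmap` (optional homology annotations);
#'   `counts` + `design` + `species_design` (optional expression stage).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; if given, all report surfaces and
#'   the run manifest are written there.
#' @param vocabulary Domain vocabulary (see [default_domain_vocabulary()]).
#' @param rules Classification rule set (see [default_ruleset()]).
#' @return A list with `assignments`, `category_counts`,
#'   `architecture_summary`, `motif_reports`, `logo_matrix` (or NULL),
#'   `annotations`, `l2fc`, `selected`, `candidates` and `manifest`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         output_dir = NULL,
                         vocabulary = default_domain_vocabulary(),
                         rules = default_ruleset()) {
  for (req in c("fasta", "domtbl", "tmhmm"))
    if (is.null(inputs[[req]]))
      stop("pipeline stage 'parse' failed: required input '", req,
           "' not configured", call. = FALSE)

  proteins <- .stage("parse", read_fasta(inputs$fasta))
  hits <- .stage("parse", parse_domain_hits(inputs$domtbl))
  tms <- .stage("parse", parse_tm_regions(inputs$tmhmm))

  annotations <- NULL
  if (!is.null(inputs$blast)) {
    if (is.null(inputs$taxmap))
      stop("pipeline stage 'filter' failed: homology input needs a taxmap",
           call. = FALSE)
    annotations <- .stage("filter", filter_annotations(
      read_blast_annotations(inputs$blast, inputs$taxmap), config))
  }

  archs <- .stage("architect",
                  build_architectures(proteins, hits, tms, config, vocabulary))
  arch_summary <- summarize_architectures(archs)
  cls <- .stage("classify", classify_all(archs, rules))

  motif_reports <- .stage("motifs", {
    reports <- lapply(names(archs), function(id) {
      p <- proteins[proteins$id == id, ]
      scan_tsp1_motifs(archs[[id]], p)
    })
    do.call(rbind, c(reports, list(make.row.names = FALSE)))
  })
  logo <- NULL
  if (!is.null(motif_reports) && nrow(motif_reports) &&
      length(unique(nchar(motif_reports$segment))) == 1L)
    logo <- .stage("logo", build_logo_matrix(motif_reports$segment,
                                             config$logo_pseudocount))

  l2fc <- NULL; selected <- character(0); candidates <- NULL; m_filtered <- NULL
  if (!is.null(inputs$counts)) {
    if (is.null(inputs$design) || is.null(inputs$species_design))
      stop("pipeline stage 'expression' failed: counts configured without ",
           "a design file and species_design", call. = FALSE)
    m <- .stage("expression", read_counts(inputs$counts))
    design <- .stage("expression",
                     read_design(inputs$design, inputs$species_design))
    m_filtered <- .stage("expression", filter_low_counts(m, config))
    m_norm <- .stage("expression", normalize_tmm(m_filtered))
    l2fc <- .stage("expression",
                   log2_fold_change(m_norm, design, config$prior_count))
    selected <- .stage("select", select_candidates(l2fc, design, config))
    candidates <- .stage("report", report_candidates(
      selected, cls$assignments, annotations, l2fc))
  }

  manifest <- list(
    tool = paste0("kleptorecept ",
                  as.character(utils::packageVersion("kleptorecept"))),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(inputs[vapply(
      inputs, function(x) is.character(x) && file.exists(x), logical(1))]))),
    counts = list(
      proteins_read = nrow(proteins),
      domain_hits_read = nrow(hits),
      tm_regions_read = nrow(tms),
      annotations_kept = if (is.null(annotations)) NA_integer_
                         else nrow(annotations),
      architectures_built = length(archs),
      classified_per_category = as.list(cls$counts),
      tsp1_segments = if (is.null(motif_reports)) 0L else nrow(motif_reports),
      genes_read = if (is.null(inputs$counts)) NA_integer_
                   else nrow(read_counts(inputs$counts)$counts),
      genes_after_filter = if (is.null(m_filtered)) NA_integer_
                           else nrow(m_filtered$counts),
      candidates_selected = length(selected)
    )
  )

  result <- list(assignments = cls$assignments,
                 category_counts = cls$counts,
                 architecture_summary = arch_summary,
                 motif_reports = motif_reports,
                 logo_matrix = logo,
                 annotations = annotations,
                 l2fc = l2fc, selected = selected,
                 candidates = candidates, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_assignments(cls$assignments,
                      file.path(output_dir, "assignments.tsv"))
    utils::write.table(arch_summary,
                       file.path(output_dir, "architecture_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(motif_reports))
      utils::write.table(motif_reports,
                         file.path(output_dir, "motif_reports.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(logo))
      write_logo_matrix(logo, file.path(output_dir, "logo_matrix.tsv"))
    if (!is.null(l2fc))
      utils::write.table(
        data.frame(gene_id = rownames(l2fc), l2fc, check.names = FALSE),
        file.path(output_dir, "l2fc.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(candidates))
      utils::write.table(candidates$candidates,
                         file.path(output_dir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
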