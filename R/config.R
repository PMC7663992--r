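#' Pipeline configuration
#'
#' Collects every numeric threshold the pipeline applies, with the defaults
#' used throughout: homology hits are kept at BLAST E-value <= 1e-10,
#' domain hits at independent E-value <= 1e-5, proteins at >= 150 aa,
#' genes at >= 100 raw counts in at least 2 samples, and candidates at
#' |log2 fold change| > 1.
#'
#' @param blast_evalue_max Maximum BLAST E-value for a homology annotation.
#' @param domain_ievalue_max Maximum independent E-value for a Pfam domain hit.
#' @param min_protein_length Minimum protein length (amino acids) for a
#'   protein to receive a domain architecture.
#' @param l2fc_threshold Log2-fold-change magnitude a gene must exceed to be
#'   called differentially expressed.
#' @param min_raw_count Raw-count level used by the low-count filter.
#' @param min_samples_at_count Number of samples that must reach
#'   `min_raw_count` for a gene to be kept.
#' @param prior_count Pseudo-offset added to group mean CPM before taking the
#'   log2 ratio, to keep fold changes finite at zero counts.
#' @param max_overlap_frac Maximum allowed overlap between two retained
#'   domain hits, as a fraction of the shorter hit.
#' @param logo_pseudocount Per-residue pseudocount used when building logo
#'   frequency matrices.
#' @param rng_seed Seed recorded for generator runs driven by this config.
#' @return A list of class `kleptorecept_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$domain_ievalue_max
#' @export
pipeline_config <- function(blast_evalue_max = 1e-10,
                            domain_ievalue_max = 1e-5,
                            min_protein_length = 150L,
                            l2fc_threshold = 1.0,
                            min_raw_count = 100L,
                            min_samples_at_count = 2L,
                            prior_count = 0.5,
                            max_overlap_frac = 0.25,
                            logo_pseudocount = 0,
                            rng_seed = 1L) {
  cfg <- list(
    blast_evalue_max = as.numeric(blast_evalue_max),
    domain_ievalue_max = as.numeric(domain_ievalue_max),
    min_protein_length = as.integer(min_protein_length),
    l2fc_threshold = as.numeric(l2fc_threshold),
    min_raw_count = as.integer(min_raw_count),
    min_samples_at_count = as.integer(min_samples_at_count),
    prior_count = as.numeric(prior_count),
    max_overlap_frac = as.numeric(max_overlap_frac),
    logo_pseudocount = as.numeric(logo_pseudocount),
    rng_seed = as.integer(rng_seed)
  )
  thresholds <- c("blast_evalue_max", "domain_ievalue_max",
                  "min_protein_length", "l2fc_threshold", "min_raw_count",
                  "min_samples_at_count")
  bad <- thresholds[vapply(cfg[thresholds], function(x) !is.finite(x) || x <= 0,
                           logical(1))]
  if (length(bad))
    stop("configuration thresholds must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (cfg$logo_pseudocount < 0) stop("logo_pseudocount must be >= 0")
  class(cfg) <- "kleptorecept_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path Path to a YAML file of configuration fields.
#' @return A `kleptorecept_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.kleptorecept_config <- function(x, ...) {
  cat("kleptorecept pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}
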