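#' Resolve overlapping domain hits on one protein
#'
#' Profile-HMM scans routinely report several overlapping family hits over
#' the same stretch of sequence; an architecture needs one winner per
#' region. Hits are admitted greedily in order of evidence strength —
#' ascending independent E-value, ties broken by descending bit score, then
#' ascending start (then end and family name, so the outcome does not
#' depend on input order) — and a hit is kept only if its overlap with every
#' already-admitted hit is at most `max_overlap_frac` of the shorter of the
#' two.
#'
#' @param hits Data frame of domain hits on a single protein
#'   (see [parse_domain_hits()]).
#' @param max_overlap_frac Maximum tolerated pairwise overlap, as a fraction
#'   of the shorter hit. Default 0.25.
#' @return The admitted subset of `hits`, sorted by start.
#' @export
resolve_overlaps <- function(hits, max_overlap_frac = 0.25) {
  if (is.null(hits) || !nrow(hits)) return(hits)
  if (length(unique(hits$protein_id)) > 1L)
    stop("resolve_overlaps expects hits on a single protein")
  ord <- order(hits$i_evalue, -hits$bit_score, hits$start, hits$end,
               hits$domain_name)
  admitted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in admitted) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov > 0) {
        shorter <- min(hits$end[i] - hits$start[i] + 1L,
                       hits$end[j] - hits$start[j] + 1L)
        if (ov > max_overlap_frac * shorter) { ok <- FALSE; break }
      }
    }
    if (ok) admitted <- c(admitted, i)
  }
  out <- hits[sort(admitted), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the domain architecture of one protein
#'
#' Applies the protein-level length filter (>= `config$min_protein_length`,
#' default 150 aa) and the per-domain independent E-value filter
#' (<= `config$domain_ievalue_max`, default 1e-5), resolves overlapping
#' Pfam hits, and merges the survivors with the protein's transmembrane
#' regions into one ascending-start element list. A TM helix that overlaps
#' a retained Pfam domain by more than half of the helix is suppressed from
#' the arrangement (a helix inside a domain is topology, not arrangement);
#' TM regions are never discarded by overlap resolution among themselves.
#' Repeated adjacent identical domains are kept as repeats, never collapsed.
#'
#' @param protein One-row data frame (or list) with `id`, `length` and
#'   optionally `sequence`.
#' @param hits Domain hits for this protein (may be empty).
#' @param tms TM regions for this protein (may be empty).
#' @param config A [pipeline_config()].
#' @param vocabulary Domain vocabulary (see [default_domain_vocabulary()]).
#' @return A list of class `domain_architecture` with fields `protein_id`,
#'   `protein_length`, `elements` (data.frame kind/label/concept/start/end)
#'   and `arrangement_string`, or `NULL` if the protein is shorter than the
#'   minimum length.
#' @examples
#' cfg <- pipeline_config()
#' prot <- data.frame(id = "p1", length = 500)
#' hits <- data.frame(protein_id = "p1", domain_name = "CD36",
#'                    accession = "PF01130.21", i_evalue = 1e-30,
#'                    start = 40, end = 380, bit_score = 200)
#' tms <- data.frame(protein_id = "p1", start = c(5, 390), end = c(27, 412))
#' build_architecture(prot, hits, tms, cfg)$arrangement_string
#' @export
build_architecture <- function(protein, hits, tms, config = pipeline_config(),
                               vocabulary = default_domain_vocabulary()) {
  plen <- as.integer(protein$length)
  if (plen < config$min_protein_length) return(NULL)
  if (!is.null(hits) && nrow(hits)) {
    if (any(hits$protein_id != protein$id))
      stop("hits do not belong to protein ", protein$id)
    hits <- hits[hits$i_evalue <= config$domain_ievalue_max, , drop = FALSE]
    hits <- resolve_overlaps(hits, config$max_overlap_frac)
  }
  if (!is.null(tms) && nrow(tms) && any(tms$protein_id != protein$id))
    stop("TM regions do not belong to protein ", protein$id)

  elements <- data.frame(kind = character(), label = character(),
                         concept = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  if (!is.null(hits) && nrow(hits)) {
    mapped <- map_domain_vocabulary(hits$domain_name, vocabulary)
    elements <- rbind(elements, data.frame(
      kind = "pfam_domain", label = mapped$label, concept = mapped$concept,
      start = hits$start, end = hits$end, stringsAsFactors = FALSE))
  }
  if (!is.null(tms) && nrow(tms)) {
    keep_tm <- rep(TRUE, nrow(tms))
    if (nrow(elements)) {
      for (k in seq_len(nrow(tms))) {
        tm_len <- tms$end[k] - tms$start[k] + 1L
        ov <- pmax(0L, pmin(tms$end[k], elements$end) -
                     pmax(tms$start[k], elements$start) + 1L)
        if (any(ov > 0.5 * tm_len)) keep_tm[k] <- FALSE
      }
    }
    if (any(keep_tm))
      elements <- rbind(elements, data.frame(
        kind = "tm", label = "TM", concept = "TM",
        start = tms$start[keep_tm], end = tms$end[keep_tm],
        stringsAsFactors = FALSE))
  }
  if (nrow(elements) && any(elements$end > plen))
    stop("element extends beyond protein ", protein$id,
         " (length ", plen, ")")
  elements <- elements[order(elements$start, elements$end), , drop = FALSE]
  rownames(elements) <- NULL
  structure(list(
    protein_id = protein$id,
    protein_length = plen,
    elements = elements,
    arrangement_string = paste(elements$label, collapse = " + ")
  ), class = "domain_architecture")
}

#' Build architectures for a whole proteome
#'
#' @param proteins Data frame from [read_fasta()].
#' @param hits All domain hits.
#' @param tms All TM regions.
#' @param config A [pipeline_config()].
#' @param vocabulary Domain vocabulary.
#' @return A named list of `domain_architecture` objects (proteins failing
#'   the length filter are absent).
#' @export
build_architectures <- function(proteins, hits, tms,
                                config = pipeline_config(),
                                vocabulary = default_domain_vocabulary()) {
  check_protein_coverage(proteins, hits, tms)
  hit_split <- if (!is.null(hits) && nrow(hits))
    split(hits, hits$protein_id) else list()
  tm_split <- if (!is.null(tms) && nrow(tms))
    split(tms, tms$protein_id) else list()
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    p <- proteins[i, ]
    arch <- build_architecture(p, hit_split[[p$id]], tm_split[[p$id]],
                               config, vocabulary)
    if (!is.null(arch)) out[[p$id]] <- arch
  }
  out
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat("<domain_architecture> ", x$protein_id, " (", x$protein_length,
      " aa)\n  ", if (nzchar(x$arrangement_string)) x$arrangement_string
      else "(no elements)", "\n", sep = "")
  invisible(x)
}

#' Summarize architectures by arrangement string
#'
#' @param archs A list of `domain_architecture` objects.
#' @param max_examples Number of example protein ids to keep per row.
#' @return A data.frame with columns `arrangement`, `n`, `examples`, sorted
#'   by descending count; counts sum to `length(archs)`.
#' @export
summarize_architectures <- function(archs, max_examples = 3L) {
  if (!length(archs))
    return(data.frame(arrangement = character(), n = integer(),
                      examples = character(), stringsAsFactors = FALSE))
  arr <- vapply(archs, `[[`, character(1), "arrangement_string")
  ids <- vapply(archs, `[[`, character(1), "protein_id")
  by_arr <- split(ids, arr)
  out <- data.frame(
    arrangement = names(by_arr),
    n = lengths(by_arr),
    examples = vapply(by_arr, function(x)
      paste(utils::head(x, max_examples), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n, out$arrangement), , drop = FALSE]
  rownames(out) <- NULL
  out
}
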