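#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and returns a plain data frame of
#' protein records. The record id is the first whitespace-delimited token of
#' the header. No length filtering happens here; short proteins are removed
#' later by [build_architecture()].
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data.frame with columns `id`, `sequence`, `length` (aa), one
#'   row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(aa)
  empty <- which(nchar(seqs) == 0L)
  if (length(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", toupper(seqs))
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  data.frame(id = ids, sequence = toupper(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# Column layout of HMMER3 per-domain tabular output (hmmscan --domtblout):
# 1 target (Pfam family) name, 2 target accession, 4 query (protein) name,
# 13 independent E-value, 14 domain bit score, 20-21 envelope from/to.
.DOMTBL_MIN_FIELDS <- 22L

#' Parse HMMER per-domain tabular output
#'
#' Reads the whitespace-delimited per-domain table written by a profile-HMM
#' scan against Pfam (`--domtblout`). Hit extents are taken from the envelope
#' coordinate columns, which bound the region the domain plausibly occupies
#' and are therefore what arrangement adjacency should see. Coordinates are
#' 1-based inclusive. No E-value filtering happens here.
#'
#' @param path Path to the tabular file; comment lines start with `#`.
#' @param dialect Table dialect; only `"domtblout"` is supported.
#' @return A data.frame with columns `protein_id`, `domain_name`,
#'   `accession`, `i_evalue`, `start`, `end`, `bit_score`.
#' @export
parse_domain_hits <- function(path, dialect = "domtblout") {
  dialect <- match.arg(dialect, "domtblout")
  if (!file.exists(path)) stop("domain table not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows))
    return(data.frame(protein_id = character(), domain_name = character(),
                      accession = character(), i_evalue = numeric(),
                      start = integer(), end = integer(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < .DOMTBL_MIN_FIELDS))
    stop("short row (", nf[which(nf < .DOMTBL_MIN_FIELDS)[1]],
         " fields, expected >= ", .DOMTBL_MIN_FIELDS, ") at line ",
         rows[which(nf < .DOMTBL_MIN_FIELDS)[1]], " of ", path)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(x))
      stop("non-numeric ", what, " at line ", rows[which(is.na(x))[1]],
           " of ", path)
    x
  }
  hits <- data.frame(
    protein_id = get(4L),
    domain_name = get(1L),
    accession = get(2L),
    i_evalue = num(13L, "independent E-value"),
    start = as.integer(num(20L, "envelope start")),
    end = as.integer(num(21L, "envelope end")),
    bit_score = num(14L, "bit score"),
    stringsAsFactors = FALSE
  )
  if (any(hits$start < 1L | hits$end < 1L))
    stop("negative or zero envelope coordinate at line ",
         rows[which(hits$start < 1L | hits$end < 1L)[1]], " of ", path)
  if (any(hits$start > hits$end))
    stop("envelope start > end at line ",
         rows[which(hits$start > hits$end)[1]], " of ", path)
  if (any(hits$i_evalue <= 0))
    stop("non-positive independent E-value at line ",
         rows[which(hits$i_evalue <= 0)[1]], " of ", path)
  hits
}

#' Parse transmembrane-helix predictions
#'
#' Accepts either TMHMM dialect, auto-detected: the long format (one
#' `TMhelix` row per predicted helix) or the one-line summary format (helix
#' coordinates embedded in the `Topology=` string). Coordinates are 1-based
#' inclusive. Regions are returned sorted by start within each protein.
#'
#' @param path Path to a TMHMM output file.
#' @return A data.frame with columns `protein_id`, `start`, `end`; zero rows
#'   if no helices are predicted.
#' @export
parse_tm_regions <- function(path) {
  if (!file.exists(path)) stop("TM prediction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(trimws(lines), "\\s+")
  long_like <- vapply(fields, function(f)
    length(f) == 5L && f[3] %in% c("TMhelix", "inside", "outside"),
    logical(1))
  short_like <- grepl("Topology=", lines, fixed = TRUE)
  if (all(long_like)) {
    helix <- vapply(fields, function(f) f[3] == "TMhelix", logical(1))
    if (!any(helix)) return(empty)
    f <- fields[helix]
    out <- data.frame(
      protein_id = vapply(f, `[[`, character(1), 1L),
      start = suppressWarnings(as.integer(vapply(f, `[[`, character(1), 4L))),
      end = suppressWarnings(as.integer(vapply(f, `[[`, character(1), 5L))),
      stringsAsFactors = FALSE
    )
  } else if (all(short_like)) {
    parse_one <- function(line, f) {
      topo <- sub("^.*Topology=", "", line)
      m <- regmatches(topo, gregexpr("\\d+-\\d+", topo))[[1]]
      if (!length(m)) return(NULL)
      ends <- strsplit(m, "-", fixed = TRUE)
      data.frame(
        protein_id = f[1],
        start = as.integer(vapply(ends, `[[`, character(1), 1L)),
        end = as.integer(vapply(ends, `[[`, character(1), 2L)),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, Map(parse_one, lines, fields))
    if (is.null(out)) return(empty)
    rownames(out) <- NULL
  } else {
    first_bad <- which(!long_like & !short_like)[1]
    stop("unrecognized TM prediction dialect; first offending line: ",
         lines[if (is.na(first_bad)) which(!long_like)[1] else first_bad])
  }
  if (anyNA(out$start) || anyNA(out$end) || any(out$start < 1L))
    stop("invalid helix coordinates in ", path)
  if (any(out$start > out$end))
    stop("helix start > end in ", path)
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  by_prot <- split(seq_len(nrow(out)), out$protein_id)
  for (idx in by_prot) {
    if (length(idx) > 1L &&
        any(out$start[idx][-1] <= out$end[idx][-length(idx)]))
      stop("overlapping helices for protein ", out$protein_id[idx[1]])
  }
  out
}

#' Read tabular homology annotations with a taxonomy mapping
#'
#' Reads 12-column tabular BLAST output (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query/subject coordinates,
#' E-value, bit score; an optional 13th column is taken as the subject
#' description) and joins each subject accession to a taxonomic group via a
#' two-column mapping file. Subjects absent from the mapping are marked
#' `unknown`.
#'
#' @param path Path to the tabular homology file.
#' @param taxmap_path Path to a two-column TSV mapping subject accession to
#'   a group label (`metazoa` or `non_metazoa`).
#' @return A data.frame with columns `protein_id`, `subject_id`,
#'   `description`, `evalue`, `taxon_group`.
#' @export
read_blast_annotations <- function(path, taxmap_path) {
  if (!file.exists(path)) stop("homology table not found: ", path)
  if (!file.exists(taxmap_path)) stop("taxonomy map not found: ", taxmap_path)
  tab <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = paste0("V", 1:13), fill = TRUE,
                           header = FALSE)
  if (nrow(tab) && any(is.na(tab$V11)))
    stop("missing E-value column; expected 12-column tabular BLAST output")
  taxmap <- utils::read.table(taxmap_path, sep = "\t", quote = "",
                              stringsAsFactors = FALSE, header = FALSE)
  if (ncol(taxmap) < 2L) stop("taxonomy map must have two columns")
  groups <- taxmap[[2]][match(tab$V2, taxmap[[1]])]
  groups[is.na(groups)] <- "unknown"
  bad <- setdiff(unique(groups), c("metazoa", "non_metazoa", "unknown"))
  if (length(bad))
    stop("unknown taxon group label(s) in map: ", paste(bad, collapse = ", "))
  desc <- tab$V13
  desc[is.na(desc) | !nzchar(desc)] <- tab$V2[is.na(desc) | !nzchar(desc)]
  data.frame(protein_id = tab$V1, subject_id = tab$V2, description = desc,
             evalue = as.numeric(tab$V11), taxon_group = groups,
             stringsAsFactors = FALSE)
}

#' Filter homology annotations by E-value and taxonomy
#'
#' A record is retained iff its E-value is at or below
#' `config$blast_evalue_max` and its subject maps to Metazoa. Records with
#' unknown taxonomy are dropped and their count reported via `message()`.
#' By default only the best (lowest-E-value) hit per protein is considered
#' before filtering; set `best_hit_only = FALSE` to keep all hits.
#'
#' @param records Data frame as returned by [read_blast_annotations()].
#' @param config A [pipeline_config()].
#' @param best_hit_only Keep only the lowest-E-value hit per protein first.
#' @return The retained subset of `records`, in input order.
#' @export
filter_annotations <- function(records, config = pipeline_config(),
                               best_hit_only = TRUE) {
  if (!nrow(records)) return(records)
  if (best_hit_only) {
    ord <- order(records$protein_id, records$evalue)
    best <- ord[!duplicated(records$protein_id[ord])]
    records <- records[sort(best), , drop = FALSE]
  }
  n_unknown <- sum(records$taxon_group == "unknown")
  if (n_unknown > 0)
    message(n_unknown, " annotation record(s) without taxonomy mapping dropped")
  keep <- records$evalue <= config$blast_evalue_max &
    records$taxon_group == "metazoa"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check that annotation files only reference known proteins
#'
#' Hits or TM regions for proteins absent from the FASTA indicate mismatched
#' inputs and are a hard error.
#'
#' @param proteins Data frame from [read_fasta()].
#' @param hits Data frame from [parse_domain_hits()] (or NULL).
#' @param tms Data frame from [parse_tm_regions()] (or NULL).
#' @return Invisibly TRUE.
#' @export
check_protein_coverage <- function(proteins, hits = NULL, tms = NULL) {
  for (tab in list(hits = hits, tms = tms)) {
    if (is.null(tab) || !nrow(tab)) next
    missing <- setdiff(unique(tab$protein_id), proteins$id)
    if (length(missing))
      stop("annotation refers to protein(s) absent from the FASTA: ",
           paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
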