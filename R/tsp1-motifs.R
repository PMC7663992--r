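AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Extract TSP1 segments from an architecture
#'
#' Returns the subsequences of the protein covered by the architecture's
#' TSP1 elements, in element order.
#'
#' @param arch A `domain_architecture` containing >= 0 TSP1 elements.
#' @param protein One-row data frame (or list) with `id` and `sequence`.
#' @return Character vector of segments (empty if the architecture has no
#'   TSP1 element).
#' @export
extract_tsp1_segments <- function(arch, protein) {
  if (arch$protein_id != protein$id)
    stop("architecture and protein ids differ")
  el <- arch$elements
  tsp1 <- el[el$kind == "pfam_domain" & el$concept == "TSP1", , drop = FALSE]
  if (!nrow(tsp1)) return(character(0))
  if (any(tsp1$end > nchar(protein$sequence)))
    stop("TSP1 element extends beyond the sequence of ", protein$id)
  substring(protein$sequence, tsp1$start, tsp1$end)
}

# Hamming distance <= max_mismatch match of `pattern` anywhere in `x`;
# positions where pattern has "X" match any residue for free.
.fuzzy_match <- function(x, pattern, max_mismatch) {
  pat <- strsplit(pattern, "")[[1]]
  fixed <- pat != "X"
  k <- length(pat)
  n <- nchar(x)
  if (n < k) return(FALSE)
  chars <- strsplit(x, "")[[1]]
  for (i in seq_len(n - k + 1L)) {
    window <- chars[i:(i + k - 1L)]
    if (sum(window[fixed] != pat[fixed]) <= max_mismatch) return(TRUE)
  }
  FALSE
}

#' Scan a TSP1 segment for its diagnostic motifs
#'
#' Reports, for one TSP1 domain segment: the total cysteine count (a
#' canonical TSP1 repeat carries six conserved cysteines); the tryptophan
#' glycosaminoglycan/protein-binding tract `WXXWXXW`; the CD36/SR-B binding
#' motifs `CSVTCG` and `GVQTRXR`, each matched exactly and in a
#' one-mismatch-tolerant mode (divergent repeats often carry a motif
#' *similar* to CSVTCG rather than the literal hexapeptide); and the
#' polar-residue `RXR` tract. In the default relaxed mode the R positions of
#' the RXR tract may be arginine, lysine or glutamine; `strict_rxr = TRUE`
#' demands arginine.
#'
#' @param segment Non-empty amino-acid string.
#' @param strict_rxr Require arginine (not R/K/Q) at the R positions.
#' @return A one-row data.frame with columns `cysteine_count`,
#'   `has_gag_motif`, `has_csvtcg`, `has_csvtcg_like`, `has_gvqtrxr`,
#'   `has_gvqtrxr_like`, `has_rxr_motif`, `segment`.
#' @examples
#' scan_motifs("ACDWSPWSEWSECSVTCGRGRQTR")
#' @export
scan_motifs <- function(segment, strict_rxr = FALSE) {
  if (!nzchar(segment)) stop("segment must be a non-empty amino-acid string")
  segment <- toupper(segment)
  rxr <- if (strict_rxr) "R.R" else "[RKQ].[RKQ]"
  data.frame(
    cysteine_count = lengths(regmatches(segment, gregexpr("C", segment))),
    has_gag_motif = grepl("W..W..W", segment),
    has_csvtcg = grepl("CSVTCG", segment, fixed = TRUE),
    has_csvtcg_like = .fuzzy_match(segment, "CSVTCG", 1L),
    has_gvqtrxr = grepl("GVQTR.R", segment),
    has_gvqtrxr_like = .fuzzy_match(segment, "GVQTRXR", 1L),
    has_rxr_motif = grepl(rxr, segment),
    segment = segment,
    stringsAsFactors = FALSE
  )
}

#' Scan every TSP1 segment of an architecture
#'
#' @param arch A `domain_architecture`.
#' @param protein One-row data frame with `id` and `sequence`.
#' @param strict_rxr Passed to [scan_motifs()].
#' @return A data.frame with `protein_id` and `segment_index` prepended to
#'   the [scan_motifs()] columns; zero rows if no TSP1 element.
#' @export
scan_tsp1_motifs <- function(arch, protein, strict_rxr = FALSE) {
  segs <- extract_tsp1_segments(arch, protein)
  if (!length(segs)) {
    out <- cbind(data.frame(protein_id = character(),
                            segment_index = integer()),
                 scan_motifs("A")[0, ])
    return(out)
  }
  reports <- do.call(rbind, lapply(segs, scan_motifs, strict_rxr = strict_rxr))
  cbind(data.frame(protein_id = arch$protein_id,
                   segment_index = seq_along(segs),
                   stringsAsFactors = FALSE),
        reports)
}

#' Build a position frequency / information matrix from aligned segments
#'
#' Computes, for each alignment column, residue frequencies (with optional
#' pseudocount smoothing: `(count + pc) / (n + 20 pc)`) and the sequence-logo
#' information content `log2(20) - H`, where `H` is the column's Shannon
#' entropy in bits. No small-sample correction is applied. Residues outside
#' the 20-letter alphabet (gaps, X) are ignored in the counts.
#'
#' @param aligned_segments Character vector of equal-length amino-acid
#'   strings (a pre-computed alignment; this package performs no MSA).
#' @param pseudocount Per-residue pseudocount (default 0).
#' @return An object of class `position_frequency_matrix`: list with
#'   `freq` (20 x L matrix, rows named by residue; columns sum to 1),
#'   `information` (length-L numeric, bits) and `n_sequences`.
#' @examples
#' pfm <- build_logo_matrix(c("CW", "CA"), pseudocount = 0)
#' pfm$information
#' @export
build_logo_matrix <- function(aligned_segments, pseudocount = 0) {
  if (!length(aligned_segments)) stop("need at least one segment")
  len <- unique(nchar(aligned_segments))
  if (length(len) != 1L)
    stop("segments are not aligned: lengths ",
         paste(sort(len), collapse = ", "))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  mat <- do.call(rbind, strsplit(toupper(aligned_segments), ""))
  freq <- matrix(0, nrow = 20L, ncol = len, dimnames = list(AA20, NULL))
  info <- numeric(len)
  for (j in seq_len(len)) {
    counts <- table(factor(mat[, j], levels = AA20))
    total <- sum(counts) + 20 * pseudocount
    if (total == 0) stop("alignment column ", j, " has no standard residues")
    p <- (as.numeric(counts) + pseudocount) / total
    freq[, j] <- p
    nz <- p > 0
    info[j] <- log2(20) + sum(p[nz] * log2(p[nz]))
  }
  structure(list(freq = freq, information = info,
                 n_sequences = length(aligned_segments)),
            class = "position_frequency_matrix")
}

#' @export
print.position_frequency_matrix <- function(x, ...) {
  cat("<position_frequency_matrix> ", ncol(x$freq), " columns, ",
      x$n_sequences, " sequences\n  total information ",
      round(sum(x$information), 2), " bits\n", sep = "")
  invisible(x)
}

#' Count conserved-cysteine columns of a logo matrix
#'
#' A column is a conserved cysteine if cysteine carries more than
#' `min_frac` of its frequency mass. This is the consensus-level reading of
#' "six conserved cysteines": individual repeats may lack a cysteine that
#' the domain consensus carries.
#'
#' @param pfm A `position_frequency_matrix`.
#' @param min_frac Majority threshold (default 0.5).
#' @return Integer count of C-majority columns.
#' @export
conserved_cysteine_count <- function(pfm, min_frac = 0.5) {
  sum(pfm$freq["C", ] > min_frac)
}

#' Write a logo matrix as TSV
#'
#' Columns: position, the 20 residue frequencies, information (bits).
#'
#' @param pfm A `position_frequency_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(pfm, path) {
  tab <- data.frame(position = seq_len(ncol(pfm$freq)),
                    t(pfm$freq), information = pfm$information,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot the information-content profile of a logo matrix
#'
#' A base-graphics bar profile of per-column information content, with
#' C-majority columns highlighted — a quick visual stand-in for a full
#' sequence logo.
#'
#' @param x A `position_frequency_matrix`.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @method plot position_frequency_matrix
#' @export
plot.position_frequency_matrix <- function(x, ...) {
  is_c <- x$freq["C", ] > 0.5
  graphics::barplot(x$information, names.arg = seq_len(ncol(x$freq)),
                    col = ifelse(is_c, "orange", "grey40"),
                    xlab = "alignment position",
                    ylab = "information (bits)", border = NA, ...)
}
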