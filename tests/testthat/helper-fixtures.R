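# Shared fixture builders. Everything is constructed in code at test time.

# A domain-hit row in the internal representation.
make_hit <- function(protein_id, domain_name, start, end,
                     i_evalue = 1e-20, bit_score = 100,
                     accession = "PF00000.1") {
  data.frame(protein_id = protein_id, domain_name = domain_name,
             accession = accession, i_evalue = i_evalue,
             start = as.integer(start), end = as.integer(end),
             bit_score = bit_score, stringsAsFactors = FALSE)
}

make_tm <- function(protein_id, start, end) {
  data.frame(protein_id = protein_id, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

# Write a minimal but field-complete domtblout file for given hits.
write_domtbl <- function(hits, path) {
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    tlen <- h$end - h$start + 1L
    sprintf(paste("%s %s %d %s - %d %.1e %.1f 0.1 1 1 %.1e %.1e %.1f 0.1",
                  "1 %d %d %d %d %d 0.90 -"),
            h$domain_name, h$accession, tlen, h$protein_id, 999L,
            h$i_evalue / 100, h$bit_score + 2, h$i_evalue / 10, h$i_evalue,
            h$bit_score, tlen, h$start, h$end, h$start, h$end)
  }, character(1))
  writeLines(c("# target name ...", rows), path)
  path
}

# Build an architecture directly from a layout specification:
# a character vector mixing "TM" and Pfam family names, laid out
# left-to-right; returns the build_architecture() product.
toy_arch <- function(layout, protein_id = "p1", protein_length = NULL,
                     config = pipeline_config()) {
  lens <- ifelse(layout == "TM", 23L, 50L)
  gap <- 15L
  starts <- 10L + c(0L, cumsum(head(lens, -1) + gap))
  ends <- starts + lens - 1L
  if (is.null(protein_length))
    protein_length <- max(160L, if (length(ends)) max(ends) + 20L else 0L)
  is_tm <- layout == "TM"
  hits <- if (any(!is_tm))
    make_hit(protein_id, layout[!is_tm], starts[!is_tm], ends[!is_tm])
  else NULL
  tms <- if (any(is_tm)) make_tm(protein_id, starts[is_tm], ends[is_tm])
         else NULL
  build_architecture(
    data.frame(id = protein_id, length = protein_length), hits, tms, config)
}

random_segment <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}
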