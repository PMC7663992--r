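#' Default Pfam-name vocabulary for receptor classification
#'
#' Maps Pfam family names onto the canonical display labels used in
#' arrangement strings and onto the concepts the classification rules test
#' (CD36, CTLD, SRCR, TSP1, ...). The mapping is deliberately editable:
#' classification rules are written against concepts, so adding a Pfam
#' family to a concept extends every rule that uses it. Pfam names absent
#' from the vocabulary keep their own name as label and concept `OTHER`.
#'
#' @return A data.frame with columns `pfam_name`, `label`, `concept`.
#' @export
default_domain_vocabulary <- function() {
  v <- rbind(
    c("CD36",         "CD36",          "CD36"),
    c("Lectin_C",     "CTLD",          "CTLD"),
    c("SRCR",         "SRCR",          "SRCR"),
    c("SRCR_2",       "SRCR",          "SRCR"),
    c("TSP_1",        "TSP1",          "TSP1"),
    c("TSP_3",        "TSP3",          "TSP3"),
    c("TSP_C",        "TSP_C",         "TSP_C"),
    c("Collagen",     "Collagen",      "COLLAGEN"),
    c("Collagen_mid", "Collagen",      "COLLAGEN"),
    c("Sema",         "SEMA",          "SEMA"),
    c("PLAC",         "PLAC",          "PLAC"),
    c("ADAM_spacer1", "ADAMTS-spacer", "ADAMTS_SPACER"),
    c("Reprolysin",   "Reprolysin",    "MP_CATALYTIC"),
    c("Pep_M12B_propep", "MP-propeptide", "MP_CATALYTIC"),
    c("EGF",          "EGF",           "EGF"),
    c("EGF_CA",       "EGF",           "EGF"),
    c("cEGF",         "EGF",           "EGF"),
    c("EGF_2",        "EGF",           "EGF"),
    c("VWA",          "VWA",           "OTHER"),
    c("I-set",        "I-set",         "OTHER"),
    c("ig",           "Ig",            "OTHER"),
    c("PSI",          "PSI",           "OTHER"),
    c("UNC-5",        "UNC-5",         "OTHER"),
    c("CUB",          "CUB",           "OTHER"),
    c("Ldl_recept_a", "LDL",           "OTHER")
  )
  data.frame(pfam_name = v[, 1], label = v[, 2], concept = v[, 3],
             stringsAsFactors = FALSE)
}

#' Read a domain vocabulary from a TSV file
#'
#' @param path TSV with columns pfam_name, label, concept (header required).
#' @return A vocabulary data.frame as from [default_domain_vocabulary()].
#' @export
read_domain_vocabulary <- function(path) {
  v <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("pfam_name", "label", "concept")
  if (!all(need %in% names(v)))
    stop("vocabulary file must have columns: ", paste(need, collapse = ", "))
  v[need]
}

# Map Pfam names to (label, concept); unmapped names pass through as OTHER.
map_domain_vocabulary <- function(domain_names, vocabulary) {
  i <- match(domain_names, vocabulary$pfam_name)
  label <- ifelse(is.na(i), domain_names, vocabulary$label[i])
  concept <- ifelse(is.na(i), "OTHER", vocabulary$concept[i])
  list(label = label, concept = concept)
}
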