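#' Receptor categories
#'
#' The closed set of categories the classifier can assign: four scavenger
#' receptor classes (SR-A, SR-B, SR-E-like, SR-I), the C-type lectin and
#' SRCR catch-all groups, the thrombospondin-superfamily groups
#' (thrombospondin/COMP, ADAMTS-like, semaphorin/plexin, TSP1-only proteins
#' with and without a transmembrane region, TSP1 mixed with other domains),
#' and `unclassified`. Only "SR-E-like" is ever emitted for single-CTLD
#' membrane proteins: calling a protein SR-E proper requires experimentally
#' demonstrated scavenging activity, which annotation cannot establish.
#'
#' @return Character vector of category names, in classification precedence
#'   order (terminated by `unclassified`).
#' @export
receptor_categories <- function() {
  c("SR_A", "SR_B", "SR_E_like", "SR_I", "C_type_lectin", "SRCR_member",
    "TSP_COMP", "ADAMTS_like", "semaphorin_plexin", "TSR_withTM",
    "TSR_noTM", "TSR_other", "unclassified")
}

#' Default receptor classification rule set
#'
#' An ordered list of rules, evaluated first-match-wins, written against the
#' concept labels of [default_domain_vocabulary()]. SR rules come before TSR
#' rules and specific rules before generic ones, so e.g. a protein with one
#' CTLD and a TM is SR-E-like, never a generic C-type lectin, and a protein
#' with two SRCR domains and a TM is SR-I, never a generic SRCR member.
#'
#' The rules, in order:
#' 1. `SR_A` — collagen domain, C-terminal SRCR domain, >= 1 TM.
#' 2. `SR_B` — a CD36 domain as an extracellular loop flanked by two TMs
#'    (one TM starting before and one ending after the CD36 domain, with no
#'    other Pfam domain between either TM and the CD36 domain).
#' 3. `SR_E_like` — exactly one CTLD in the protein plus exactly one TM
#'    ("a transmembrane region with a single C-type lectin domain"; a single
#'    CTLD flanked by two TMs is a generic C-type lectin, not SR-E-like).
#' 4. `SR_I` — two or more SRCR domains plus >= 1 TM.
#' 5. `C_type_lectin` — >= 1 CTLD and >= 1 TM, not assignable to SR-E-like.
#' 6. `SRCR_member` — >= 1 SRCR domain, not assignable to an SR class.
#' 7. `TSP_COMP` — thrombospondin C-terminal region: type-3 repeats plus the
#'    C-terminal lectin-like domain (repeat counts in domain tables are
#'    fragmentary, so no fixed repeat number is required).
#' 8. `ADAMTS_like` — >= 1 TSP1 together with an ADAMTS spacer,
#'    metalloproteinase-family domain or PLAC domain; an ADAMTS spacer with
#'    no TSP1 also matches and is flagged "no TSP1" in the matched rule.
#' 9. `semaphorin_plexin` — a Sema domain is present.
#' 10. `TSR_withTM` — only TSP1 Pfam domains, with >= 1 TM.
#' 11. `TSR_noTM` — only TSP1 Pfam domains, no TM (properdin-like).
#' 12. `TSR_other` — >= 1 TSP1 mixed with other domains.
#' 13. `unclassified` — nothing above matched.
#'
#' @return A list of rules of class `receptor_ruleset`; each rule has
#'   `category`, `name` and `matches(elements)`.
#' @export
default_ruleset <- function() {
  n_of <- function(el, concept)
    sum(el$kind == "pfam_domain" & el$concept == concept)
  n_tm <- function(el) sum(el$kind == "tm")
  pfam <- function(el) el[el$kind == "pfam_domain", , drop = FALSE]

  cd36_flanked <- function(el) {
    cd <- which(el$kind == "pfam_domain" & el$concept == "CD36")
    tm <- which(el$kind == "tm")
    if (!length(cd) || length(tm) < 2L) return(FALSE)
    dom <- which(el$kind == "pfam_domain")
    for (i in cd) {
      before <- tm[el$start[tm] < el$start[i]]
      after <- tm[el$end[tm] > el$end[i]]
      ok_before <- any(vapply(before, function(t) {
        gap <- setdiff(dom, i)
        !any(el$end[gap] > el$end[t] & el$start[gap] < el$start[i])
      }, logical(1)))
      ok_after <- any(vapply(after, function(t) {
        gap <- setdiff(dom, i)
        !any(el$start[gap] < el$start[t] & el$end[gap] > el$end[i])
      }, logical(1)))
      if (ok_before && ok_after) return(TRUE)
    }
    FALSE
  }

  only_tsp1 <- function(el) {
    p <- pfam(el)
    nrow(p) >= 1L && all(p$concept == "TSP1")
  }

  rule <- function(category, name, matches)
    list(category = category, name = name, matches = matches)

  rules <- list(
    rule("SR_A", "collagen + C-terminal SRCR + TM", function(el) {
      p <- pfam(el)
      n_tm(el) >= 1L && n_of(el, "COLLAGEN") >= 1L && n_of(el, "SRCR") >= 1L &&
        nrow(p) >= 1L && p$concept[which.max(p$start)] == "SRCR"
    }),
    rule("SR_B", "CD36 loop flanked by two TMs", cd36_flanked),
    rule("SR_E_like", "single CTLD + single TM", function(el)
      n_of(el, "CTLD") == 1L && n_tm(el) == 1L),
    rule("SR_I", "multiple SRCR + TM", function(el)
      n_of(el, "SRCR") >= 2L && n_tm(el) >= 1L),
    rule("C_type_lectin", "CTLD(s) + TM, not SR-E-like", function(el)
      n_of(el, "CTLD") >= 1L && n_tm(el) >= 1L),
    rule("SRCR_member", "SRCR domain(s), not an SR class", function(el)
      n_of(el, "SRCR") >= 1L),
    rule("TSP_COMP", "TSP3 repeats + C-terminal lectin-like domain",
         function(el) n_of(el, "TSP3") >= 1L && n_of(el, "TSP_C") >= 1L),
    rule("ADAMTS_like", "TSP1 + ADAMTS spacer/metalloproteinase/PLAC",
         function(el) {
           anchor <- n_of(el, "ADAMTS_SPACER") >= 1L ||
             n_of(el, "MP_CATALYTIC") >= 1L || n_of(el, "PLAC") >= 1L
           (n_of(el, "TSP1") >= 1L && anchor) || n_of(el, "ADAMTS_SPACER") >= 1L
         }),
    rule("semaphorin_plexin", "Sema domain present", function(el)
      n_of(el, "SEMA") >= 1L),
    rule("TSR_withTM", "only TSP1 domains + TM", function(el)
      only_tsp1(el) && n_tm(el) >= 1L),
    rule("TSR_noTM", "only TSP1 domains, no TM (properdin-like)", function(el)
      only_tsp1(el) && n_tm(el) == 0L),
    rule("TSR_other", "TSP1 mixed with other domains", function(el)
      n_of(el, "TSP1") >= 1L)
  )
  class(rules) <- "receptor_ruleset"
  rules
}

#' Classify one domain architecture
#'
#' Evaluates the ordered rule set against the architecture's elements; the
#' first matching rule assigns the category. An ADAMTS spacer with no TSP1
#' domain is reported as `ADAMTS_like` with `"(no TSP1)"` appended to the
#' matched rule.
#'
#' @param arch A `domain_architecture` (see [build_architecture()]).
#' @param rules A rule set from [default_ruleset()].
#' @return A one-row data.frame with `protein_id`, `category`,
#'   `matched_rule`, `arrangement_string`.
#' @examples
#' cfg <- pipeline_config()
#' prot <- data.frame(id = "p1", length = 500)
#' hits <- data.frame(protein_id = "p1", domain_name = "CD36",
#'                    accession = "PF01130.21", i_evalue = 1e-30,
#'                    start = 40, end = 380, bit_score = 200)
#' tms <- data.frame(protein_id = "p1", start = c(5, 390), end = c(27, 412))
#' classify(build_architecture(prot, hits, tms, cfg))$category
#' @export
classify <- function(arch, rules = default_ruleset()) {
  el <- arch$elements
  category <- "unclassified"
  matched <- ""
  for (r in rules) {
    if (isTRUE(r$matches(el))) {
      category <- r$category
      matched <- r$name
      if (category == "ADAMTS_like" &&
          !any(el$kind == "pfam_domain" & el$concept == "TSP1"))
        matched <- paste(matched, "(no TSP1)")
      break
    }
  }
  data.frame(protein_id = arch$protein_id, category = category,
             matched_rule = matched,
             arrangement_string = arch$arrangement_string,
             stringsAsFactors = FALSE)
}

#' Classify a set of architectures
#'
#' @param archs A list of `domain_architecture` objects.
#' @param rules A rule set from [default_ruleset()].
#' @return A list with `assignments` (one row per architecture) and
#'   `counts` (named integer vector over all categories; sums to
#'   `length(archs)`).
#' @export
classify_all <- function(archs, rules = default_ruleset()) {
  if (!length(archs)) {
    assignments <- data.frame(protein_id = character(),
                              category = character(),
                              matched_rule = character(),
                              arrangement_string = character(),
                              stringsAsFactors = FALSE)
  } else {
    assignments <- do.call(rbind, lapply(archs, classify, rules = rules))
    rownames(assignments) <- NULL
  }
  counts <- table(factor(assignments$category, levels = receptor_categories()))
  list(assignments = assignments,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Write receptor assignments to TSV
#'
#' @param assignments Assignment data frame from [classify_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
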