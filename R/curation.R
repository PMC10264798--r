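# Explicit recuration rules: origin assignment, pathogenicity
# reclassification and population-frequency classification. These
# encode the catalog's stated curation decisions, not a general ACMG
# engine; the rule set is small, ordered and config-extensible.

.PATHO_LEVELS <- c(B = 1L, LB = 2L, VUS = 3L, LP = 4L, P = 5L)

# Normalize free-text reported significance to {B, LB, VUS, LP, P, NA}.
# Combined labels ("Pathogenic/Likely pathogenic") map to the more
# severe class.
.norm_patho <- function(x) {
  if (length(x) != 1 || is.na(x) || !nzchar(trimws(x))) return(NA_character_)
  t <- tolower(trimws(x))
  exact <- c(p = "P", pathogenic = "P", lp = "LP", `likely pathogenic` = "LP",
             vus = "VUS", `uncertain significance` = "VUS",
             `variant of uncertain significance` = "VUS",
             `variant of unknown significance` = "VUS",
             lb = "LB", `likely benign` = "LB", b = "B", benign = "B")
  if (t %in% names(exact)) return(unname(exact[t]))
  # merged multi-source values ("LP|P"): most severe mentioned class
  parts <- trimws(strsplit(t, "|", fixed = TRUE)[[1]])
  if (length(parts) > 1) {
    cls <- vapply(parts, .norm_patho, character(1))
    cls <- cls[!is.na(cls)]
    if (!length(cls)) return(NA_character_)
    return(names(.PATHO_LEVELS)[max(.PATHO_LEVELS[cls])])
  }
  if (grepl("conflict", t)) return("VUS")
  # free text: "pathogenic/likely pathogenic" keeps the more severe
  if (grepl("pathogenic", t) && grepl("likely pathogenic", t) &&
      !startsWith(t, "likely")) return("P")
  if (grepl("likely pathogenic", t)) return("LP")
  if (grepl("pathogenic", t)) return("P")
  if (grepl("uncertain|unknown", t)) return("VUS")
  if (grepl("likely benign", t)) return("LB")
  if (grepl("benign", t)) return("B")
  NA_character_
}

#' Assign variant origin from reported text and trio availability
#'
#' A de novo or inherited origin is accepted only when the source
#' states it *and* trio (proband plus both parents) sequencing backs
#' it; without trio confirmation the origin is `unknown`.
#'
#' @param origin_raw Reported origin text (may be `NA`/empty; merged
#'   multi-source values separated by `|` are accepted).
#' @param trio_available Logical: trio confirmation available.
#' @return `"de_novo"`, `"inherited"` or `"unknown"`.
#' @export
assign_origin <- function(origin_raw, trio_available) {
  if (!isTRUE(trio_available)) return("unknown")
  if (is.na(origin_raw) || !nzchar(trimws(origin_raw))) return("unknown")
  t <- .norm_text(origin_raw)
  if (grepl("\\bde novo\\b|\\bdenovo\\b|\\bdnm\\b", t)) return("de_novo")
  if (grepl("maternal|paternal|inherited|familial|transmitted", t)) return("inherited")
  "unknown"
}

.decision_row <- function(field, before, after, rule_id, rationale) {
  data.frame(field = field,
             before = ifelse(is.na(before), "", before),
             after = after, rule_id = rule_id, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' Reclassify pathogenicity of a canonical variant
#'
#' Ordered rules (every change is logged as a decision):
#' \describe{
#'   \item{R1}{Synonymous variants are excluded from the catalog
#'     (`EXCLUDED`): a synonymous CTCF change is not credibly
#'     pathogenic.}
#'   \item{R2}{A missense change at a zinc-coordinating Cys/His is at
#'     least likely pathogenic (`LP`); a reported `P` is retained.}
#'   \item{R3}{A missense change reported benign/likely benign but
#'     carried by an NDD phenotype is reclassified `VUS`.}
#'   \item{R4}{Variants with no reported class default to `VUS`
#'     (unless R2 applies).}
#' }
#' Reported classes are otherwise retained; rules never downgrade
#' (severity order P > LP > VUS > LB > B) and the mapping is
#' idempotent.
#'
#' @param klass Consequence class (e.g. `"missense"`, `"synonymous"`).
#' @param phenotype_category Phenotype category from
#'   [classify_phenotype()].
#' @param residue_role Residue role from [residue_role()] (may be `NA`).
#' @param reported_class Reported significance text (may be `NA`).
#' @return List with `class` (one of B, LB, VUS, LP, P, EXCLUDED) and
#'   `decisions` (`data.frame`, one row per applied change).
#' @export
reclassify_pathogenicity <- function(klass, phenotype_category = "UNKNOWN",
                                     residue_role = NA_character_,
                                     reported_class = NA_character_) {
  reported <- .norm_patho(reported_class)
  decisions <- .decision_row(character(), character(), character(),
                             character(), character())[0, ]
  if (identical(klass, "synonymous")) {
    decisions <- rbind(decisions, .decision_row(
      "catalog_membership", reported, "EXCLUDED", "R1",
      "synonymous variant removed from the nonsynonymous catalog"))
    return(list(class = "EXCLUDED", decisions = decisions))
  }
  current <- reported
  coord <- identical(klass, "missense") &&
    !is.na(residue_role) &&
    residue_role %in% c("zinc_coordinating_cys", "zinc_coordinating_his")
  if (coord && (is.na(current) || .PATHO_LEVELS[current] < .PATHO_LEVELS["LP"])) {
    decisions <- rbind(decisions, .decision_row(
      "pathogenicity", current, "LP", "R2",
      "missense at a zinc-coordinating residue is at least likely pathogenic"))
    current <- "LP"
  } else if (!coord && !is.na(current) && current %in% c("LB", "B") &&
             identical(klass, "missense") && is_ndd(phenotype_category)) {
    decisions <- rbind(decisions, .decision_row(
      "pathogenicity", current, "VUS", "R3",
      "benign-reported missense with an NDD phenotype reclassified as VUS"))
    current <- "VUS"
  }
  if (is.na(current)) {
    decisions <- rbind(decisions, .decision_row(
      "pathogenicity", NA_character_, "VUS", "R4",
      "no reported class; defaulting to VUS"))
    current <- "VUS"
  }
  list(class = current, decisions = decisions)
}

#' Classify population allele frequency as rare or common
#'
#' Rare is defined strictly as allele frequency below 0.05; the
#' boundary value 0.05 is common.
#'
#' @param af Allele fraction(s) in `[0, 1]`.
#' @return Character vector, `"rare"` or `"common"` (`NA` in, `NA` out).
#' @export
classify_af <- function(af) {
  bad <- !is.na(af) & (af < 0 | af > 1)
  if (any(bad)) stop("allele frequency outside [0, 1]: ", af[which(bad)[1]])
  ifelse(is.na(af), NA_character_, ifelse(af < 0.05, "rare", "common"))
}
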