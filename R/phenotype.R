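# Rule-based classification of free-text reported conditions into the
# phenotype categories used for NDD association.

.PHENO_CATEGORIES <- c("CRD", "ASD", "EP", "ID", "DD", "IGD", "ANS",
                       "NON_NDD", "CONTROL")

# Matching is normalized-substring based: lowercase, punctuation
# stripped, whitespace collapsed, then word-boundary regex search.
.norm_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Default phenotype terminology rules
#'
#' The screening terminology: CTCF-related disorder and its legacy
#' synonyms ("Mental retardation, autosomal dominant 21", "MRD21"),
#' the qualifying NDD diagnoses (ASD, EP, ID, DD, IGD, abnormality of
#' the nervous system), the non-NDD exclusion phenotypes (mammary
#' neoplasms/breast cancer, acute megakaryoblastic leukemia, congenital
#' diaphragmatic hernia) and control-cohort markers. Priority (lower
#' wins) encodes diagnostic specificity: CRD > ASD > EP > ID > DD >
#' IGD > ANS > NON_NDD > CONTROL; the order is config-overridable.
#'
#' @return Rule `data.frame` with columns `pattern`, `category`,
#'   `priority`, `regex`.
#' @export
phenotype_rules <- function() {
  rule <- function(patterns, category, priority) {
    data.frame(pattern = patterns, category = category, priority = priority,
               regex = FALSE, stringsAsFactors = FALSE)
  }
  rbind(
    rule(c("ctcf related neurodevelopmental disorder",
           "ctcf related disorder", "crd",
           "mental retardation autosomal dominant 21", "mrd21",
           "intellectual disability feeding difficulties developmental delay microcephaly"),
         "CRD", 1L),
    rule(c("autism spectrum disorder", "autism", "autistic behavior",
           "autistic disorder", "asd", "asperger"), "ASD", 2L),
    rule(c("epilepsy", "epileptic encephalopathy", "seizure", "seizures"),
         "EP", 3L),
    rule(c("intellectual disability", "intellectual developmental disorder",
           "mental retardation"), "ID", 4L),
    rule(c("developmental disorder", "developmental delay",
           "global developmental delay", "developmental disability",
           "neurodevelopmental delay", "neurodevelopmental disorder"),
         "DD", 5L),
    rule(c("inborn genetic disease", "inborn genetic diseases"), "IGD", 6L),
    rule(c("abnormality of the nervous system",
           "congenital nervous system disorder",
           "nervous system abnormality"), "ANS", 7L),
    rule(c("mammary neoplasm", "mammary neoplasms", "breast cancer",
           "acute megakaryoblastic leukemia", "congenital diaphragmatic hernia",
           "neoplasm", "carcinoma", "cancer"), "NON_NDD", 8L),
    rule(c("detected in controls", "control cohort", "control", "controls",
           "unaffected"), "CONTROL", 9L)
  )
}

#' Load phenotype rules from a config table or file
#'
#' @param config `NULL` for the defaults, a `data.frame` with columns
#'   `pattern`, `category`, `priority` (optional `regex`), or a path to
#'   a TSV with those columns. An empty table yields an empty rule set
#'   (everything classifies as `UNKNOWN`).
#' @return Validated rule `data.frame`.
#' @export
load_phenotype_rules <- function(config = NULL) {
  rules <- if (is.null(config)) {
    phenotype_rules()
  } else if (is.character(config)) {
    utils::read.delim(config, stringsAsFactors = FALSE)
  } else {
    as.data.frame(config)
  }
  if (!nrow(rules)) {
    return(data.frame(pattern = character(), category = character(),
                      priority = integer(), regex = logical()))
  }
  stopifnot(all(c("pattern", "category", "priority") %in% names(rules)))
  if (!"regex" %in% names(rules)) rules$regex <- FALSE
  if (any(!nzchar(rules$pattern))) stop("phenotype rule patterns must be nonempty")
  if (any(!rules$category %in% .PHENO_CATEGORIES)) {
    stop("unknown phenotype category in rules: ",
         paste(setdiff(rules$category, .PHENO_CATEGORIES), collapse = ", "))
  }
  norm <- ifelse(rules$regex, rules$pattern, .norm_text(rules$pattern))
  dup <- duplicated(norm) | duplicated(norm, fromLast = TRUE)
  if (any(dup)) {
    clash <- tapply(rules$category[dup], norm[dup], function(x) length(unique(x)) > 1)
    if (any(clash)) {
      stop("conflicting phenotype rules: pattern(s) ",
           paste(names(clash)[clash], collapse = ", "),
           " mapped to multiple categories")
    }
  }
  rules
}

#' Classify reported phenotype texts
#'
#' All matching rules across all texts are collected; the final
#' category is the highest-priority (lowest number) match. Matching is
#' case-insensitive, punctuation-insensitive and invariant under
#' permutation of the input texts.
#'
#' @param texts Character vector of reported conditions (a single
#'   record's phenotype strings). `NULL`, empty, or all-blank input
#'   yields `NO_PHENOTYPE_DATA`; nonempty text matching no rule yields
#'   `UNKNOWN`.
#' @param rules Rule set from [load_phenotype_rules()].
#' @return List with `category` and `matched` (the matching patterns).
#' @export
classify_phenotype <- function(texts, rules = load_phenotype_rules()) {
  texts <- texts[!is.na(texts)]
  texts <- texts[nzchar(trimws(texts))]
  if (!length(texts)) return(list(category = "NO_PHENOTYPE_DATA", matched = character()))
  if (!nrow(rules)) return(list(category = "UNKNOWN", matched = character()))
  norm <- .norm_text(texts)
  hit <- logical(nrow(rules))
  for (j in seq_len(nrow(rules))) {
    pat <- if (isTRUE(rules$regex[j])) rules$pattern[j] else
      paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                         .norm_text(rules$pattern[j])), "\\b")
    hit[j] <- any(grepl(pat, norm, perl = TRUE))
  }
  if (!any(hit)) return(list(category = "UNKNOWN", matched = character()))
  best <- min(rules$priority[hit])
  cats <- unique(rules$category[hit & rules$priority == best])
  list(category = cats[1], matched = rules$pattern[hit])
}

#' Does a phenotype category qualify as NDD?
#'
#' True exactly for CRD, ASD, DD, EP, ID, IGD and ANS; false for
#' NON_NDD, CONTROL, UNKNOWN and NO_PHENOTYPE_DATA (records without
#' phenotype data do not qualify).
#'
#' @param category Category string(s).
#' @return Logical vector.
#' @export
is_ndd <- function(category) {
  category %in% c("CRD", "ASD", "DD", "EP", "ID", "IGD", "ANS")
}
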