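# Final catalog assembly and paper-style tidy summary tables.

#' Round half away from zero
#'
#' Integer-percentage convention used throughout the catalog tables
#' (base `round()` rounds half to even, which prints 0.5 as 0).
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a fraction as an integer percentage
#'
#' @param num,den Numerator and denominator (or pass a fraction as
#'   `num` with `den = 1`).
#' @return Character, e.g. `format_percent(149, 225)` is `"66%"`.
#' @export
format_percent <- function(num, den = 1) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n); den <- rep_len(den, n)
  out <- paste0(round_half_up(100 * num / den), "%")
  out[den == 0] <- NA_character_
  out
}

#' Assemble the final catalog bundle
#'
#' Runs the per-variant annotation stages over a deduplicated catalog —
#' phenotype classification, consequence calling, origin assignment and
#' pathogenicity recuration — and assembles the catalog bundle: the
#' exonic NDD catalog (region `exonic_cds`, not `EXCLUDED`,
#' NDD-associated), the full unfiltered companion table, the noncoding
#' table, counts at each filter step, the decisions log and an audit
#' trail. Every ingested record is accounted for in exactly one of a
#' catalog row's provenance or an exclusion with reason (the
#' conservation invariant, asserted).
#'
#' @param dedup Result of [deduplicate()].
#' @param model GRCh37 [transcript_model()] with `cds_sequence`.
#' @param domains Optional [domain_map()] for residue-role annotation.
#' @param rules Phenotype rules from [load_phenotype_rules()].
#' @param excluded Optional exclusion `data.frame`s (from
#'   [ingest_source()] / [standardize_records()]) appended to the audit
#'   log and counted in the conservation check.
#' @param n_source_records Optional total number of ingested source
#'   rows; when given, the conservation invariant
#'   `n_source_records = n_records + n_excluded` is asserted.
#' @return A `catalog_bundle` list: `full`, `exonic_ndd_catalog`,
#'   `noncoding_table`, `filter_steps`, `decisions`, `audit`,
#'   `conservation`.
#' @export
build_catalog <- function(dedup, model, domains = NULL,
                          rules = load_phenotype_rules(), excluded = NULL,
                          n_source_records = NULL) {
  cat0 <- dedup$catalog
  n <- nrow(cat0)
  full <- cat0
  full$phenotype_category <- full$klass <- full$hgvs_p <-
    full$domain_label <- full$residue_role <- full$origin <-
    full$curated_class <- full$af_class <- NA_character_
  full$residue <- NA_integer_
  full$ndd <- FALSE
  decisions <- NULL
  for (i in seq_len(n)) {
    texts <- if (is.na(cat0$phenotype[i])) character(0) else
      strsplit(cat0$phenotype[i], ";", fixed = TRUE)[[1]]
    ph <- classify_phenotype(texts, rules)
    v <- parse_c(cat0$hgvs_c[i])
    cc <- call_consequence(model, v, domains)
    full$phenotype_category[i] <- ph$category
    full$ndd[i] <- is_ndd(ph$category)
    full$klass[i] <- cc$klass
    full$hgvs_p[i] <- if (is.null(cc$hgvs_p)) NA_character_ else cc$hgvs_p
    full$domain_label[i] <- if (is.null(cc$domain_label)) NA_character_ else cc$domain_label
    full$residue_role[i] <- if (is.null(cc$residue_role)) NA_character_ else cc$residue_role
    full$residue[i] <- if (is.null(cc$protein_change)) NA_integer_ else
      cc$protein_change$first_residue
    full$origin[i] <- assign_origin(cat0$origin_raw[i], cat0$trio[i])
    rc <- reclassify_pathogenicity(cc$klass, ph$category,
                                   full$residue_role[i],
                                   cat0$reported_class[i])
    full$curated_class[i] <- rc$class
    full$af_class[i] <- classify_af(cat0$af[i])
    if (nrow(rc$decisions)) {
      d <- rc$decisions
      d$key <- cat0$key[i]
      decisions <- rbind(decisions, d)
    }
  }
  if (is.null(decisions)) {
    decisions <- data.frame(field = character(), before = character(),
                            after = character(), rule_id = character(),
                            rationale = character(), key = character(),
                            stringsAsFactors = FALSE)
  }
  exonic <- full[full$region == "exonic_cds", , drop = FALSE]
  nonsyn <- exonic[exonic$curated_class != "EXCLUDED", , drop = FALSE]
  ndd_catalog <- nonsyn[nonsyn$ndd, , drop = FALSE]
  noncoding <- full[full$region != "exonic_cds", , drop = FALSE]
  filter_steps <- data.frame(
    step = c("distinct_variants", "exonic_cds", "non_excluded_nonsynonymous",
             "ndd_associated"),
    n = c(n, nrow(exonic), nrow(nonsyn), nrow(ndd_catalog)),
    stringsAsFactors = FALSE)
  excluded <- if (is.null(excluded)) .empty_exclusions() else
    do.call(rbind, c(list(.empty_exclusions()),
                     if (is.data.frame(excluded)) list(excluded) else excluded))
  n_excl <- nrow(excluded)
  conservation <- list(
    n_records = dedup$stats$n_records,
    n_distinct = dedup$stats$n_distinct,
    n_duplicate_records = dedup$stats$n_duplicate_records,
    n_excluded = n_excl,
    n_source_records = n_source_records,
    ok = dedup$stats$n_records ==
      dedup$stats$n_distinct + dedup$stats$n_duplicate_records &&
      (is.null(n_source_records) ||
         n_source_records == dedup$stats$n_records + n_excl))
  if (!conservation$ok) {
    stop("record conservation violated: ", dedup$stats$n_records,
         " records != ", dedup$stats$n_distinct, " distinct + ",
         dedup$stats$n_duplicate_records, " duplicates (+ ", n_excl,
         " excluded of ",
         if (is.null(n_source_records)) "?" else n_source_records,
         " source rows)")
  }
  audit <- rbind(
    excluded,
    if (nrow(full)) data.frame(source = "catalog", record_id = full$key,
                               reason = "retained", stringsAsFactors = FALSE))
  structure(list(full = full, exonic_ndd_catalog = ndd_catalog,
                 noncoding_table = noncoding, filter_steps = filter_steps,
                 decisions = decisions, audit = audit,
                 conservation = conservation),
            class = "catalog_bundle")
}

#' @export
print.catalog_bundle <- function(x, ...) {
  fs <- x$filter_steps
  cat("Catalog bundle:", fs$n[fs$step == "distinct_variants"],
      "distinct variants;", nrow(x$exonic_ndd_catalog),
      "in the exonic NDD catalog;", nrow(x$noncoding_table),
      "noncoding\n")
  invisible(x)
}

.prop_table <- function(x, name) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    out <- data.frame(v = character(), n = integer(), fraction = numeric(),
                      pct = character(), stringsAsFactors = FALSE)
    names(out)[1] <- name
    return(out)
  }
  t <- as.data.frame(table(x), stringsAsFactors = FALSE)
  names(t) <- c(name, "n")
  t <- t[order(-t$n, t[[1]]), , drop = FALSE]
  t$fraction <- t$n / sum(t$n)
  t$pct <- format_percent(t$n, sum(t$n))
  rownames(t) <- NULL
  t
}

#' Tidy summary tables for a catalog bundle
#'
#' The figure-style views as plain data: phenotype proportions among
#' exonic variants, consequence classes / origin / curated
#' pathogenicity among the exonic NDD catalog, per-domain mutational
#' burden, and a per-residue lollipop table. Raw fractions accompany
#' every integer percentage.
#'
#' @param bundle A `catalog_bundle` from [build_catalog()].
#' @param domains Optional [domain_map()] for the burden table.
#' @return Named list of `data.frame`s: `phenotype`, `consequence`,
#'   `origin`, `pathogenicity`, `domain_burden`, `lollipop`,
#'   `ndd_share`.
#' @export
summarize_catalog <- function(bundle, domains = NULL) {
  exonic <- bundle$full[bundle$full$region == "exonic_cds", , drop = FALSE]
  ndd <- bundle$exonic_ndd_catalog
  phenotype <- .prop_table(exonic$phenotype_category, "category")
  consequence <- .prop_table(ndd$klass, "klass")
  origin <- .prop_table(ndd$origin, "origin")
  pathogenicity <- .prop_table(ndd$curated_class, "class")
  n_ndd_all <- sum(is_ndd(exonic$phenotype_category))
  ndd_share <- data.frame(n_ndd = n_ndd_all, n_exonic = nrow(exonic),
                          fraction = if (nrow(exonic)) n_ndd_all / nrow(exonic) else NA_real_,
                          pct = format_percent(n_ndd_all, nrow(exonic)),
                          stringsAsFactors = FALSE)
  coding <- ndd[!is.na(ndd$residue), , drop = FALSE]
  lollipop <- coding[order(coding$residue),
                     c("residue", "hgvs_p", "klass", "curated_class",
                       "phenotype_category", "domain_label"), drop = FALSE]
  rownames(lollipop) <- NULL
  domain_burden <- if (!is.null(domains)) {
    lab <- vapply(coding$residue, function(r) domain_of(domains, r), character(1))
    t <- .prop_table(lab, "domain")
    all_labels <- unique(c(domains$entries$label, "linker"))
    missing <- setdiff(all_labels, t$domain)
    if (length(missing)) {
      t <- rbind(t, data.frame(domain = missing, n = 0L, fraction = 0,
                               pct = "0%", stringsAsFactors = FALSE))
    }
    t
  } else {
    .prop_table(coding$domain_label, "domain")
  }
  list(phenotype = phenotype, consequence = consequence, origin = origin,
       pathogenicity = pathogenicity, domain_burden = domain_burden,
       lollipop = lollipop, ndd_share = ndd_share)
}

#' Write a catalog bundle as TSV files
#'
#' Deterministic text outputs (stable column order, no timestamps):
#' fixed inputs give byte-identical files.
#'
#' @param bundle A `catalog_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_catalog <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c(full = "catalog_full.tsv",
           exonic_ndd_catalog = "catalog_exonic_ndd.tsv",
           noncoding_table = "catalog_noncoding.tsv",
           filter_steps = "filter_steps.tsv",
           decisions = "decisions.tsv", audit = "audit.tsv")
  paths <- file.path(dir, out)
  names(paths) <- names(out)
  for (nm in names(out)) {
    utils::write.table(bundle[[nm]], paths[nm], sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(paths)
}
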