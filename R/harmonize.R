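# Multi-source ingestion, GRCh37/HGVS standardization, canonical keys
# and cross-source deduplication with provenance.

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
}

#' Registered source schema dialects
#'
#' Each genotype-phenotype database exports a different tabular schema;
#' a dialect maps its columns onto the standard record fields. Adding a
#' database is a config-only change: pass extra dialects to
#' [ingest_source()] via `dialects`.
#'
#' @return Named list of dialect descriptions (separator, column map,
#'   phenotype separator).
#' @export
schema_dialects <- function() {
  list(
    clinvar_like = list(
      sep = "\t", phen_sep = ";",
      cols = c(record_id = "VariationID", assembly = "Assembly",
               chrom = "Chromosome", pos = "Start", ref = "ReferenceAllele",
               alt = "AlternateAllele", hgvs_c = "HGVS_c",
               phenotype = "PhenotypeList", origin = "Origin",
               trio = "TrioConfirmed", pathogenicity = "ClinicalSignificance",
               af = "AlleleFrequency")),
    decipher_like = list(
      sep = ",", phen_sep = "|",
      cols = c(record_id = "variant_id", assembly = "genome_build",
               chrom = "chr", pos = "start", ref = "ref_allele",
               alt = "alt_allele", hgvs_c = "hgvs",
               phenotype = "phenotypes", origin = "inheritance",
               trio = "trio", pathogenicity = "pathogenicity",
               af = "allele_frequency")),
    denovo_like = list(
      sep = "\t", phen_sep = ";",
      cols = c(record_id = "SampleID", assembly = "Build", chrom = "Chr",
               pos = "Position", ref = "Ref", alt = "Alt",
               hgvs_c = "cDnaVariant", phenotype = "PrimaryPhenotype",
               origin = "Validation", trio = "Trio",
               pathogenicity = "Significance", af = "Frequency")),
    generic_tsv = list(
      sep = "\t", phen_sep = ";",
      cols = c(record_id = "record_id", assembly = "assembly",
               chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
               hgvs_c = "hgvs_c", phenotype = "phenotype", origin = "origin",
               trio = "trio", pathogenicity = "reported_class", af = "af"))
  )
}

.empty_records <- function() {
  data.frame(source = character(), record_id = character(),
             assembly = character(), chrom = character(), pos = numeric(),
             ref = character(), alt = character(), hgvs_c = character(),
             variant_class = character(), phenotype = character(),
             origin_raw = character(), trio = logical(),
             reported_class = character(), af = numeric(),
             stringsAsFactors = FALSE)
}

.empty_exclusions <- function() {
  data.frame(source = character(), record_id = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Ingest one source export
#'
#' Reads a TSV/CSV export in a registered schema dialect (or a VCF) and
#' maps it onto standard source-record fields. Rows carrying neither
#' genomic coordinates nor an HGVS c. description are excluded with
#' reason `"ambiguous"`.
#'
#' @param path File path.
#' @param schema Dialect name (see [schema_dialects()]) or `"vcf"`.
#' @param source_name Database name recorded as provenance.
#' @param dialects Dialect registry, default [schema_dialects()].
#' @param assembly Assembly assumed for VCF input (default `"GRCh37"`).
#' @return List with `records` (standard-field `data.frame`) and
#'   `excluded` (`data.frame` of record_id/reason).
#' @export
ingest_source <- function(path, schema, source_name = schema,
                          dialects = schema_dialects(), assembly = "GRCh37") {
  if (identical(schema, "vcf")) return(.ingest_vcf(path, source_name, assembly))
  if (!schema %in% names(dialects)) {
    stop("unknown schema dialect '", schema, "'")
  }
  d <- dialects[[schema]]
  raw <- utils::read.table(path, sep = d$sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = NULL)
  cols <- d$cols
  has_coords_cols <- all(cols[c("chrom", "pos", "ref", "alt")] %in% names(raw))
  has_hgvs_col <- cols[["hgvs_c"]] %in% names(raw)
  if (!has_coords_cols && !has_hgvs_col) {
    stop("source file ", path, " lacks both coordinate columns and an HGVS ",
         "column required by dialect '", schema, "'")
  }
  get <- function(field) {
    col <- cols[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))
  rec <- data.frame(
    source = rep(source_name, nrow(raw)),
    record_id = blank_to_na(get("record_id")),
    assembly = blank_to_na(get("assembly")),
    chrom = blank_to_na(get("chrom")),
    pos = suppressWarnings(as.numeric(blank_to_na(get("pos")))),
    ref = blank_to_na(get("ref")),
    alt = blank_to_na(get("alt")),
    hgvs_c = blank_to_na(get("hgvs_c")),
    variant_class = rep("snv_like", nrow(raw)),
    phenotype = get("phenotype"),
    origin_raw = blank_to_na(get("origin")),
    trio = tolower(blank_to_na(get("trio"))) %in% c("yes", "true", "1", "trio"),
    reported_class = blank_to_na(get("pathogenicity")),
    af = suppressWarnings(as.numeric(blank_to_na(get("af")))),
    stringsAsFactors = FALSE
  )
  if (nrow(rec) && anyNA(rec$record_id)) {
    rec$record_id[is.na(rec$record_id)] <-
      paste0(source_name, "_row", which(is.na(rec$record_id)))
  }
  rec$phenotype <- gsub(d$phen_sep, ";", rec$phenotype, fixed = TRUE)
  rec$assembly[is.na(rec$assembly)] <- assembly
  has_coords <- !is.na(rec$chrom) & !is.na(rec$pos) &
    (!is.na(rec$ref) | !is.na(rec$alt))
  has_hgvs <- !is.na(rec$hgvs_c)
  ambiguous <- !has_coords & !has_hgvs
  excluded <- if (any(ambiguous)) {
    data.frame(source = source_name, record_id = rec$record_id[ambiguous],
               reason = "ambiguous", stringsAsFactors = FALSE)
  } else {
    .empty_exclusions()
  }
  list(records = rec[!ambiguous, , drop = FALSE], excluded = excluded)
}

# Minimal VCF reader: fixed columns of an uncompressed single-sample
# site list are all the pipeline needs from VCF input.
.ingest_vcf <- function(path, source_name, assembly) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!any(startsWith(lines, "#CHROM"))) stop("not a VCF file: ", path)
  rec <- .empty_records()
  if (length(body)) {
    f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    rec <- data.frame(
      source = source_name,
      record_id = ifelse(f[, 3] == ".", paste0(source_name, "_row", seq_len(nrow(f))), f[, 3]),
      assembly = assembly, chrom = f[, 1], pos = as.numeric(f[, 2]),
      ref = toupper(f[, 4]), alt = toupper(f[, 5]), hgvs_c = NA_character_,
      variant_class = "snv_like", phenotype = NA_character_,
      origin_raw = NA_character_, trio = FALSE,
      reported_class = NA_character_, af = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  list(records = rec, excluded = .empty_exclusions())
}

# Build a cdna_variant from genomic pos/ref/alt (plain or VCF-anchored).
.coords_to_cdna <- function(model, pos, ref, alt) {
  ref <- ifelse(is.na(ref) | ref %in% c("-", "."), "", toupper(ref))
  alt <- ifelse(is.na(alt) | alt %in% c("-", "."), "", toupper(alt))
  sgn <- .strand_sign(model)
  if (model$strand == "-") {
    if (nzchar(ref)) ref <- .revcomp(ref)
    if (nzchar(alt)) alt <- .revcomp(alt)
  }
  co_at <- function(p) genomic_to_cdna(model, p)
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    return(cdna_variant("sub", co_at(pos), ref = ref, alt = alt))
  }
  # VCF anchored forms share the first base
  if (nchar(ref) > 0 && nchar(alt) > 0 &&
      substr(ref, 1, 1) == substr(alt, 1, 1) && model$strand == "+") {
    if (nchar(alt) == 1 && nchar(ref) > 1) {
      s <- co_at(pos + 1); e <- co_at(pos + nchar(ref) - 1)
      return(cdna_variant("del", s, e, ref = substr(ref, 2, nchar(ref))))
    }
    if (nchar(ref) == 1 && nchar(alt) > 1) {
      return(cdna_variant("ins", co_at(pos), co_at(pos + 1),
                          alt = substr(alt, 2, nchar(alt))))
    }
  }
  if (nchar(ref) > 0 && nchar(alt) == 0) {
    a <- co_at(pos); b <- co_at(pos + (nchar(ref) - 1) * sgn)
    if (.cdna_key(a) > .cdna_key(b)) { tmp <- a; a <- b; b <- tmp }
    return(cdna_variant("del", a, b, ref = ref))
  }
  if (nchar(ref) == 0 && nchar(alt) > 0) {
    return(cdna_variant("ins", co_at(pos), co_at(pos + sgn), alt = alt))
  }
  a <- co_at(pos); b <- co_at(pos + (nchar(ref) - 1) * sgn)
  if (.cdna_key(a) > .cdna_key(b)) { tmp <- a; a <- b; b <- tmp }
  cdna_variant("delins", a, b, ref = ref, alt = alt)
}

#' Standardize ingested records to GRCh37 + canonical HGVS
#'
#' GRCh38 coordinates are lifted through the supplied chains; missing
#' coordinates are reconstructed from the HGVS description via the
#' transcript model and vice versa; coding descriptions are
#' 3'-normalized and validated against the transcript CDS. Records that
#' cannot be standardized are excluded with a reason
#' (`liftover_no_chain`, `liftover_in_gap`, `hgvs_parse_error`,
#' `unsupported_kind`, `reference_mismatch`, `inconsistent`,
#' `out_of_transcript`).
#'
#' @param records Record `data.frame` from [ingest_source()] (rows may
#'   be concatenated across sources).
#' @param chains Chain list from [parse_chain()] mapping GRCh38 to
#'   GRCh37 (may be `NULL` when all records are GRCh37).
#' @param model GRCh37 [transcript_model()].
#' @return List with `records` (standardized rows, extra columns `key`,
#'   `hgvs_norm`, `g_pos`, `region`) and `excluded`.
#' @export
standardize_records <- function(records, chains, model) {
  records <- as.data.frame(records)
  n <- nrow(records)
  keep <- logical(n)
  key <- hgvs_norm <- region <- rep(NA_character_, n)
  g_pos <- rep(NA_real_, n)
  excl <- .empty_exclusions()
  drop <- function(i, reason) {
    excl[nrow(excl) + 1L, ] <<- list(records$source[i], records$record_id[i], reason)
  }
  for (i in seq_len(n)) {
    chrom <- records$chrom[i]; pos <- records$pos[i]
    has_coords <- !is.na(chrom) && !is.na(pos)
    if (has_coords && identical(records$assembly[i], "GRCh38")) {
      m <- map_position(chains, chrom, pos)
      if (!m$mapped) { drop(i, paste0("liftover_", m$reason)); next }
      chrom <- m$chrom; pos <- m$pos
      records$assembly[i] <- "GRCh37"
      records$chrom[i] <- chrom; records$pos[i] <- pos
    }
    if (has_coords && !identical(chrom, model$chrom)) {
      drop(i, "out_of_transcript"); next
    }
    v <- NULL
    if (!is.na(records$hgvs_c[i])) {
      v <- tryCatch(parse_c(records$hgvs_c[i]), error = function(e) e)
      if (inherits(v, "error")) {
        drop(i, if (grepl("unsupported", conditionMessage(v)))
          "unsupported_kind" else "hgvs_parse_error")
        next
      }
    }
    if (is.null(v)) {
      v <- tryCatch(.coords_to_cdna(model, pos, records$ref[i], records$alt[i]),
                    error = function(e) e)
      if (inherits(v, "error")) { drop(i, "out_of_transcript"); next }
    }
    # 3'-normalize coding descriptions and validate stated reference
    vn <- tryCatch(normalize_3prime(model$cds_sequence, v), error = function(e) e)
    if (inherits(vn, "ctcfcat_ref_mismatch")) { drop(i, "reference_mismatch"); next }
    if (inherits(vn, "error")) { drop(i, "out_of_transcript"); next }
    if (vn$kind == "sub" && vn$start$kind == "cds" &&
        !is.null(model$cds_sequence) && nzchar(vn$ref)) {
      have <- substr(model$cds_sequence, vn$start$base, vn$start$base)
      if (have != vn$ref) { drop(i, "reference_mismatch"); next }
    }
    g <- tryCatch(cdna_to_genomic(model, vn$start), error = function(e) e)
    if (inherits(g, "error")) { drop(i, "out_of_transcript"); next }
    if (has_coords && is.na(records$hgvs_c[i]) == FALSE) {
      # both representations present: they must agree after normalization
      v_coords <- tryCatch(
        normalize_3prime(model$cds_sequence,
                         .coords_to_cdna(model, pos, records$ref[i],
                                         records$alt[i])),
        error = function(e) e)
      ok <- !inherits(v_coords, "error") &&
        identical(format_c(v_coords), format_c(vn))
      if (!ok) { drop(i, "inconsistent"); next }
    }
    keep[i] <- TRUE
    hgvs_norm[i] <- format_c(vn)
    g_pos[i] <- g
    region[i] <- switch(vn$start$kind, cds = "exonic_cds", utr5 = "utr5",
                        utr3 = "utr3", intronic = "intronic")
    key[i] <- paste0(model$chrom, ":", format_c(vn))
  }
  out <- records[keep, , drop = FALSE]
  out$hgvs_norm <- hgvs_norm[keep]
  out$g_pos <- g_pos[keep]
  out$region <- region[keep]
  out$key <- key[keep]
  out$assembly <- "GRCh37"
  list(records = out, excluded = excl)
}

.merge_vals <- function(x, sources) {
  x <- x[!is.na(x) & nzchar(x)]
  u <- unique(x)
  if (!length(u)) NA_character_ else paste(u, collapse = "|")
}

#' Deduplicate standardized records into canonical variants
#'
#' One canonical variant per distinct key (transcript-anchored,
#' 3'-normalized HGVS on GRCh37). Reported attributes from all records
#' are retained (pipe-merged, flagged when conflicting); without
#' patient identifiers, same-key records from different sources are
#' treated as duplicate reports of one variant, so no recurrence is
#' inferred.
#'
#' @param records Standardized record `data.frame` from
#'   [standardize_records()].
#' @return List with `catalog` (one row per canonical variant),
#'   `stats` (record/duplicate/distinct counts, per-source table,
#'   multi-source count) and `records` (input, for audit).
#' @export
deduplicate <- function(records) {
  records <- as.data.frame(records)
  n_records <- nrow(records)
  if (n_records == 0) {
    catalog <- data.frame(key = character(), hgvs_c = character(),
                          chrom = character(), pos = numeric(),
                          region = character(), n_records = integer(),
                          n_sources = integer(), sources = character(),
                          phenotype = character(), origin_raw = character(),
                          trio = logical(), reported_class = character(),
                          af = numeric(), conflict_fields = character(),
                          stringsAsFactors = FALSE)
    stats <- list(n_records = 0L, n_distinct = 0L, n_duplicate_records = 0L,
                  per_source = data.frame(), n_multi_source = 0L)
    return(list(catalog = catalog, stats = stats, records = records))
  }
  # sort for order-invariance of merged outputs
  records <- records[order(records$key, records$source, records$record_id), ]
  groups <- split(seq_len(nrow(records)), records$key)
  rows <- lapply(groups, function(idx) {
    g <- records[idx, , drop = FALSE]
    conflicts <- character(0)
    merge_field <- function(field) {
      val <- .merge_vals(g[[field]], g$source)
      if (!is.na(val) && grepl("|", val, fixed = TRUE)) {
        conflicts <<- c(conflicts, field)
      }
      val
    }
    phen <- unique(unlist(strsplit(g$phenotype[!is.na(g$phenotype)], ";")))
    phen <- trimws(phen[nzchar(trimws(phen))])
    origin <- merge_field("origin_raw")
    reported <- merge_field("reported_class")
    af <- suppressWarnings(max(g$af, na.rm = TRUE))
    data.frame(
      key = g$key[1], hgvs_c = g$hgvs_norm[1], chrom = g$chrom[1],
      pos = g$g_pos[1], region = g$region[1],
      n_records = nrow(g), n_sources = length(unique(g$source)),
      sources = paste(sort(unique(g$source)), collapse = ","),
      phenotype = if (length(phen)) paste(phen, collapse = ";") else NA_character_,
      origin_raw = origin, trio = any(g$trio),
      reported_class = reported,
      af = if (is.finite(af)) af else NA_real_,
      conflict_fields = paste(conflicts, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  catalog <- do.call(rbind, rows)
  rownames(catalog) <- NULL
  catalog <- catalog[order(catalog$pos, catalog$key), , drop = FALSE]
  per_source <- do.call(rbind, lapply(split(records, records$source), function(g) {
    src <- g$source[1]
    keys <- unique(g$key)
    exclusive <- vapply(keys, function(k) {
      all(records$source[records$key == k] == src)
    }, logical(1))
    data.frame(source = src, n_entries = nrow(g), n_variants = length(keys),
               n_exclusive = sum(exclusive), stringsAsFactors = FALSE)
  }))
  rownames(per_source) <- NULL
  stats <- list(
    n_records = n_records,
    n_distinct = nrow(catalog),
    n_duplicate_records = n_records - nrow(catalog),
    per_source = per_source,
    n_multi_source = sum(catalog$n_sources >= 2)
  )
  list(catalog = catalog, stats = stats, records = records)
}

#' Per-source entry/overlap summary table
#'
#' The database-summary view: per source, its record count and share of
#' all records, its distinct variant count, how many of those variants
#' are exclusive to it, and the exclusive share — plus a totals row.
#'
#' @param dedup Result of [deduplicate()].
#' @return `data.frame` with one row per source and a `Total` row.
#' @export
source_overlap_table <- function(dedup) {
  ps <- dedup$stats$per_source
  if (!nrow(ps)) return(data.frame())
  total_entries <- sum(ps$n_entries)
  out <- data.frame(
    source = ps$source,
    n_entries = ps$n_entries,
    pct_of_entries = 100 * ps$n_entries / total_entries,
    n_variants = ps$n_variants,
    n_exclusive = ps$n_exclusive,
    pct_exclusive = ifelse(ps$n_variants > 0,
                           100 * ps$n_exclusive / ps$n_variants, 0),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_entries, out$source), ]
  rbind(out, data.frame(source = "Total", n_entries = total_entries,
                        pct_of_entries = 100,
                        n_variants = dedup$stats$n_distinct,
                        n_exclusive = sum(ps$n_exclusive),
                        pct_exclusive = 100 * sum(ps$n_exclusive) /
                          max(dedup$stats$n_distinct, 1)))
}
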