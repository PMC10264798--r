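# Copy-number variant curation: exact-coordinate deduplication, dosage
# and size summaries, gene-overlap calls.

#' Read a CNV table
#'
#' Accepts a TSV with 1-based closed coordinates (columns `chrom`,
#' `start`, `end`, `dosage`, optional `origin`, `pathogenicity`,
#' `phenotype`, `source`, `record_id`) or a BED-like file
#' (`bed = TRUE`), whose 0-based half-open coordinates are converted to
#' the internal 1-based closed convention on input.
#'
#' @param path File path.
#' @param bed Input is BED-like 0-based half-open.
#' @param assembly Assembly label.
#' @return CNV record `data.frame`.
#' @export
read_cnv_table <- function(path, bed = FALSE, assembly = "GRCh37") {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (bed) {
    names(x)[1:4] <- c("chrom", "start", "end", "dosage")
    x$start <- x$start + 1  # 0-based half-open -> 1-based closed
  }
  stopifnot(all(c("chrom", "start", "end", "dosage") %in% names(x)))
  if (any(!x$dosage %in% c("gain", "loss"))) {
    bad <- setdiff(unique(x$dosage), c("gain", "loss"))
    stop("unsupported CNV dosage value(s): ", paste(bad, collapse = ", "),
         " (translocations and other rearrangements are not supported)")
  }
  for (opt in c("origin", "pathogenicity", "phenotype", "source", "record_id")) {
    if (!opt %in% names(x)) x[[opt]] <- NA_character_
  }
  x$assembly <- assembly
  x
}

#' Deduplicate CNV records on exact coordinates
#'
#' One record per exact `(chrom, start, end, dosage)` tuple; dosage is
#' part of CNV identity, so a gain and a loss over the same interval
#' stay distinct. Provenance of merged records is retained.
#'
#' @param records CNV record `data.frame`.
#' @return List with `records` (distinct, with `n_records` and merged
#'   `sources`) and `stats` (`n_records`, `n_duplicates`, `n_distinct`).
#' @export
dedup_cnv <- function(records) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0) {
    return(list(records = records,
                stats = list(n_records = 0L, n_duplicates = 0L, n_distinct = 0L)))
  }
  key <- paste(records$chrom, records$start, records$end, records$dosage)
  ord <- order(key, seq_len(n))
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  groups <- split(seq_len(n), key)
  rows <- lapply(groups, function(idx) {
    g <- records[idx, , drop = FALSE]
    # canonical within-group order so the representative row (and the
    # result as a whole) is invariant under input record order
    g <- g[order(apply(g, 1, paste, collapse = "\r")), , drop = FALSE]
    out <- g[1, , drop = FALSE]
    out$n_records <- nrow(g)
    if ("source" %in% names(g)) {
      out$sources <- paste(sort(unique(stats::na.omit(g$source))), collapse = ",")
    }
    out
  })
  distinct <- do.call(rbind, rows)
  distinct <- distinct[order(distinct$chrom, distinct$start, distinct$end,
                             distinct$dosage), , drop = FALSE]
  rownames(distinct) <- NULL
  list(records = distinct,
       stats = list(n_records = n, n_duplicates = n - nrow(distinct),
                    n_distinct = nrow(distinct)))
}

#' CNV size in base pairs and human-readable text
#'
#' Sizes at or above 1 Mb are printed in Mb to one decimal, at or above
#' 1 kb in kb to one decimal, otherwise in bp.
#'
#' @param start,end 1-based closed interval endpoints (or pass a
#'   [genomic_interval()] as `start`).
#' @return List with `bp` and `text`.
#' @examples
#' cnv_size(65347298, 90148393)  # 24801096 bp, "24.8 Mb"
#' @export
cnv_size <- function(start, end = NULL) {
  if (inherits(start, "genomic_interval")) {
    bp <- interval_length(start)
  } else {
    stopifnot(start <= end)
    bp <- end - start + 1
  }
  text <- if (bp >= 1e6) {
    sprintf("%.1f Mb", bp / 1e6)
  } else if (bp >= 1e3) {
    sprintf("%.1f kb", bp / 1e3)
  } else {
    sprintf("%d bp", as.integer(bp))
  }
  list(bp = bp, text = text)
}

#' Overlap class of a CNV with respect to a gene
#'
#' @param rec A CNV row (list/`data.frame` row with `chrom`, `start`,
#'   `end`) or a [genomic_interval()].
#' @param gene A [genomic_interval()] for the gene.
#' @return `"contains_gene"` when the CNV fully covers the gene,
#'   `"partial"` for any other nonzero overlap, `"none"` otherwise
#'   (including chromosome mismatch).
#' @export
gene_overlap <- function(rec, gene) {
  stopifnot(inherits(gene, "genomic_interval"))
  chrom <- if (inherits(rec, "genomic_interval")) rec$chrom else rec$chrom
  s <- rec$start; e <- rec$end
  if (!identical(as.character(chrom), gene$chrom)) return("none")
  if (s <= gene$start && e >= gene$end) return("contains_gene")
  if (max(s, gene$start) <= min(e, gene$end)) return("partial")
  "none"
}

#' Summarize curated CNV records
#'
#' Counts and size ranges by dosage and phenotype class (NDD /
#' non-NDD / no data), plus origin and pathogenicity breakdowns.
#' `phenotype_category` should hold categories from
#' [classify_phenotype()]; records without one are treated as no-data.
#'
#' @param records Distinct CNV `data.frame` (with `dosage`, `start`,
#'   `end`, optional `phenotype_category`, `origin`, `pathogenicity`).
#' @return List of tidy tables: `by_group`, `by_origin`,
#'   `by_pathogenicity`.
#' @export
summarize_cnvs <- function(records) {
  records <- as.data.frame(records)
  grp_levels <- expand.grid(dosage = c("gain", "loss"),
                            phenotype_class = c("NDD", "non_NDD", "no_data"),
                            stringsAsFactors = FALSE)
  if (!nrow(records)) {
    by_group <- cbind(grp_levels, n = 0L, min_bp = NA_real_, max_bp = NA_real_,
                      min_size = NA_character_, max_size = NA_character_)
    return(list(by_group = by_group,
                by_origin = data.frame(origin = character(), n = integer()),
                by_pathogenicity = data.frame(pathogenicity = character(),
                                              n = integer())))
  }
  cat <- if ("phenotype_category" %in% names(records)) {
    records$phenotype_category
  } else {
    rep(NA_character_, nrow(records))
  }
  pclass <- ifelse(is_ndd(cat), "NDD",
                   ifelse(!is.na(cat) & cat %in% c("NON_NDD", "CONTROL"),
                          "non_NDD", "no_data"))
  bp <- records$end - records$start + 1
  by_group <- do.call(rbind, lapply(seq_len(nrow(grp_levels)), function(i) {
    sel <- records$dosage == grp_levels$dosage[i] &
      pclass == grp_levels$phenotype_class[i]
    data.frame(grp_levels[i, ], n = sum(sel),
               min_bp = if (any(sel)) min(bp[sel]) else NA_real_,
               max_bp = if (any(sel)) max(bp[sel]) else NA_real_,
               min_size = if (any(sel)) cnv_size(1, min(bp[sel]))$text else NA_character_,
               max_size = if (any(sel)) cnv_size(1, max(bp[sel]))$text else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  tab <- function(x, name) {
    x <- ifelse(is.na(x) | !nzchar(x), "unknown", x)
    t <- as.data.frame(table(x), stringsAsFactors = FALSE)
    names(t) <- c(name, "n")
    t
  }
  list(by_group = by_group,
       by_origin = tab(records$origin, "origin"),
       by_pathogenicity = tab(records$pathogenicity, "pathogenicity"))
}
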