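# Synthetic multi-source variant exports with a ground-truth ledger.
# The generator emulates the statistical structure of the aggregated
# CTCF dataset (record/duplicate totals, phenotype and consequence
# composition, origin mixture, build mixture, schema dialects) so the
# whole pipeline is testable end to end without any download; every
# emitted record traces back to one truth variant.

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Convert a mixture of proportions to integer counts
#'
#' Largest-remainder apportionment; the mixture must sum to 1.
#'
#' @param n Total count.
#' @param mix Named numeric proportions summing to 1.
#' @return Named integer counts summing to `n`.
#' @export
mix_to_counts <- function(n, mix) {
  if (abs(sum(mix) - 1) > 1e-8) {
    stop("mixture proportions must sum to 1 (got ", sum(mix), ")")
  }
  raw <- n * mix
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(mix))
}

#' Generate a random valid toy transcript
#'
#' Builds a plus-strand transcript on a synthetic chromosome: a CDS of
#' `cds_codons` codons (ATG start, single terminal stop, no internal
#' stop) flanked by UTRs, split across `n_exons` exons separated by
#' random introns. Deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @param n_exons Number of exons (>= 1).
#' @param cds_codons Total codons including start and stop (>= 2).
#' @param utr5_len,utr3_len UTR lengths in nt.
#' @param chrom Chromosome name.
#' @param tx_start Genomic start of the first exon.
#' @return A [transcript_model()] with `cds_sequence` set.
#' @export
generate_transcript <- function(seed, n_exons = 3, cds_codons = 60,
                                utr5_len = 30, utr3_len = 40,
                                chrom = "chrT", tx_start = 1001) {
  if (cds_codons < 2) {
    stop("cds_codons must be >= 2 (a start and a stop codon)")
  }
  if (n_exons < 1) stop("n_exons must be >= 1")
  with_seed(seed, {
    cds <- paste0("ATG",
                  paste(sample(.SENSE_CODONS, cds_codons - 2, replace = TRUE),
                        collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1))
    mrna_len <- utr5_len + nchar(cds) + utr3_len
    min_exon <- 5L
    if (mrna_len < n_exons * min_exon) {
      stop("transcript too short for ", n_exons, " exons")
    }
    repeat {
      cuts <- if (n_exons > 1) sort(sample(seq_len(mrna_len - 1), n_exons - 1)) else integer(0)
      lens <- diff(c(0L, cuts, mrna_len))
      if (all(lens >= min_exon)) break
    }
    introns <- if (n_exons > 1) sample(50:300, n_exons - 1, replace = TRUE) else integer(0)
    starts <- ends <- numeric(n_exons)
    g <- tx_start
    for (i in seq_len(n_exons)) {
      starts[i] <- g
      ends[i] <- g + lens[i] - 1
      g <- ends[i] + 1 + if (i < n_exons) introns[i] else 0
    }
    exons <- data.frame(start = starts, end = ends)
    # genomic coordinates of the first/last coding base
    tx_to_g <- function(t) {
      cum <- 0
      for (i in seq_len(n_exons)) {
        if (t <= cum + lens[i]) return(starts[i] + (t - cum) - 1)
        cum <- cum + lens[i]
      }
      stop("internal: transcript index out of range")
    }
    transcript_model(
      transcript_id = sprintf("SYNTX%06d.1", seed %% 1000000),
      gene_symbol = "TOY1", chrom = chrom, strand = "+", exons = exons,
      cds_start = tx_to_g(utr5_len + 1),
      cds_end = tx_to_g(utr5_len + nchar(cds)),
      assembly = "GRCh37", cds_sequence = cds
    )
  })
}

# Per-category pools of reported-condition wording, deliberately messy
# in casing and punctuation to exercise the text normalizer.
.PHENO_POOLS <- list(
  CRD = c("CTCF-related neurodevelopmental disorder",
          "Mental retardation, autosomal dominant 21", "MRD21",
          "ctcf related Disorder"),
  ASD = c("Autism spectrum disorder", "AUTISM", "Autistic behavior;",
          "autism spectrum disorder (ASD)"),
  IGD = c("Inborn genetic diseases", "INBORN GENETIC DISEASE"),
  DD = c("Developmental delay", "Global developmental delay",
         "developmental disorder"),
  EP = c("Epilepsy", "seizures", "Epileptic encephalopathy"),
  ID = c("Intellectual disability", "INTELLECTUAL DISABILITY"),
  ANS = c("Abnormality of the nervous system"),
  NON_NDD = c("Mammary neoplasms", "Breast cancer",
              "Acute megakaryoblastic leukemia in Down syndrome",
              "Congenital diaphragmatic hernia"),
  CONTROL = c("Detected in controls", "control cohort"),
  NONE = character(0)
)

.REPORTED_TEXT <- c(P = "Pathogenic", LP = "Likely pathogenic",
                    VUS = "Uncertain significance", LB = "Likely benign",
                    B = "Benign", NONE = NA_character_)

# Draw one coding variant of a requested consequence class on the model
# (verified with the consequence engine); returns a cdna_variant.
.draw_coding_variant <- function(model, klass, used_keys) {
  cds <- model$cds_sequence
  len <- nchar(cds)
  bases <- c("A", "C", "G", "T")
  for (attempt in seq_len(500)) {
    v <- switch(klass,
      missense = , synonymous = , nonsense = {
        p <- sample(4:(len - 3), 1)
        ref <- substr(cds, p, p)
        alt <- sample(setdiff(bases, ref), 1)
        cdna_variant("sub", cdna_coordinate("cds", p), ref = ref, alt = alt)
      },
      frameshift = {
        p <- sample(4:(len - 30), 1)
        if (stats::runif(1) < 0.5) {
          cdna_variant("del", cdna_coordinate("cds", p),
                       ref = substr(cds, p, p))
        } else {
          cdna_variant("dup", cdna_coordinate("cds", p),
                       ref = substr(cds, p, p))
        }
      },
      inframe_del = {
        p <- sample(4:(len - 6), 1)
        cdna_variant("del", cdna_coordinate("cds", p),
                     cdna_coordinate("cds", p + 2),
                     ref = substr(cds, p, p + 2))
      },
      stop("cannot draw consequence class ", klass))
    cc <- tryCatch(call_consequence(model, v), error = function(e) NULL)
    if (is.null(cc) || cc$klass != klass) next
    key <- cc$hgvs_c
    if (key %in% used_keys) next
    return(list(v = parse_c(cc$hgvs_c), key = key))
  }
  stop("could not realise consequence class '", klass,
       "' on this transcript (transcript too small?)")
}

.draw_noncoding_variant <- function(model, region, used_keys) {
  bases <- c("A", "C", "G", "T")
  b <- .cds_tx_bounds(model)
  utr3_len <- .tx_length(model) - b["last"]
  for (attempt in seq_len(500)) {
    co <- if (region == "utr3") {
      cdna_coordinate("utr3", sample(seq_len(utr3_len), 1))
    } else {
      # random intronic position
      n <- nrow(model$exons)
      if (n < 2) stop("intronic variants need a multi-exon transcript")
      i <- sample(seq_len(n - 1), 1)
      gap_lo <- model$exons$end[i] + 1
      gap_hi <- model$exons$start[i + 1] - 1
      genomic_to_cdna(model, sample(gap_lo:gap_hi, 1))
    }
    ref <- sample(bases, 1)
    v <- cdna_variant("sub", co, ref = ref, alt = sample(setdiff(bases, ref), 1))
    key <- format_c(v)
    if (key %in% used_keys) next
    return(list(v = v, key = key))
  }
  stop("could not place a distinct ", region, " variant")
}

.counts_ok <- function(x, what) {
  if (any(x < 0) || any(x != floor(x))) stop(what, " must be nonnegative integers")
  invisible(TRUE)
}

#' Generate the ground-truth variant catalog (truth ledger)
#'
#' Places distinct SNVs on a toy transcript so that every drawn
#' consequence class is actually achieved (verified with the
#' consequence engine at generation time), then assigns phenotype
#' categories, origins and reported pathogenicity. The defaults
#' reproduce the integer composition of the aggregated CTCF catalog:
#' 225 exonic variants (phenotypes CRD 54 / ASD 41 / IGD 29 / DD 18 /
#' EP 3 / ID 2 / ANS 2 / non-NDD 7 / no data 69, i.e. 149 NDD = 66%;
#' the 149 split into 85 missense, 32 frameshift, 13 nonsense, 4
#' in-frame deletion, 15 synonymous) and 86 noncoding variants (ASD 24
#' / CRD 6 / ANS 1 / no data 46 / controls 9), 311 distinct in total.
#' Origin among the 149 NDD exonic variants: 128 de novo, 6 inherited,
#' 15 unconfirmed.
#'
#' @param seed Integer seed.
#' @param model Transcript from [generate_transcript()]; the default
#'   (`NULL`) builds a 250-codon, 4-exon transcript from the same seed.
#' @param exonic_phenotype_counts Named integer counts over CRD, ASD,
#'   IGD, DD, EP, ID, ANS, NON_NDD, NONE.
#' @param ndd_class_counts Consequence-class counts for the NDD-labeled
#'   exonic variants; must sum to the NDD total implied by
#'   `exonic_phenotype_counts`.
#' @param noncoding_phenotype_counts Named counts over categories
#'   (plus NONE/CONTROL) for noncoding variants; set to `NULL` or an
#'   empty vector for an exonic-only catalog.
#' @param origin_counts_ndd Counts of de_novo / inherited / unknown
#'   among NDD exonic variants.
#' @param reported_counts_ndd Counts of reported classes (P, LP, VUS,
#'   LB, B, NONE) among NDD exonic variants.
#' @return A `truth_ledger`: `data.frame` of distinct truth variants
#'   with attribute `expected` (bookkeeping counts used by
#'   parameter-recovery tests) and attribute `model`.
#' @export
generate_catalog_truth <- function(
    seed, model = NULL,
    exonic_phenotype_counts = c(CRD = 54, ASD = 41, IGD = 29, DD = 18,
                                EP = 3, ID = 2, ANS = 2, NON_NDD = 7,
                                NONE = 69),
    ndd_class_counts = c(missense = 85, frameshift = 32, nonsense = 13,
                         inframe_del = 4, synonymous = 15),
    noncoding_phenotype_counts = c(ASD = 24, CRD = 6, ANS = 1, NONE = 46,
                                   CONTROL = 9),
    origin_counts_ndd = c(de_novo = 128, inherited = 6, unknown = 15),
    reported_counts_ndd = c(P = 50, LP = 41, VUS = 27, LB = 10, B = 8,
                            NONE = 13)) {
  if (is.null(model)) model <- generate_transcript(seed, n_exons = 4,
                                                   cds_codons = 250,
                                                   utr3_len = 120)
  .counts_ok(exonic_phenotype_counts, "exonic_phenotype_counts")
  .counts_ok(ndd_class_counts, "ndd_class_counts")
  if (is.null(noncoding_phenotype_counts)) noncoding_phenotype_counts <- integer(0)
  .counts_ok(noncoding_phenotype_counts, "noncoding_phenotype_counts")
  ndd_cats <- names(exonic_phenotype_counts)[is_ndd(names(exonic_phenotype_counts))]
  n_ndd <- sum(exonic_phenotype_counts[ndd_cats])
  if (sum(ndd_class_counts) != n_ndd) {
    stop("ndd_class_counts must sum to the NDD exonic total (", n_ndd, ")")
  }
  if (sum(origin_counts_ndd) != n_ndd || sum(reported_counts_ndd) != n_ndd) {
    stop("origin_counts_ndd and reported_counts_ndd must sum to ", n_ndd)
  }
  n_exonic <- sum(exonic_phenotype_counts)
  with_seed(seed + 1L, {
    used <- character(0)
    rows <- list()
    add_row <- function(v, key, region, klass, category, origin, reported) {
      cc <- call_consequence(model, v)
      g <- cdna_to_genomic(model, v$start)
      ref_g <- v$ref; alt_g <- v$alt
      rows[[length(rows) + 1L]] <<- data.frame(
        variant_id = sprintf("TV%04d", length(rows) + 1L),
        key = key, hgvs_c = key, region = region, klass = klass,
        g_pos = g, ref = ref_g, alt = alt_g, kind = v$kind,
        end_base = if (v$end$kind == "cds") v$end$base else NA_integer_,
        phenotype_category = category,
        origin = origin,
        trio = origin %in% c("de_novo", "inherited"),
        reported_class = reported,
        stringsAsFactors = FALSE)
      used <<- c(used, key)
    }
    # --- exonic variants -------------------------------------------------
    pheno_seq <- sample(rep(names(exonic_phenotype_counts),
                            times = exonic_phenotype_counts))
    is_ndd_var <- is_ndd(pheno_seq)
    # consequence classes: prescribed for NDD variants, proportional draw
    # for the rest
    class_seq <- character(n_exonic)
    class_seq[is_ndd_var] <- sample(rep(names(ndd_class_counts),
                                        times = ndd_class_counts))
    n_rest <- sum(!is_ndd_var)
    if (n_rest > 0) {
      class_seq[!is_ndd_var] <- sample(names(ndd_class_counts), n_rest,
                                       replace = TRUE,
                                       prob = ndd_class_counts / sum(ndd_class_counts))
    }
    origin_seq <- rep("unknown", n_exonic)
    origin_seq[is_ndd_var] <- sample(rep(names(origin_counts_ndd),
                                         times = origin_counts_ndd))
    reported_seq <- rep("NONE", n_exonic)
    reported_seq[is_ndd_var] <- sample(rep(names(reported_counts_ndd),
                                           times = reported_counts_ndd))
    for (i in seq_len(n_exonic)) {
      d <- .draw_coding_variant(model, class_seq[i], used)
      add_row(d$v, d$key, "exonic_cds", class_seq[i], pheno_seq[i],
              origin_seq[i], reported_seq[i])
    }
    # --- noncoding variants ----------------------------------------------
    if (sum(noncoding_phenotype_counts) > 0) {
      nc_pheno <- sample(rep(names(noncoding_phenotype_counts),
                             times = noncoding_phenotype_counts))
      nc_region <- sample(c("intronic", "utr3"), length(nc_pheno),
                          replace = TRUE, prob = c(0.7, 0.3))
      for (i in seq_along(nc_pheno)) {
        d <- .draw_noncoding_variant(model, nc_region[i], used)
        add_row(d$v, d$key, nc_region[i], "noncoding", nc_pheno[i],
                "unknown", "NONE")
      }
    }
    ledger <- do.call(rbind, rows)
    rownames(ledger) <- NULL
    exonic <- ledger[ledger$region == "exonic_cds", ]
    ndd_ex <- exonic[is_ndd(exonic$phenotype_category), ]
    # expected tables use the pipeline vocabulary: variants without
    # phenotype data classify as NO_PHENOTYPE_DATA
    as_pipeline_cat <- function(x) {
      table(ifelse(x == "NONE", "NO_PHENOTYPE_DATA", x))
    }
    ndd_nonsyn <- ndd_ex[ndd_ex$klass != "synonymous", ]
    expected <- list(
      n_distinct = nrow(ledger),
      n_exonic = nrow(exonic),
      n_noncoding = nrow(ledger) - nrow(exonic),
      n_exonic_ndd = nrow(ndd_ex),
      pct_exonic_ndd = round_half_up(100 * nrow(ndd_ex) / max(nrow(exonic), 1)),
      n_ndd_catalog = nrow(ndd_nonsyn),
      exonic_phenotype_counts = as_pipeline_cat(exonic$phenotype_category),
      ndd_class_counts = table(ndd_ex$klass),
      ndd_catalog_class_counts = table(ndd_nonsyn$klass),
      ndd_catalog_origin_counts = table(ndd_nonsyn$origin),
      ndd_origin_counts = table(ndd_ex$origin),
      noncoding_phenotype_counts =
        as_pipeline_cat(ledger$phenotype_category[ledger$region != "exonic_cds"])
    )
    structure(ledger, expected = expected, model = model,
              class = c("truth_ledger", class(ledger)))
  })
}

.DB_SOURCES <- data.frame(
  source = c("ClinVar", "AutDB", "Gene4denovo", "SFARI", "LOVD", "DECIPHER",
             "VariCarta", "DenovoDB", "DisGeNET", "EGIdb", "DBD"),
  weight = c(228, 80, 76, 72, 68, 55, 44, 28, 13, 8, 7),
  schema = c("clinvar_like", "generic_tsv", "denovo_like", "generic_tsv",
             "generic_tsv", "decipher_like", "generic_tsv", "denovo_like",
             "generic_tsv", "generic_tsv", "generic_tsv"),
  stringsAsFactors = FALSE
)

.mess_up <- function(s) {
  r <- stats::runif(1)
  if (r < 0.25) toupper(s)
  else if (r < 0.5) tolower(s)
  else if (r < 0.6) paste0("  ", s, " .")
  else s
}

#' Emit per-source export files for a truth ledger
#'
#' Allocates records to sources (one record per truth variant plus
#' `n_records - n_distinct` duplicate records sampled with replacement,
#' so every extra record is a coordinate-and-allele duplicate of an
#' earlier one), writes per-source TSV/CSV files in their schema
#' dialects, puts a configurable fraction of coordinate-bearing records
#' on GRCh38 (with a matching synthetic chain file back to GRCh37), and
#' samples phenotype wording from category-appropriate terminology
#' pools with deliberately messy casing.
#'
#' @param ledger A `truth_ledger` from [generate_catalog_truth()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed); `NULL` returns the
#'   record table without writing files.
#' @param n_records Total records to emit (>= number of truth variants).
#' @param sources Source table (`source`, `weight`, `schema`); default
#'   the 11-database layout.
#' @param build38_frac Fraction of coordinate-bearing records emitted
#'   on GRCh38.
#' @param hgvs_only_frac Fraction of records emitted with an HGVS
#'   description and no coordinates.
#' @param chain_offset Constant offset of the synthetic GRCh38
#'   coordinates relative to GRCh37.
#' @return List with `records` (the emitted record table in standard
#'   fields), `manifest` (source/schema/path), `chain_file`,
#'   `chains` (parsed), `files`.
#' @export
emit_source_exports <- function(ledger, seed, dir = NULL, n_records = 538,
                                sources = .DB_SOURCES, build38_frac = 0.4,
                                hgvs_only_frac = 0.25, chain_offset = 10000) {
  model <- attr(ledger, "model")
  n_distinct <- nrow(ledger)
  if (n_records < n_distinct) {
    stop("n_records must be at least the number of truth variants (",
         n_distinct, ")")
  }
  with_seed(seed + 2L, {
    idx <- c(seq_len(n_distinct),
             if (n_records > n_distinct)
               sample(seq_len(n_distinct), n_records - n_distinct, replace = TRUE))
    idx <- sample(idx)  # shuffle record order
    src <- sample(sources$source, n_records, replace = TRUE,
                  prob = sources$weight)
    rec <- ledger[idx, , drop = FALSE]
    out <- data.frame(
      source = src,
      record_id = paste0(src, "_", seq_len(n_records)),
      assembly = "GRCh37",
      chrom = model$chrom, pos = rec$g_pos,
      ref = rec$ref, alt = rec$alt,
      hgvs_c = rec$hgvs_c,
      variant_class = "snv_like",
      phenotype = NA_character_,
      origin_raw = NA_character_,
      trio = rec$trio,
      reported_class = .REPORTED_TEXT[rec$reported_class],
      af = NA_real_,
      stringsAsFactors = FALSE
    )
    # representation mode: substitutions may travel as coordinates only,
    # everything may travel as HGVS only; non-subs keep HGVS
    mode <- ifelse(stats::runif(n_records) < hgvs_only_frac, "hgvs",
                   ifelse(rec$kind == "sub" & stats::runif(n_records) < 0.5,
                          "coords", "both"))
    out$hgvs_c[mode == "coords"] <- NA_character_
    out$chrom[mode == "hgvs"] <- NA_character_
    out$pos[mode == "hgvs"] <- NA_real_
    out$ref[mode == "hgvs"] <- NA_character_
    out$alt[mode == "hgvs"] <- NA_character_
    # non-sub kinds: plain-style coordinates (del keeps ref, empty alt;
    # dup/ins travel as HGVS only)
    plain_del <- mode != "hgvs" & rec$kind == "del"
    out$alt[plain_del] <- "-"
    no_coords <- mode != "hgvs" & rec$kind %in% c("dup", "ins", "delins")
    out$chrom[no_coords] <- NA_character_
    out$pos[no_coords] <- NA_real_
    out$ref[no_coords] <- NA_character_
    out$alt[no_coords] <- NA_character_
    out$hgvs_c[no_coords] <- rec$hgvs_c[no_coords]
    # build mixture: only coordinate-bearing records can be GRCh38
    has_coords <- !is.na(out$pos)
    to38 <- has_coords & stats::runif(n_records) < build38_frac
    out$assembly[to38] <- "GRCh38"
    out$pos[to38] <- out$pos[to38] + chain_offset
    # phenotype strings and origin wording
    for (i in seq_len(n_records)) {
      pool <- .PHENO_POOLS[[rec$phenotype_category[i]]]
      if (length(pool)) {
        k <- sample(seq_along(pool), min(length(pool), sample(1:2, 1)))
        out$phenotype[i] <- paste(vapply(pool[k], .mess_up, character(1)),
                                  collapse = ";")
      }
      out$origin_raw[i] <- switch(rec$origin[i],
        de_novo = sample(c("de novo", "De Novo", "confirmed de novo"), 1),
        inherited = sample(c("maternal", "paternal", "inherited"), 1),
        unknown = sample(c(NA_character_, "not specified", "de novo"), 1))
      # unconfirmed records never carry trio backing
    }
    # synthetic chain: GRCh38 = GRCh37 + chain_offset on this chromosome
    span_end <- max(ledger$g_pos) + 1000
    chain <- structure(list(
      score = 1000, s_name = model$chrom, s_size = span_end + chain_offset,
      s_strand = "+", s_start = chain_offset, s_end = span_end + chain_offset,
      t_name = model$chrom, t_size = span_end, t_strand = "+",
      t_start = 0, t_end = span_end, id = "1",
      blocks = data.frame(size = span_end, s_gap = 0, t_gap = 0)),
      class = "chain_alignment")
    files <- list(); manifest <- NULL; chain_file <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      manifest <- data.frame(source = sources$source, schema = sources$schema,
                             path = file.path(dir, paste0(sources$source, ".txt")),
                             stringsAsFactors = FALSE)
      for (j in seq_len(nrow(manifest))) {
        d <- schema_dialects()[[manifest$schema[j]]]
        sub <- out[out$source == manifest$source[j], , drop = FALSE]
        native <- data.frame(row.names = seq_len(nrow(sub)))
        for (field in names(d$cols)) {
          std <- switch(field, pathogenicity = "reported_class",
                        origin = "origin_raw", phenotype = "phenotype", field)
          val <- sub[[std]]
          if (field == "phenotype") {
            val <- gsub(";", d$phen_sep, val, fixed = TRUE)
          }
          if (field == "trio") val <- ifelse(sub$trio, "yes", "no")
          native[[d$cols[[field]]]] <- val
        }
        utils::write.table(native, manifest$path[j], sep = d$sep,
                           row.names = FALSE, quote = TRUE, na = "")
      }
      chain_file <- file.path(dir, "synthetic_grch38_to_grch37.chain")
      write_chain(list(chain), chain_file)
      utils::write.table(as.data.frame(ledger), file.path(dir, "truth_ledger.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE, na = "")
      write_transcript_config(model, file.path(dir, "transcript.cfg"),
                              fasta = file.path(dir, "transcript_cds.fa"))
      utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- as.list(c(manifest$path, chain_file))
    }
    list(records = out, manifest = manifest, chain_file = chain_file,
         chains = list(chain), files = files)
  })
}

#' Generate synthetic CNV exports with ground truth
#'
#' Emits copy-number records overlapping the CTCF gene locus
#' (GRCh37 chr16:67,596,310-67,673,088): by default 62 distinct CNVs
#' (27 gains sized 5-90 Mb, 35 losses sized 1.4 kb-44 Mb) plus 11
#' records that duplicate earlier records' exact coordinates, 73
#' records in total. 36 of the distinct CNVs carry CRD/DD phenotypes;
#' 21 of those are de novo and 32 are reported LP/P, 2 VUS.
#'
#' @param seed Integer seed.
#' @param dir Output directory; `NULL` skips file writing.
#' @param n_gains,n_losses Distinct gain/loss counts.
#' @param n_duplicates Number of duplicate records to add.
#' @param gain_size_range,loss_size_range Size ranges in bp.
#' @param gene Gene interval the CNVs must overlap.
#' @return List with `records` (emitted table, duplicates included),
#'   `ledger` (distinct truth), `expected` (bookkeeping counts),
#'   `file`.
#' @export
generate_cnv_exports <- function(seed, dir = NULL, n_gains = 27, n_losses = 35,
                                 n_duplicates = 11,
                                 gain_size_range = c(5e6, 90e6),
                                 loss_size_range = c(1.4e3, 44e6),
                                 gene = genomic_interval("chr16", 67596310,
                                                         67673088)) {
  chrom_len <- 90354753  # GRCh37 chr16
  gene_len <- interval_length(gene)
  with_seed(seed + 3L, {
    n_distinct <- n_gains + n_losses
    draw_size <- function(n, range) {
      # log-uniform across the stated range
      round(exp(stats::runif(n, log(range[1]), log(range[2]))))
    }
    sizes <- c(draw_size(n_gains, gain_size_range),
               draw_size(n_losses, loss_size_range))
    dosage <- c(rep("gain", n_gains), rep("loss", n_losses))
    start <- end <- numeric(n_distinct)
    for (i in seq_len(n_distinct)) {
      sz <- sizes[i]
      if (sz >= gene_len) {
        lead <- sample(0:min(sz - gene_len, gene$start - 1), 1)
        start[i] <- gene$start - lead
      } else {
        start[i] <- sample(gene$start:(gene$end - sz + 1), 1)
      }
      end[i] <- start[i] + sz - 1
      if (end[i] > chrom_len) {  # shift left, size preserved
        end[i] <- chrom_len
        start[i] <- end[i] - sz + 1
      }
    }
    # exact-coordinate collisions among distinct CNVs would break the
    # bookkeeping; nudge until unique
    key <- function() paste(start, end, dosage)
    while (anyDuplicated(key())) {
      d <- which(duplicated(key()))
      start[d] <- start[d] + 1
      end[d] <- end[d] + 1
    }
    n_ndd <- 36
    pheno_cat <- c(sample(rep(c("CRD", "DD"), times = c(24, 12))),
                   rep("NONE", n_distinct - n_ndd))
    pheno_cat <- sample(pheno_cat)
    origin <- rep("unknown", n_distinct)
    patho <- rep(NA_character_, n_distinct)
    ndd_idx <- which(pheno_cat != "NONE")
    origin[sample(ndd_idx, 21)] <- "de novo"
    patho_lab <- sample(rep(c("Pathogenic", "Likely pathogenic",
                              "Uncertain significance", NA_character_),
                            times = c(18, 14, 2, 2)))
    patho[ndd_idx] <- patho_lab
    ledger <- data.frame(
      cnv_id = sprintf("CNV%03d", seq_len(n_distinct)),
      chrom = gene$chrom, start = start, end = end, dosage = dosage,
      size_bp = sizes, phenotype_category = pheno_cat, origin = origin,
      pathogenicity = patho, stringsAsFactors = FALSE)
    dup_idx <- sample(seq_len(n_distinct), n_duplicates, replace = TRUE)
    records <- rbind(ledger, ledger[dup_idx, , drop = FALSE])
    records <- records[sample(nrow(records)), , drop = FALSE]
    records$record_id <- sprintf("CNVREC%03d", seq_len(nrow(records)))
    records$source <- sample(c("DECIPHER", "ClinVar", "literature"),
                             nrow(records), replace = TRUE)
    records$phenotype <- vapply(records$phenotype_category, function(cat) {
      pool <- .PHENO_POOLS[[cat]]
      if (length(pool)) .mess_up(sample(pool, 1)) else NA_character_
    }, character(1))
    rownames(records) <- NULL
    expected <- list(
      n_records = nrow(records), n_duplicates = n_duplicates,
      n_distinct = n_distinct, n_gains = n_gains, n_losses = n_losses,
      n_ndd = n_ndd,
      gain_size_range_bp = range(sizes[dosage == "gain"]),
      loss_size_range_bp = range(sizes[dosage == "loss"]))
    file <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      file <- file.path(dir, "cnv_records.tsv")
      utils::write.table(
        records[, c("record_id", "source", "chrom", "start", "end", "dosage",
                    "origin", "pathogenicity", "phenotype")],
        file, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
      utils::write.table(ledger, file.path(dir, "cnv_truth_ledger.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE, na = "")
    }
    list(records = records, ledger = ledger, expected = expected, file = file)
  })
}
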