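# Ingestion dialects, standardization to GRCh37 + canonical HGVS,
# deduplication with provenance, conservation and order-invariance.

write_generic <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = TRUE, na = "")
  path
}

t1_cds <- function() {
  # CDS sequence for a T1-like model (single CDS across two exons):
  # 120 nt, 40 codons; keep it deterministic
  set.seed(7)
  paste0("ATG", paste(sample(ORACLE_SENSE, 38, replace = TRUE), collapse = ""), "TAA")
}

t1_seq_model <- function() {
  # two-exon model carrying a 120 nt CDS: exon1 contributes coding bases
  # 1-40 (genomic 121-160), exon2 bases 41-120 (genomic 201-280)
  transcript_model("T1", "TOY1", "chrT", "+",
                   exons = data.frame(start = c(101, 201), end = c(160, 290)),
                   cds_start = 121, cds_end = 280, cds_sequence = t1_cds())
}

test_that("ingest_source maps dialect columns onto standard fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(record_id = c("r1", "r2", "r3"), assembly = "GRCh37",
                   chrom = "chrT", pos = c(121, 125, 130), ref = "A", alt = "G",
                   hgvs_c = NA, phenotype = "Autism spectrum disorder",
                   origin = "de novo", trio = c("yes", "no", "yes"),
                   reported_class = "Pathogenic", af = 0.001)
  write_generic(df, path)
  out <- ingest_source(path, "generic_tsv", "SRC")
  expect_equal(nrow(out$records), 3)
  expect_equal(out$records$source, rep("SRC", 3))
  expect_equal(out$records$trio, c(TRUE, FALSE, TRUE))
  expect_equal(out$records$af, rep(0.001, 3))
  expect_error(ingest_source(path, "nope"), "unknown schema")
})

test_that("rows without coordinates or HGVS are excluded as ambiguous", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(record_id = c("a", "b"), assembly = "GRCh37",
                   chrom = c("chrT", NA), pos = c(121, NA), ref = "A", alt = "G",
                   hgvs_c = NA, phenotype = NA, origin = NA, trio = NA,
                   reported_class = NA, af = NA)
  write_generic(df, path)
  out <- ingest_source(path, "generic_tsv", "SRC")
  expect_equal(nrow(out$records), 1)
  expect_equal(out$excluded$record_id, "b")
  expect_equal(out$excluded$reason, "ambiguous")
})

test_that("VCF data lines become coordinate-bearing records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrT\t121\trs1\tA\tG\t.\t.\t."), path)
  out <- ingest_source(path, "vcf", "VSRC")
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$pos, 121)
  expect_equal(out$records$ref, "A")
  expect_error(ingest_source(withr::local_tempfile(lines = "no header"), "vcf"),
               "not a VCF")
})

test_that("standardize lifts GRCh38, reconstructs missing representations, excludes with reasons", {
  m <- t1_seq_model()
  cds <- m$cds_sequence
  ref5 <- substr(cds, 5, 5)
  alt5 <- setdiff(c("A", "C", "G", "T"), ref5)[1]
  chain <- parse_chain(c("chain 10 chrT 100000 + 10100 10260 chrT 100000 + 100 260 1",
                         "160", ""))
  rec <- data.frame(
    source = "S", record_id = c("r37", "r38", "rhgvs", "rbadref", "rsplit",
                                "rbadhgvs", "runsupp", "rinconsistent"),
    assembly = c("GRCh37", "GRCh38", "GRCh37", "GRCh37", "GRCh38", "GRCh37",
                 "GRCh37", "GRCh37"),
    chrom = c("chrT", "chrT", NA, "chrT", "chrT", NA, NA, "chrT"),
    pos = c(125, 10125, NA, 125, 50125, NA, NA, 125),
    ref = c(ref5, ref5, NA, setdiff(c("A","C","G","T"), ref5)[1], "A", NA, NA, ref5),
    alt = c(alt5, alt5, NA, "T", "G", NA, NA, alt5),
    hgvs_c = c(NA, NA, paste0("c.5", ref5, ">", alt5), NA, NA, "c.banana",
               "c.1_5inv", paste0("c.9", substr(cds, 9, 9), ">",
                                  setdiff(c("A","C","G","T"), substr(cds, 9, 9))[1])),
    variant_class = "snv_like", phenotype = NA, origin_raw = NA, trio = FALSE,
    reported_class = NA, af = NA_real_, stringsAsFactors = FALSE)
  out <- standardize_records(rec, chain, m)
  expect_setequal(out$records$record_id, c("r37", "r38", "rhgvs"))
  # all three describe the same canonical variant
  expect_equal(length(unique(out$records$key)), 1)
  expect_equal(unique(out$records$hgvs_norm), paste0("c.5", ref5, ">", alt5))
  expect_equal(unique(out$records$g_pos), 125)
  reasons <- setNames(out$excluded$reason, out$excluded$record_id)
  expect_equal(unname(reasons["rbadref"]), "reference_mismatch")
  expect_equal(unname(reasons["rsplit"]), "liftover_no_chain")
  expect_equal(unname(reasons["rbadhgvs"]), "hgvs_parse_error")
  expect_equal(unname(reasons["runsupp"]), "unsupported_kind")
  expect_equal(unname(reasons["rinconsistent"]), "inconsistent")
  # conservation at this stage
  expect_equal(nrow(out$records) + nrow(out$excluded), nrow(rec))
})

test_that("deduplicate merges same-key records with provenance and conservation", {
  m <- t1_seq_model()
  cds <- m$cds_sequence
  ref5 <- substr(cds, 5, 5); alt5 <- setdiff(c("A","C","G","T"), ref5)[1]
  ref9 <- substr(cds, 9, 9); alt9 <- setdiff(c("A","C","G","T"), ref9)[1]
  mk <- function(id, src, hgvs, pheno = NA, origin = NA, cls = NA, af = NA_real_,
                 trio = FALSE) {
    data.frame(source = src, record_id = id, assembly = "GRCh37",
               chrom = NA_character_, pos = NA_real_, ref = NA_character_,
               alt = NA_character_, hgvs_c = hgvs, variant_class = "snv_like",
               phenotype = pheno, origin_raw = origin, trio = trio,
               reported_class = cls, af = af, stringsAsFactors = FALSE)
  }
  rec <- rbind(
    mk("a1", "A", paste0("c.5", ref5, ">", alt5), "autism", "de novo", "Pathogenic", 0.001, TRUE),
    mk("b1", "B", paste0("c.5", ref5, ">", alt5), "epilepsy", "de novo", "Likely pathogenic", NA),
    mk("a2", "A", paste0("c.9", ref9, ">", alt9), "autism"))
  st <- standardize_records(rec, NULL, m)
  dd <- deduplicate(st$records)
  expect_equal(dd$stats$n_records, 3)
  expect_equal(dd$stats$n_distinct, 2)
  expect_equal(dd$stats$n_duplicate_records, 1)
  expect_equal(dd$stats$n_records,
               dd$stats$n_distinct + dd$stats$n_duplicate_records)
  merged <- dd$catalog[dd$catalog$n_records == 2, ]
  expect_equal(merged$sources, "A,B")
  expect_equal(merged$n_sources, 2)
  expect_true(grepl("autism", merged$phenotype) && grepl("epilepsy", merged$phenotype))
  expect_setequal(strsplit(merged$reported_class, "|", fixed = TRUE)[[1]],
                  c("Pathogenic", "Likely pathogenic"))
  expect_true(grepl("reported_class", merged$conflict_fields))
  expect_equal(merged$af, 0.001)
  expect_equal(dd$stats$n_multi_source, 1)
  # per-source table
  ps <- dd$stats$per_source
  expect_equal(ps$n_exclusive[ps$source == "A"], 1)
  expect_equal(ps$n_exclusive[ps$source == "B"], 0)
  tab <- source_overlap_table(dd)
  expect_equal(tab$n_entries[tab$source == "Total"], 3)
  expect_equal(tab$n_variants[tab$source == "Total"], 2)
})

test_that("deduplicate output is invariant under record order", {
  set.seed(61)
  truth <- generate_catalog_truth(5, generate_transcript(5, n_exons = 3,
                                                         cds_codons = 80),
                                  exonic_phenotype_counts = c(CRD = 6, ASD = 4, NONE = 5),
                                  ndd_class_counts = c(missense = 7, nonsense = 2,
                                                       frameshift = 1),
                                  noncoding_phenotype_counts = c(ASD = 2, NONE = 2),
                                  origin_counts_ndd = c(de_novo = 8, inherited = 1,
                                                        unknown = 1),
                                  reported_counts_ndd = c(P = 4, LP = 2, VUS = 2,
                                                          LB = 1, NONE = 1))
  ex <- emit_source_exports(truth, 5, dir = NULL, n_records = 40)
  model <- attr(truth, "model")
  st <- standardize_records(ex$records, ex$chains, model)
  base <- deduplicate(st$records)
  for (k in 1:3) {
    perm <- st$records[sample(nrow(st$records)), , drop = FALSE]
    dd <- deduplicate(perm)
    expect_equal(dd$catalog, base$catalog)
    expect_equal(dd$stats$n_distinct, base$stats$n_distinct)
  }
})

test_that("minus-strand transcripts reverse-complement coordinate alleles", {
  # minus-strand single-exon model: genomic plus-strand alleles must be
  # complemented before transcript-space comparison
  cds <- "ATGGACTTGAGCTAA"
  n <- 6 + nchar(cds) + 9
  m <- transcript_model("TM", "TOY1", "chrT", "-",
                        exons = data.frame(start = 2001, end = 2000 + n),
                        cds_start = 2000 + 9 + 1,
                        cds_end = 2000 + 9 + nchar(cds), cds_sequence = cds)
  # c.4 is G; its genomic plus-strand base is C at cds_end - 3
  gpos <- cdna_to_genomic(m, cdna_coordinate("cds", 4))
  rec <- data.frame(source = "S", record_id = "m1", assembly = "GRCh37",
                    chrom = "chrT", pos = gpos, ref = "C", alt = "T",
                    hgvs_c = NA_character_, variant_class = "snv_like",
                    phenotype = NA, origin_raw = NA, trio = FALSE,
                    reported_class = NA, af = NA_real_, stringsAsFactors = FALSE)
  out <- standardize_records(rec, NULL, m)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$hgvs_norm, "c.4G>A")
})
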