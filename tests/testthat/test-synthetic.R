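# Synthetic generator: determinism, validity-by-construction, export
# emission and small-scale parameter recovery through the real pipeline.

# Shared small configuration (kept small so rejection sampling is fast).
small_truth <- function(seed) {
  generate_catalog_truth(
    seed, generate_transcript(seed, n_exons = 3, cds_codons = 80),
    exonic_phenotype_counts = c(CRD = 6, ASD = 4, NON_NDD = 2, NONE = 4),
    ndd_class_counts = c(missense = 5, nonsense = 2, frameshift = 2,
                         synonymous = 1),
    noncoding_phenotype_counts = c(ASD = 2, CONTROL = 1, NONE = 2),
    origin_counts_ndd = c(de_novo = 7, inherited = 1, unknown = 2),
    reported_counts_ndd = c(P = 4, LP = 2, VUS = 2, LB = 1, NONE = 1))
}

test_that("mix_to_counts apportions exactly by largest remainder", {
  expect_equal(mix_to_counts(10, c(a = 0.5, b = 0.5)), c(a = 5L, b = 5L))
  expect_equal(sum(mix_to_counts(7, c(a = 1/3, b = 1/3, c = 1/3))), 7L)
  expect_equal(mix_to_counts(3, c(a = 0.55, b = 0.45)), c(a = 2L, b = 1L))
  expect_error(mix_to_counts(10, c(a = 0.5, b = 0.4)), "sum to 1")
  set.seed(3)
  for (k in 1:20) {
    p <- runif(4); p <- p / sum(p)
    n <- sample(1:500, 1)
    counts <- mix_to_counts(n, setNames(p, letters[1:4]))
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - n * p) < 1))
  }
})

test_that("generate_transcript builds valid models and validates inputs", {
  m <- generate_transcript(42)
  expect_s3_class(m, "transcript_model")
  expect_equal(nchar(m$cds_sequence), 180)
  expect_equal(substr(m$cds_sequence, 1, 3), "ATG")
  expect_equal(sum(m$exons$end - m$exons$start + 1), 30 + 180 + 40)
  expect_identical(generate_transcript(42), generate_transcript(42))
  expect_false(identical(generate_transcript(42)$cds_sequence,
                         generate_transcript(43)$cds_sequence))
  expect_error(generate_transcript(1, cds_codons = 1), "cds_codons")
  expect_error(generate_transcript(1, n_exons = 0), "n_exons")
})

test_that("generator calls never disturb the caller's RNG stream", {
  set.seed(99)
  a1 <- runif(1)
  set.seed(99)
  invisible(generate_transcript(5))
  invisible(small_truth(5))
  a2 <- runif(1)
  expect_identical(a1, a2)
})

test_that("truth ledger is deterministic, distinct, and oracle-verified", {
  t1 <- small_truth(11)
  t2 <- small_truth(11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "expected"), attr(t2, "expected"))
  expect_false(identical(as.data.frame(t1), as.data.frame(small_truth(12))))
  expect_equal(anyDuplicated(t1$key), 0)
  model <- attr(t1, "model")
  # every exonic row's claimed class is what the engine actually calls,
  # and the recorded genomic position matches the coordinate mapping
  for (i in which(t1$region == "exonic_cds")) {
    v <- parse_c(t1$hgvs_c[i])
    cc <- call_consequence(model, v)
    expect_equal(cc$klass, t1$klass[i], info = t1$hgvs_c[i])
    expect_equal(cdna_to_genomic(model, v$start), t1$g_pos[i])
  }
  # noncoding rows really are noncoding
  for (i in which(t1$region != "exonic_cds")) {
    v <- parse_c(t1$hgvs_c[i])
    expect_equal(call_consequence(model, v)$klass, "noncoding")
  }
  # expected bookkeeping is internally consistent
  exp <- attr(t1, "expected")
  expect_equal(exp$n_distinct, nrow(t1))
  expect_equal(exp$n_exonic + exp$n_noncoding, exp$n_distinct)
  expect_equal(sum(exp$exonic_phenotype_counts), exp$n_exonic)
  expect_equal(sum(exp$ndd_class_counts), exp$n_exonic_ndd)
  expect_equal(exp$n_ndd_catalog,
               exp$n_exonic_ndd - sum(exp$ndd_class_counts["synonymous"],
                                      na.rm = TRUE))
})

test_that("count mismatches are rejected", {
  expect_error(generate_catalog_truth(
    1, generate_transcript(1, cds_codons = 40),
    exonic_phenotype_counts = c(CRD = 3, NONE = 1),
    ndd_class_counts = c(missense = 2),
    noncoding_phenotype_counts = NULL,
    origin_counts_ndd = c(de_novo = 3),
    reported_counts_ndd = c(P = 3)), "sum to the NDD exonic total")
  expect_error(generate_catalog_truth(
    1, generate_transcript(1, cds_codons = 40),
    exonic_phenotype_counts = c(CRD = 2, NONE = 1),
    ndd_class_counts = c(missense = 2),
    noncoding_phenotype_counts = NULL,
    origin_counts_ndd = c(de_novo = 1),
    reported_counts_ndd = c(P = 2)), "origin_counts_ndd")
  expect_error(generate_catalog_truth(
    1, generate_transcript(1, cds_codons = 40),
    exonic_phenotype_counts = c(CRD = -2, NONE = 1),
    ndd_class_counts = c(missense = -2),
    noncoding_phenotype_counts = NULL), "nonnegative")
})

test_that("emitted exports trace back to the truth and respect totals", {
  truth <- small_truth(21)
  n_distinct <- nrow(truth)
  ex <- emit_source_exports(truth, 21, n_records = n_distinct + 12)
  expect_equal(nrow(ex$records), n_distinct + 12)
  expect_identical(ex$records,
                   emit_source_exports(truth, 21,
                                       n_records = n_distinct + 12)$records)
  expect_error(emit_source_exports(truth, 21, n_records = n_distinct - 1),
               "at least")
  st <- standardize_records(ex$records, ex$chains, attr(truth, "model"))
  expect_equal(nrow(st$excluded), 0)
  expect_true(all(st$records$hgvs_norm %in% truth$hgvs_c))
  dd <- deduplicate(st$records)
  expect_equal(dd$stats$n_distinct, n_distinct)
  expect_equal(dd$stats$n_duplicate_records, 12)
  # zero-duplication profile: one record per truth variant
  ex0 <- emit_source_exports(truth, 21, n_records = n_distinct)
  dd0 <- deduplicate(standardize_records(ex0$records, ex0$chains,
                                         attr(truth, "model"))$records)
  expect_equal(dd0$stats$n_duplicate_records, 0)
  expect_equal(dd0$stats$n_distinct, n_distinct)
})

test_that("written export files round-trip through ingestion", {
  truth <- small_truth(33)
  dir <- withr::local_tempdir()
  ex <- emit_source_exports(truth, 33, dir = dir, n_records = nrow(truth) + 10)
  expect_true(file.exists(ex$chain_file))
  expect_true(all(file.exists(ex$manifest$path)))
  ing <- list()
  for (j in seq_len(nrow(ex$manifest))) {
    ing[[j]] <- ingest_source(ex$manifest$path[j], ex$manifest$schema[j],
                              ex$manifest$source[j])$records
  }
  rec <- do.call(rbind, ing)
  expect_equal(nrow(rec), nrow(ex$records))
  model <- read_transcript_config(file.path(dir, "transcript.cfg"))
  expect_equal(model$cds_sequence, attr(truth, "model")$cds_sequence)
  chains <- parse_chain(readLines(ex$chain_file))
  st <- standardize_records(rec, chains, model)
  expect_equal(nrow(st$excluded), 0)
  dd <- deduplicate(st$records)
  expect_equal(dd$stats$n_distinct, nrow(truth))
  expect_equal(dd$stats$n_records, nrow(truth) + 10)
})

test_that("pipeline recovers the ledger's expected counts exactly (small scale)", {
  truth <- small_truth(55)
  exp <- attr(truth, "expected")
  model <- attr(truth, "model")
  ex <- emit_source_exports(truth, 55, n_records = nrow(truth) + 15)
  st <- standardize_records(ex$records, ex$chains, model)
  dd <- deduplicate(st$records)
  b <- build_catalog(dd, model, excluded = st$excluded,
                     n_source_records = nrow(ex$records))
  s <- summarize_catalog(b)
  as_named <- function(df) setNames(df$n, df[[1]])
  expect_same_counts <- function(got, want) {
    want <- c(want)
    expect_setequal(names(got), names(want))
    nm <- sort(names(want))
    expect_equal(unname(as.integer(got[nm])), unname(as.integer(want[nm])))
  }
  expect_same_counts(as_named(s$phenotype), exp$exonic_phenotype_counts)
  expect_same_counts(as_named(s$consequence), exp$ndd_catalog_class_counts)
  expect_same_counts(as_named(s$origin), exp$ndd_catalog_origin_counts)
  nc <- table(ifelse(is.na(b$noncoding_table$phenotype_category),
                     "NO_PHENOTYPE_DATA", b$noncoding_table$phenotype_category))
  expect_same_counts(c(nc), exp$noncoding_phenotype_counts)
  expect_equal(s$ndd_share$n_ndd, exp$n_exonic_ndd)
  expect_equal(s$ndd_share$n_exonic, exp$n_exonic)
  n_syn <- sum(b$full$klass == "synonymous" & b$full$region == "exonic_cds")
  expect_equal(b$filter_steps$n,
               c(exp$n_distinct, exp$n_exonic, exp$n_exonic - n_syn,
                 exp$n_ndd_catalog))
})
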