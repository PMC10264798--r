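# Consequence engine: worked examples, translation vs the hand-written
# codon table, and large-scale equivalence against the brute-force
# translate-and-diff oracle.

toy_model <- function() make_cds_model("ATGGACTTGAGCTAA")  # M-D-L-S-*

test_that("toy CDS worked examples classify as printed", {
  m <- toy_model()
  cases <- list(
    list("c.4G>A", "missense", "p.Asp2Asn"),
    list("c.6C>T", "synonymous", "p.Asp2="),
    list("c.8T>A", "nonsense", "p.Leu3Ter"),
    list("c.5del", "frameshift", "p.Asp2Alafs*2"),
    list("c.4_6del", "inframe_del", "p.Asp2del"))
  for (cs in cases) {
    cc <- call_consequence(m, parse_c(cs[[1]]))
    expect_equal(cc$klass, cs[[2]], info = cs[[1]])
    expect_equal(cc$hgvs_p, cs[[3]], info = cs[[1]])
    expect_equal(cc$region, "exonic_cds")
  }
})

test_that("UTR and intronic variants get region labels only", {
  m <- toy_model()
  cc <- call_consequence(m, parse_c("c.*2T>G"))
  expect_equal(cc$region, "utr3"); expect_equal(cc$klass, "noncoding")
  expect_null(cc$protein_change)
  cc <- call_consequence(m, parse_c("c.-3G>A"))
  expect_equal(cc$region, "utr5")
  cc <- call_consequence(m, parse_c("c.4+7A>G"))
  expect_equal(cc$region, "intronic")
})

test_that("start-lost, stop-lost and inframe_ins are detected", {
  m <- toy_model()
  expect_equal(call_consequence(m, parse_c("c.2T>C"))$klass, "start_lost")
  expect_equal(call_consequence(m, parse_c("c.13T>C"))$klass, "stop_lost")
  cc <- call_consequence(m, parse_c("c.6_7insGCA"))
  expect_equal(cc$klass, "inframe_ins")
})

test_that("coding calls require a CDS sequence", {
  m <- make_t1()  # no cds_sequence
  expect_error(call_consequence(m, parse_c("c.4G>A")), "cds_sequence")
})

test_that("apply_variant rejects reference mismatches", {
  m <- toy_model()
  expect_error(apply_variant(m$cds_sequence, parse_c("c.4A>T")),
               class = "ctcfcat_ref_mismatch")
  expect_error(call_consequence(m, parse_c("c.4_6delAAA")),
               class = "ctcfcat_ref_mismatch")
})

test_that("translate_cds agrees with the hand-written codon table", {
  set.seed(51)
  for (k in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:60, 1), replace = TRUE),
               collapse = "")
    got <- translate_cds(s)
    ext <- oracle_translate_ext(s)
    want_stop <- endsWith(ext, "*")
    expect_equal(got$stop_reached, want_stop)
    expect_equal(got$aa, sub("\\*$", "", ext))
  }
  expect_error(translate_cds("ATGN"), "non-ACGT")
  expect_error(translate_cds(""), "empty")
})

test_that("classifier is equivalent to the brute-force oracle on >= 10^4 variants", {
  set.seed(52)
  n_total <- 0L
  bases <- c("A", "C", "G", "T")
  while (n_total < 10500L) {
    cds <- oracle_random_cds(sample(4:40, 1))
    m <- make_cds_model(cds)
    len <- nchar(cds)
    for (r in 1:60) {
      kind <- sample(c("sub", "del", "dup", "ins", "delins"), 1)
      p <- sample(1:len, 1)
      v <- switch(kind,
        sub = {
          ref <- substr(cds, p, p)
          cdna_variant("sub", cdna_coordinate("cds", p), ref = ref,
                       alt = sample(setdiff(bases, ref), 1))
        },
        del = , dup = {
          e <- min(len, p + sample(0:4, 1))
          cdna_variant(kind, cdna_coordinate("cds", p), cdna_coordinate("cds", e))
        },
        ins = {
          if (p == len) next
          cdna_variant("ins", cdna_coordinate("cds", p),
                       cdna_coordinate("cds", p + 1),
                       alt = paste(sample(bases, sample(1:4, 1), replace = TRUE),
                                   collapse = ""))
        },
        delins = {
          e <- min(len, p + sample(0:3, 1))
          cdna_variant("delins", cdna_coordinate("cds", p),
                       cdna_coordinate("cds", e),
                       alt = paste(sample(bases, sample(1:4, 1), replace = TRUE),
                                   collapse = ""))
        })
      vn <- normalize_3prime(cds, v)
      mut_impl <- apply_variant(cds, vn)
      mut_oracle <- oracle_apply(cds, v)
      expect_equal(mut_impl, mut_oracle)  # normalization preserves the edit
      cc <- call_consequence(m, v)
      want <- oracle_classify(cds, mut_oracle)
      expect_equal(cc$klass, want$kind,
                   info = paste(cds, format_c(v), "->", cc$hgvs_p))
      if (!is.na(want$first) && want$kind != "synonymous") {
        expect_equal(cc$protein_change$first_residue, want$first,
                     info = paste(cds, format_c(v)))
      }
      if (want$kind == "frameshift") {
        expect_equal(cc$protein_change$fs_term_offset, want$fs,
                     info = paste(cds, format_c(v)))
      }
      n_total <- n_total + 1L
    }
  }
  expect_gte(n_total, 10000L)
})

test_that("fs_term_offset equals 1 + (mutant stop index - first diff index)", {
  set.seed(53)
  found <- 0L
  while (found < 200L) {
    cds <- oracle_random_cds(sample(6:30, 1))
    m <- make_cds_model(cds)
    p <- sample(4:(nchar(cds) - 3), 1)
    v <- cdna_variant("del", cdna_coordinate("cds", p))
    cc <- call_consequence(m, v)
    if (cc$klass != "frameshift" || is.na(cc$protein_change$fs_term_offset)) next
    M <- oracle_translate_ext(oracle_apply(cds, v))
    stop_idx <- nchar(M)  # '*' position in the extended mutant string
    expect_equal(cc$protein_change$fs_term_offset,
                 1L + (stop_idx - cc$protein_change$first_residue))
    found <- found + 1L
  }
})

test_that("frame-preserving pure del/dup/ins are never frameshift and vice versa", {
  set.seed(54)
  for (k in 1:400) {
    cds <- oracle_random_cds(sample(6:30, 1))
    m <- make_cds_model(cds)
    len <- nchar(cds)
    p <- sample(4:(len - 6), 1)
    w <- sample(1:4, 1)
    kind <- sample(c("del", "dup", "ins"), 1)
    v <- if (kind == "ins") {
      cdna_variant("ins", cdna_coordinate("cds", p), cdna_coordinate("cds", p + 1),
                   alt = paste(rep("A", w), collapse = ""))
    } else {
      cdna_variant(kind, cdna_coordinate("cds", p),
                   cdna_coordinate("cds", p + w - 1))
    }
    cc <- call_consequence(m, v)
    if (cc$klass %in% c("start_lost")) next
    if (w %% 3 == 0) {
      expect_false(cc$klass == "frameshift", info = paste(cds, format_c(v)))
    } else {
      expect_true(cc$klass %in% c("frameshift", "nonsense"),
                  info = paste(cds, format_c(v)))
    }
  }
})

test_that("domain annotation rides along on consequence calls", {
  dm <- domain_map(data.frame(label = "ZFt", aa_start = 2L, aa_end = 3L,
                              category = "zinc_finger", cys = "2,3", his = "",
                              verified = FALSE, stringsAsFactors = FALSE),
                   protein_length = 4L)
  m <- toy_model()
  cc <- call_consequence(m, parse_c("c.4G>A"), domains = dm)
  expect_equal(cc$domain_label, "ZFt")
  expect_equal(cc$residue_role, "zinc_coordinating_cys")
})
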