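# Genomic intervals, transcript coordinate mapping, codon arithmetic,
# domain/residue-role annotation.

test_that("genomic_interval validates and measures 1-based closed spans", {
  expect_equal(interval_length(genomic_interval("chr16", 67596310, 67673088)),
               76779)
  expect_equal(interval_length(genomic_interval("chr16", 67644736, 67671775)),
               27040)
  expect_equal(interval_length(genomic_interval("chrT", 5, 5)), 1)
  expect_error(genomic_interval("chrT", 10, 9), "start")
  expect_error(genomic_interval("chrT", 1, 2, assembly = "hg18"))
})

test_that("interval_length equals brute-force position count", {
  set.seed(11)
  for (k in 1:50) {
    s <- sample(1:1000, 1); e <- s + sample(0:100, 1)
    expect_equal(interval_length(genomic_interval("chrT", s, e)),
                 length(seq(s, e)))
  }
})

test_that("T1 coordinate mapping matches worked examples", {
  m <- make_t1()
  co <- genomic_to_cdna(m, 121)
  expect_equal(co$kind, "cds"); expect_equal(co$base, 1L)
  co <- genomic_to_cdna(m, 201)
  expect_equal(co$kind, "cds"); expect_equal(co$base, 41L)
  co <- genomic_to_cdna(m, 165)
  expect_equal(co$kind, "intronic")
  expect_equal(co$base, 40L); expect_equal(co$offset, 5L)
  expect_equal(co$anchor_kind, "cds")
  co <- genomic_to_cdna(m, 245)
  expect_equal(co$kind, "utr3"); expect_equal(co$base, 5L)
  # inverses
  expect_equal(cdna_to_genomic(m, cdna_coordinate("cds", 1)), 121)
  expect_equal(cdna_to_genomic(m, cdna_coordinate("cds", 41)), 201)
  expect_equal(cdna_to_genomic(m, cdna_coordinate("utr3", 5)), 245)
  expect_error(genomic_to_cdna(m, 50), "outside")
  expect_error(genomic_to_cdna(m, 300), "outside")
})

test_that("region annotation matches worked examples", {
  m <- make_t1()
  expect_equal(annotate_position(m, 130), "exonic_cds")
  expect_equal(annotate_position(m, 110), "utr5")
  expect_equal(annotate_position(m, 180), "intronic")
  expect_equal(annotate_position(m, 245), "utr3")
})

test_that("intronic ties go to the upstream-in-transcript exon", {
  m <- make_t1()
  # intron is 161..200 (40 nt); midpoint tie at d5 = d3 = 20 -> pos 180
  co <- genomic_to_cdna(m, 180)
  expect_equal(co$offset, 20L)   # anchored +20 from the 5' exon
  co <- genomic_to_cdna(m, 181)
  expect_equal(co$offset, -20L)  # one past the tie -> downstream anchor
})

test_that("coordinate mapping round-trips exhaustively on toy models", {
  m <- make_t1()
  for (p in c(101:160, 201:260)) {
    expect_equal(cdna_to_genomic(m, genomic_to_cdna(m, p)), p)
  }
  # intronic positions round-trip through anchor+offset too
  for (p in 161:200) {
    expect_equal(cdna_to_genomic(m, genomic_to_cdna(m, p)), p)
  }
})

test_that("minus-strand models map coding bases in decreasing genomic order", {
  m <- transcript_model("T2", "TOY1", "chrT", "-",
                        exons = data.frame(start = c(201, 101), end = c(260, 160)),
                        cds_start = 121, cds_end = 240)
  pos <- c(260:201, 160:101)  # transcript order
  keys <- vapply(pos, function(p) {
    co <- genomic_to_cdna(m, p)
    cdna_to_genomic(m, co)
  }, numeric(1))
  expect_equal(keys, pos)
  cds_bases <- Filter(function(p) genomic_to_cdna(m, p)$kind == "cds", pos)
  cvals <- vapply(cds_bases, function(p) genomic_to_cdna(m, p)$base, integer(1))
  expect_true(all(diff(cvals) == 1))  # increasing c. along decreasing genomic
  expect_equal(genomic_to_cdna(m, 240)$base, 1L)
})

test_that("random valid models round-trip everywhere", {
  set.seed(21)
  for (k in 1:10) {
    m <- generate_transcript(seed = k, n_exons = sample(1:4, 1),
                             cds_codons = sample(5:30, 1))
    span <- c(min(m$exons$start), max(m$exons$end))
    for (p in span[1]:span[2]) {
      expect_equal(cdna_to_genomic(m, genomic_to_cdna(m, p)), p)
    }
  }
})

test_that("codon arithmetic matches worked examples and its identity", {
  expect_equal(codon_of(1456), list(residue = 486, codon_offset = 1))
  expect_equal(codon_of(1430), list(residue = 477, codon_offset = 2))
  expect_equal(codon_of(3), list(residue = 1, codon_offset = 3))
  expect_error(codon_of(0))
  expect_error(codon_of(10, cds_length = 9), "exceeds")
  for (p in 1:300) {
    co <- codon_of(p)
    expect_equal(3 * (co$residue - 1) + co$codon_offset, p)
  }
})

test_that("transcript model invariants are enforced", {
  exons <- data.frame(start = c(101, 201), end = c(160, 260))
  expect_error(transcript_model("T", "G", "chrT", "+",
                                data.frame(start = c(101, 150), end = c(160, 260)),
                                121, 240), "overlap")
  expect_error(transcript_model("T", "G", "chrT", "+", exons, 170, 240),
               "inside exons")
  # bad CDS sequences
  expect_silent(make_cds_model("ATGAAATAA"))
  expect_error(make_cds_model("ATGAAAAAA"), "stop")
  expect_error(make_cds_model("TTGAAATAA"), "ATG")
  expect_error(make_cds_model("ATGTAATAA"), "internal stop")
  expect_error(make_cds_model("ATGAATAA"), "multiple of 3")
})

test_that("domain map and residue roles follow the configuration", {
  dm <- domain_map(data.frame(
    label = c("ZFt"), aa_start = 10L, aa_end = 32L, category = "zinc_finger",
    cys = "12,15", his = "28,32", helix_anchor = 20L, rbd = FALSE,
    verified = TRUE, stringsAsFactors = FALSE), protein_length = 50L)
  expect_equal(residue_role(dm, 12), "zinc_coordinating_cys")
  expect_equal(residue_role(dm, 15), "zinc_coordinating_cys")
  expect_equal(residue_role(dm, 28), "zinc_coordinating_his")
  expect_equal(residue_role(dm, 19), "dna_contact")  # anchor - 1
  expect_equal(residue_role(dm, 22), "dna_contact")  # anchor + 2
  expect_equal(residue_role(dm, 23), "dna_contact")  # anchor + 3
  expect_equal(residue_role(dm, 26), "dna_contact")  # anchor + 6
  expect_equal(residue_role(dm, 21), "none")
  expect_equal(domain_of(dm, 11), "ZFt")
  expect_equal(domain_of(dm, 40), "none")
  expect_error(domain_of(dm, 51), "range")
  # missing coordinating indices on a verified ZF is a config error
  expect_error(domain_map(data.frame(label = "Z", aa_start = 1L, aa_end = 30L,
                                     category = "zinc_finger", cys = "2",
                                     his = "10,14", verified = TRUE),
                          protein_length = 40L), "exactly 2")
})

test_that("CTCF default domain map carries the published spans", {
  dm <- ctcf_domains()
  expect_equal(dm$protein_length, 726L)
  expect_equal(domain_of(dm, 226), "YDF")
  expect_equal(residue_role(dm, 226), "ydf")
  expect_equal(domain_of(dm, 270), "ZF1")
  expect_equal(residue_role(dm, 270), "rbd")
  expect_equal(domain_of(dm, 540), "ZF10")
  expect_equal(domain_of(dm, 300), "linker")  # between ZF1 and ZF10
  expect_equal(domain_of(dm, 600), "C_term")
  expect_equal(domain_of(dm, 100), "N_term")
})
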