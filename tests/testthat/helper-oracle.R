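# Independent test oracles. The codon table below is hand-written from
# the standard-code wheel (not taken from Biostrings) so translation
# tests exercise two independently-sourced tables.

ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

ORACLE_SENSE <- names(ORACLE_CODONS)[ORACLE_CODONS != "*"]
ORACLE_STOPS <- names(ORACLE_CODONS)[ORACLE_CODONS == "*"]

# Translate up to (excluding) the first stop; appends "*" when a stop
# was reached so stop shifts participate in diffs.
oracle_translate_ext <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  codons <- substring(seq, seq(1, by = 3, length.out = n),
                      seq(3, by = 3, length.out = n))
  aa <- unname(ORACLE_CODONS[codons])
  stop_at <- match("*", aa)
  if (is.na(stop_at)) paste(aa, collapse = "")
  else paste0(paste(aa[seq_len(stop_at - 1)], collapse = ""), "*")
}

# Independent variant application using split character vectors.
oracle_apply <- function(cds, v) {
  x <- strsplit(cds, "")[[1]]
  s <- v$start$base; e <- v$end$base
  out <- switch(v$kind,
    sub = { x[s] <- v$alt; x },
    del = x[-(s:e)],
    dup = append(x, x[s:e], after = e),
    ins = append(x, strsplit(v$alt, "")[[1]], after = s),
    delins = append(x[-(s:e)], strsplit(v$alt, "")[[1]], after = s - 1))
  paste(out, collapse = "")
}

# Brute-force classification by full translate-and-diff.
oracle_classify <- function(cds, mutant) {
  if (substr(mutant, 1, 3) != "ATG") {
    return(list(kind = "start_lost", first = 1L, fs = NA_integer_))
  }
  W <- oracle_translate_ext(cds)
  M <- oracle_translate_ext(mutant)
  if (W == M) return(list(kind = "synonymous", first = NA_integer_, fs = NA_integer_))
  wl <- nchar(W); ml <- nchar(M)
  i <- 1L
  while (i <= min(wl, ml) && substr(W, i, i) == substr(M, i, i)) i <- i + 1L
  if (substr(M, i, i) == "*") return(list(kind = "nonsense", first = i, fs = NA_integer_))
  len_delta <- (nchar(mutant) - nchar(cds)) %% 3L
  if (len_delta != 0L) {
    fs <- if (substr(M, ml, ml) == "*") ml - i + 1L else NA_integer_
    return(list(kind = "frameshift", first = i, fs = fs))
  }
  if (substr(W, i, i) == "*") return(list(kind = "stop_lost", first = i, fs = NA_integer_))
  if (wl == ml) return(list(kind = "missense", first = i, fs = NA_integer_))
  if (ml < wl) return(list(kind = "inframe_del", first = i, fs = NA_integer_))
  list(kind = "inframe_ins", first = i, fs = NA_integer_)
}

# Random valid CDS from the hand-written table.
oracle_random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(ORACLE_SENSE, n_codons - 2, replace = TRUE), collapse = ""),
         sample(ORACLE_STOPS, 1))
}

# The spec-style toy transcript T1: plus strand, exon1 chrT:101-160,
# exon2 chrT:201-260, CDS genomic span 121-240 (no CDS sequence).
make_t1 <- function() {
  transcript_model("T1", "TOY1", "chrT", "+",
                   exons = data.frame(start = c(101, 201), end = c(160, 260)),
                   cds_start = 121, cds_end = 240)
}

# Single-exon plus-strand model wrapping a CDS with small UTRs.
make_cds_model <- function(cds, utr5 = 6, utr3 = 9) {
  n <- utr5 + nchar(cds) + utr3
  transcript_model("TX1.1", "TOY1", "chrT", "+",
                   exons = data.frame(start = 1001, end = 1000 + n),
                   cds_start = 1000 + utr5 + 1,
                   cds_end = 1000 + utr5 + nchar(cds),
                   cds_sequence = cds)
}

# Per-base expansion of a chain: brute-force source->target table
# (0-based on both sides).
oracle_expand_chain <- function(ch) {
  s <- numeric(0); t <- numeric(0)
  s_cur <- ch$s_start; t_cur <- ch$t_start
  for (j in seq_len(nrow(ch$blocks))) {
    sz <- ch$blocks$size[j]
    s <- c(s, s_cur + seq_len(sz) - 1)
    t <- c(t, t_cur + seq_len(sz) - 1)
    s_cur <- s_cur + sz + ch$blocks$s_gap[j]
    t_cur <- t_cur + sz + ch$blocks$t_gap[j]
  }
  data.frame(s0 = s, t0 = t)
}

# Random valid single-chromosome chain (plus-strand both sides).
oracle_random_chain <- function(n_blocks = 3, id = "1", score = 100) {
  sizes <- sample(1:20, n_blocks, replace = TRUE)
  s_gap <- if (n_blocks > 1) sample(0:15, n_blocks - 1, replace = TRUE) else numeric(0)
  t_gap <- if (n_blocks > 1) sample(0:15, n_blocks - 1, replace = TRUE) else numeric(0)
  s_start <- sample(0:50, 1); t_start <- sample(0:50, 1)
  s_end <- s_start + sum(sizes) + sum(s_gap)
  t_end <- t_start + sum(sizes) + sum(t_gap)
  structure(list(score = score, s_name = "chrS", s_size = s_end + 10,
                 s_strand = "+", s_start = s_start, s_end = s_end,
                 t_name = "chrQ", t_size = t_end + 10, t_strand = "+",
                 t_start = t_start, t_end = t_end, id = id,
                 blocks = data.frame(size = sizes, s_gap = c(s_gap, 0),
                                     t_gap = c(t_gap, 0))),
            class = "chain_alignment")
}
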