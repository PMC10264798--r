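# Amino-acid code tables ------------------------------------------------

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

#' Three-letter amino-acid code
#' @param aa One-letter amino-acid code(s); `"*"` maps to `"Ter"`.
#' @return Three-letter code(s).
#' @export
aa_three <- function(aa) {
  out <- .AA3[strsplit(paste(aa, collapse = ""), "")[[1]]]
  if (anyNA(out)) stop("unknown amino-acid code in '", paste(aa, collapse = ""), "'")
  paste(out, collapse = "")
}

# cDNA variant -----------------------------------------------------------

#' Construct a coding-DNA variant description
#'
#' The structured form of the HGVS c. subset handled by this package:
#' substitutions, deletions, duplications, insertions and
#' deletion-insertions, addressed by [cdna_coordinate()]s (coding, UTR
#' or intronic).
#'
#' @param kind `"sub"`, `"del"`, `"dup"`, `"ins"` or `"delins"`.
#' @param start,end [cdna_coordinate()]s; `end` defaults to `start`.
#' @param ref Reference bases (may be `""` when unstated).
#' @param alt Alternate bases (`""` for del/dup).
#' @return Object of class `cdna_variant`.
#' @export
cdna_variant <- function(kind, start, end = start, ref = "", alt = "") {
  kind <- match.arg(kind, c("sub", "del", "dup", "ins", "delins"))
  stopifnot(inherits(start, "cdna_coordinate"), inherits(end, "cdna_coordinate"))
  ref <- toupper(ref); alt <- toupper(alt)
  if (.cdna_key(start) > .cdna_key(end)) {
    stop("variant start must not follow end in transcript order")
  }
  if (kind == "sub" && (nchar(ref) != 1 || nchar(alt) != 1)) {
    stop("substitution requires single-base ref and alt")
  }
  if (kind == "ins") {
    if (!nzchar(alt)) stop("insertion requires inserted bases")
    if (.cdna_key(end) - .cdna_key(start) > 1 + 1e-9) {
      stop("insertion flanks must be adjacent")
    }
  }
  structure(list(kind = kind, start = start, end = end, ref = ref, alt = alt),
            class = "cdna_variant")
}

.ADDR_RE <- "([-*]?)(\\d+)([+-]\\d+)?"

.parse_addr <- function(s) {
  m <- regmatches(s, regexec(paste0("^", .ADDR_RE, "$"), s))[[1]]
  if (!length(m)) stop("HGVS parse error: bad position token '", s, "'")
  kind <- switch(m[2], "-" = "utr5", "*" = "utr3", "cds")
  base <- as.integer(m[3])
  if (nzchar(m[4])) {
    cdna_coordinate("intronic", base, offset = as.integer(m[4]), anchor_kind = kind)
  } else {
    cdna_coordinate(kind, base)
  }
}

#' Parse an HGVS coding-DNA description
#'
#' Supports the subset used throughout the catalog: substitutions
#' (`c.1456C>T`), deletions (`c.804_805del`, with or without stated
#' bases), duplications (`c.604dupA`), insertions (`c.4_5insGGA`) and
#' deletion-insertions (`c.4_6delinsTT`), at coding, UTR (`c.-N`,
#' `c.*N`) and intronic (`c.N+M`) addresses.
#'
#' @param text A string beginning `"c."`.
#' @return A [cdna_variant()].
#' @export
parse_c <- function(text) {
  text <- trimws(text)
  if (!startsWith(text, "c.")) stop("HGVS parse error: expected 'c.' prefix in '", text, "'")
  body <- substr(text, 3, nchar(text))
  m <- regmatches(body, regexec(
    paste0("^", .ADDR_RE, "(?:_", .ADDR_RE, ")?(.*)$"), body))[[1]]
  if (!length(m)) stop("HGVS parse error: cannot parse '", text, "'")
  start <- .parse_addr(paste0(m[2], m[3], m[4]))
  end <- if (nzchar(m[6])) .parse_addr(paste0(m[5], m[6], m[7])) else start
  tail <- m[8]
  if (grepl("^(inv|con|\\[|=)", tail) || grepl("^[ACGT]*\\[", tail)) {
    stop("unsupported HGVS kind in '", text,
         "' (inversions, conversions and repeats are not handled)")
  }
  if (grepl("^[ACGTacgt]>[ACGTacgt]$", tail)) {
    parts <- strsplit(toupper(tail), ">", fixed = TRUE)[[1]]
    return(cdna_variant("sub", start, end, ref = parts[1], alt = parts[2]))
  }
  if (grepl("^delins[ACGTacgt]+$", tail)) {
    return(cdna_variant("delins", start, end, alt = toupper(sub("^delins", "", tail))))
  }
  if (grepl("^del[ACGTacgt]*$", tail)) {
    return(cdna_variant("del", start, end, ref = sub("^DEL", "", toupper(tail))))
  }
  if (grepl("^dup[ACGTacgt]*$", tail)) {
    return(cdna_variant("dup", start, end, ref = sub("^DUP", "", toupper(tail))))
  }
  if (grepl("^ins[ACGTacgt]+$", tail)) {
    return(cdna_variant("ins", start, end, alt = sub("^INS", "", toupper(tail))))
  }
  stop("HGVS parse error: unrecognized change '", tail, "' in '", text, "'")
}

#' Format a coding-DNA variant as HGVS
#'
#' Reference bases are kept in the output when known (`c.604dupA`);
#' otherwise the bare form is emitted (`c.804_805del`).
#'
#' @param v A [cdna_variant()].
#' @return HGVS string beginning `"c."`.
#' @export
format_c <- function(v) {
  stopifnot(inherits(v, "cdna_variant"))
  single <- identical(.cdna_addr(v$start), .cdna_addr(v$end))
  addr <- if (single) .cdna_addr(v$start) else
    paste0(.cdna_addr(v$start), "_", .cdna_addr(v$end))
  tail <- switch(v$kind,
                 sub = paste0(v$ref, ">", v$alt),
                 del = paste0("del", v$ref),
                 dup = paste0("dup", v$ref),
                 ins = paste0("ins", v$alt),
                 delins = paste0("delins", v$alt))
  paste0("c.", addr, tail)
}

#' @export
print.cdna_variant <- function(x, ...) {
  cat(format_c(x), "\n")
  invisible(x)
}

# 3' normalization -------------------------------------------------------

#' Shift a deletion/duplication/insertion to its most 3' representation
#'
#' The HGVS 3' rule: in repetitive sequence an ambiguous del/dup/ins
#' must be described at the most 3' position that leaves the mutated
#' sequence unchanged. Substitutions and delins are returned untouched.
#' Only variants fully addressed in coding bases of `cds_seq` are
#' shifted; the operation is idempotent and, when stated, the reference
#' bases are validated against the sequence.
#'
#' @param cds_seq Spliced CDS nucleotide string.
#' @param v A [cdna_variant()].
#' @return The normalized [cdna_variant()]; an insertion that exactly
#'   duplicates the adjacent upstream bases is rewritten as a `dup`.
#' @export
normalize_3prime <- function(cds_seq, v) {
  stopifnot(inherits(v, "cdna_variant"))
  if (is.null(cds_seq) || !nzchar(cds_seq[1])) return(v)
  if (!v$kind %in% c("del", "dup", "ins")) return(v)
  if (v$start$kind != "cds" || v$end$kind != "cds") return(v)
  seq <- toupper(cds_seq)
  len <- nchar(seq)
  s <- v$start$base; e <- v$end$base
  if (e > len) stop("variant ", format_c(v), " beyond CDS length ", len)
  if (v$kind %in% c("del", "dup")) {
    span <- substr(seq, s, e)
    if (nzchar(v$ref) && v$ref != span) {
      stop_ref_mismatch(format_c(v), v$ref, span)
    }
    while (e < len && substr(seq, s, s) == substr(seq, e + 1, e + 1)) {
      s <- s + 1L; e <- e + 1L
    }
    return(cdna_variant(v$kind, cdna_coordinate("cds", s),
                        cdna_coordinate("cds", e), ref = substr(seq, s, e)))
  }
  # insertion between p and p+1
  p <- s
  alt <- v$alt
  while (p < len && substr(alt, 1, 1) == substr(seq, p + 1, p + 1)) {
    alt <- paste0(substr(alt, 2, nchar(alt)), substr(alt, 1, 1))
    p <- p + 1L
  }
  k <- nchar(alt)
  if (p >= k && substr(seq, p - k + 1, p) == alt) {
    # insertion duplicating the adjacent bases: write as dup
    return(cdna_variant("dup", cdna_coordinate("cds", p - k + 1),
                        cdna_coordinate("cds", p), ref = alt))
  }
  cdna_variant("ins", cdna_coordinate("cds", p),
               cdna_coordinate("cds", p + 1L), alt = alt)
}

stop_ref_mismatch <- function(desc, stated, found) {
  cond <- structure(
    class = c("ctcfcat_ref_mismatch", "error", "condition"),
    list(message = paste0("reference mismatch for ", desc, ": stated '",
                          stated, "' but sequence has '", found, "'"),
         call = sys.call(-1)))
  stop(cond)
}

# Protein change ---------------------------------------------------------

#' Construct a protein-change description
#'
#' @param kind One of `"missense"`, `"synonymous"`, `"nonsense"`,
#'   `"frameshift"`, `"inframe_del"`, `"inframe_ins"`, `"start_lost"`,
#'   `"stop_lost"`, `"no_protein"`.
#' @param first_residue 1-based index of the first affected residue.
#' @param ref_aa,alt_aa One-letter codes (ref/alt at that residue).
#' @param fs_term_offset For frameshifts, the N of `fs*N`: the position
#'   of the new stop counting the first changed residue as 1 (`NA` when
#'   no stop is reached in the shifted frame). Must be >= 2: a
#'   frameshift whose first affected codon is itself a stop is a
#'   nonsense change, not a frameshift.
#' @param last_residue For in-frame deletions, the last deleted residue.
#' @param last_ref_aa One-letter code of the residue at `last_residue`.
#' @return Object of class `protein_change`.
#' @export
protein_change <- function(kind, first_residue, ref_aa = "", alt_aa = "",
                           fs_term_offset = NA_integer_,
                           last_residue = NA_integer_, last_ref_aa = "") {
  kind <- match.arg(kind, c("missense", "synonymous", "nonsense", "frameshift",
                            "inframe_del", "inframe_ins", "start_lost",
                            "stop_lost", "no_protein"))
  if (kind != "frameshift" && !is.na(fs_term_offset)) {
    stop("fs_term_offset may be set only for frameshifts")
  }
  if (kind == "frameshift" && !is.na(fs_term_offset) && fs_term_offset < 2) {
    stop("fs_term_offset must be >= 2 (an immediate stop is a nonsense change)")
  }
  structure(list(kind = kind, first_residue = as.integer(first_residue),
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 fs_term_offset = as.integer(fs_term_offset),
                 last_residue = as.integer(last_residue),
                 last_ref_aa = last_ref_aa),
            class = "protein_change")
}

#' Format a protein change in HGVS p. style
#'
#' Three-letter codes with `Ter` for stops, the style used throughout
#' the catalog: `p.Asp2Asn`, `p.Val6=`, `p.Gln486Ter`, `p.Asp2Alafs*2`
#' (`fs*?` when no downstream stop exists), `p.Asp2del`,
#' `p.Asp2_Leu4del`, `p.Met1?`.
#'
#' @param pc A [protein_change()].
#' @return HGVS protein string.
#' @export
format_p <- function(pc) {
  stopifnot(inherits(pc, "protein_change"))
  r <- pc$first_residue
  ref3 <- if (nzchar(pc$ref_aa)) aa_three(pc$ref_aa) else ""
  alt3 <- if (nzchar(pc$alt_aa)) aa_three(pc$alt_aa) else ""
  switch(pc$kind,
         missense   = paste0("p.", ref3, r, alt3),
         synonymous = paste0("p.", ref3, r, "="),
         nonsense   = paste0("p.", ref3, r, "Ter"),
         frameshift = paste0("p.", ref3, r, alt3, "fs*",
                             if (is.na(pc$fs_term_offset)) "?" else pc$fs_term_offset),
         inframe_del = if (is.na(pc$last_residue) || pc$last_residue == r) {
           paste0("p.", ref3, r, "del")
         } else {
           paste0("p.", ref3, r, "_", aa_three(pc$last_ref_aa), pc$last_residue, "del")
         },
         inframe_ins = paste0("p.", ref3, r, "_", aa_three(pc$last_ref_aa),
                              pc$last_residue, "ins", alt3),
         start_lost = "p.Met1?",
         stop_lost  = paste0("p.Ter", r, alt3, "ext*?"),
         no_protein = "p.0")
}

#' @export
print.protein_change <- function(x, ...) {
  cat(format_p(x), "\n")
  invisible(x)
}
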