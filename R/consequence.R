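# Protein-consequence engine: apply a normalized coding variant to the
# CDS, translate both alleles with the standard nuclear code, and
# classify the change (including the frameshift termination offset).

#' Apply a coding variant to a CDS sequence
#'
#' @param cds_seq Spliced CDS nucleotide string.
#' @param v A [cdna_variant()] addressed entirely in coding bases.
#' @return The edited nucleotide string. Stated reference bases are
#'   checked against the sequence.
#' @export
apply_variant <- function(cds_seq, v) {
  stopifnot(inherits(v, "cdna_variant"))
  if (v$start$kind != "cds" || v$end$kind != "cds") {
    stop("apply_variant requires a variant addressed in coding bases")
  }
  seq <- toupper(cds_seq)
  len <- nchar(seq)
  s <- v$start$base; e <- v$end$base
  # an insertion between the last CDS base and the next position is a
  # legal append (reachable by 3'-shifting an interior insertion)
  if (e > len && !(v$kind == "ins" && s == len)) {
    stop("variant ", format_c(v), " beyond CDS length ", len)
  }
  span <- substr(seq, s, e)
  check_ref <- function(stated) {
    if (nzchar(stated) && stated != span) stop_ref_mismatch(format_c(v), stated, span)
  }
  switch(v$kind,
         sub = {
           check_ref(v$ref)
           paste0(substr(seq, 1, s - 1), v$alt, substr(seq, s + 1, len))
         },
         del = {
           check_ref(v$ref)
           paste0(substr(seq, 1, s - 1), substr(seq, e + 1, len))
         },
         dup = {
           check_ref(v$ref)
           paste0(substr(seq, 1, e), span, substr(seq, e + 1, len))
         },
         ins = {
           paste0(substr(seq, 1, s), v$alt, substr(seq, s + 1, len))
         },
         delins = {
           check_ref(v$ref)
           paste0(substr(seq, 1, s - 1), v$alt, substr(seq, e + 1, len))
         })
}

# Codon table from Biostrings (standard nuclear code), cached at load.
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate a nucleotide sequence until the first stop codon
#'
#' Successive codons are translated with the standard nuclear code; a
#' trailing partial codon is ignored. Translation stops at (and
#' excludes) the first stop codon.
#'
#' @param seq Nucleotide string (A/C/G/T only).
#' @return List with `aa` (one-letter protein string, stop excluded)
#'   and `stop_reached` (logical).
#' @export
translate_cds <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("cannot translate an empty sequence")
  if (grepl("[^ACGT]", seq)) stop("non-ACGT character in sequence")
  n_codon <- nchar(seq) %/% 3
  if (n_codon == 0) return(list(aa = "", stop_reached = FALSE))
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(.codon_table()[codons])
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) {
    list(aa = paste(aa[seq_len(stop_at - 1L)], collapse = ""), stop_reached = TRUE)
  } else {
    list(aa = paste(aa, collapse = ""), stop_reached = FALSE)
  }
}

#' Call the protein-level consequence of a cDNA variant
#'
#' UTR and intronic variants receive a region label only
#' (`klass = "noncoding"`); no splice-effect prediction is attempted.
#' Coding variants are 3'-normalized, applied to the CDS, and both
#' alleles are translated and compared: identical proteins are
#' synonymous; a single substituted residue is missense (nonsense when
#' the new residue is a stop); frame-preserving deletions/insertions
#' are in-frame events; frame-changing edits are frameshifts whose
#' `fs*N` offset counts the first changed residue as 1. A frameshift
#' whose first affected codon becomes a stop is reported as nonsense at
#' that residue. Edits destroying the initiator ATG are start-lost;
#' frame-preserving edits removing the stop are stop-lost.
#'
#' @param model A [transcript_model()] carrying `cds_sequence` (needed
#'   for coding calls).
#' @param v A [cdna_variant()].
#' @param domains Optional [domain_map()]; when supplied, the call is
#'   annotated with the domain label and residue role of the first
#'   affected residue.
#' @return Object of class `consequence_call` with fields `region`,
#'   `klass`, `protein_change` (or `NULL`), `hgvs_c`, `hgvs_p`,
#'   `domain_label`, `residue_role`.
#' @export
call_consequence <- function(model, v, domains = NULL) {
  stopifnot(inherits(v, "cdna_variant"))
  kinds <- c(v$start$kind, v$end$kind)
  region <- if (all(kinds == "cds")) {
    "exonic_cds"
  } else if (any(kinds == "intronic")) {
    "intronic"
  } else if (any(kinds == "utr5")) {
    "utr5"
  } else {
    "utr3"
  }
  if (region != "exonic_cds") {
    return(structure(list(region = region, klass = "noncoding",
                          protein_change = NULL, hgvs_c = format_c(v),
                          hgvs_p = NA_character_, domain_label = NA_character_,
                          residue_role = NA_character_),
                     class = "consequence_call"))
  }
  cds <- model$cds_sequence
  if (is.null(cds)) {
    stop("transcript model carries no cds_sequence; coding consequences ",
         "cannot be called")
  }
  v <- normalize_3prime(cds, v)
  mutant <- apply_variant(cds, v)
  pc <- .classify_coding(cds, mutant, v)
  hgvs_p <- format_p(pc)
  lab <- NA_character_; role <- NA_character_
  if (!is.null(domains) && !pc$kind %in% c("no_protein", "start_lost") &&
      pc$first_residue <= domains$protein_length) {
    lab <- domain_of(domains, pc$first_residue)
    role <- residue_role(domains, pc$first_residue)
  }
  structure(list(region = region, klass = pc$kind, protein_change = pc,
                 hgvs_c = format_c(v), hgvs_p = hgvs_p,
                 domain_label = lab, residue_role = role),
            class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("%s | %s | %s%s\n", x$hgvs_c, x$klass,
              ifelse(is.na(x$hgvs_p), x$region, x$hgvs_p),
              if (!is.na(x$domain_label)) paste0(" [", x$domain_label, "]") else ""))
  invisible(x)
}

# Core classifier on wild-type vs mutant CDS strings.
.classify_coding <- function(cds, mutant, v) {
  if (substr(mutant, 1, 3) != "ATG") {
    return(protein_change("start_lost", 1L, ref_aa = "M"))
  }
  wt <- translate_cds(cds)
  mt <- translate_cds(mutant)
  # extended strings carry '*' when a stop was reached, so stop gains,
  # losses and shifts participate in the residue-wise diff
  W <- paste0(wt$aa, if (wt$stop_reached) "*")
  M <- paste0(mt$aa, if (mt$stop_reached) "*")
  if (W == M) {
    res <- codon_of(v$start$base)$residue
    aa <- .aa_at(W, res)
    return(protein_change("synonymous", res, ref_aa = aa, alt_aa = aa))
  }
  wl <- nchar(W); ml <- nchar(M)
  nmin <- min(wl, ml)
  i <- 1L
  while (i <= nmin && substr(W, i, i) == substr(M, i, i)) i <- i + 1L
  wa <- .aa_at(W, i); ma <- .aa_at(M, i)
  frame_change <- .length_change(v) %% 3L
  if (identical(ma, "*")) {
    return(protein_change("nonsense", i, ref_aa = wa, alt_aa = "*"))
  }
  if (frame_change != 0L) {
    stop_idx <- if (mt$stop_reached) ml else NA_integer_
    off <- if (is.na(stop_idx)) NA_integer_ else stop_idx - i + 1L
    return(protein_change("frameshift", i, ref_aa = wa, alt_aa = ma,
                          fs_term_offset = off))
  }
  if (identical(wa, "*")) {
    # frame-intact edit that removes or substitutes the stop codon
    return(protein_change("stop_lost", i, ref_aa = "*", alt_aa = ma))
  }
  if (wl == ml) {
    return(protein_change("missense", i, ref_aa = wa, alt_aa = ma))
  }
  if (ml < wl) {
    n_del <- wl - ml
    return(protein_change("inframe_del", i, ref_aa = wa,
                          last_residue = i + n_del - 1L,
                          last_ref_aa = .aa_at(W, i + n_del - 1L)))
  }
  # mutant longer, frame intact
  protein_change("inframe_ins", i, ref_aa = wa, alt_aa = ma,
                 last_residue = i + 1L, last_ref_aa = .aa_at(W, min(i + 1L, wl)))
}

.aa_at <- function(s, i) if (i <= nchar(s)) substr(s, i, i) else ""

.length_change <- function(v) {
  span <- function() {
    if (v$start$kind == "cds" && v$end$kind == "cds") {
      v$end$base - v$start$base + 1L
    } else {
      nchar(v$ref)
    }
  }
  switch(v$kind,
         sub = 0L,
         del = -span(),
         dup = span(),
         ins = nchar(v$alt),
         delins = nchar(v$alt) - span())
}
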