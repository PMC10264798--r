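#' cDNA coordinate
#'
#' HGVS coding-DNA addresses: `c.N` for coding bases (`kind = "cds"`),
#' `c.-N` for 5' UTR bases counted back from the base before c.1
#' (`kind = "utr5"`), `c.*N` for 3' UTR bases counted forward from the
#' base after the stop codon (`kind = "utr3"`), and `c.N+M` / `c.N-M`
#' for intronic positions anchored to the nearest exonic base
#' (`kind = "intronic"`, signed `offset`, anchor base stored in `base`
#' with its own `anchor_kind`).
#'
#' @param kind One of `"cds"`, `"utr5"`, `"utr3"`, `"intronic"`.
#' @param base Positive integer address (anchor address for intronic).
#' @param offset Signed intronic offset; must be 0 unless intronic.
#' @param anchor_kind For intronic coordinates, the kind of the exonic
#'   anchor (`"cds"`, `"utr5"` or `"utr3"`).
#' @return An object of class `cdna_coordinate`.
#' @export
cdna_coordinate <- function(kind, base, offset = 0L, anchor_kind = "cds") {
  kind <- match.arg(kind, c("cds", "utr5", "utr3", "intronic"))
  base <- as.integer(base)
  offset <- as.integer(offset)
  if (is.na(base) || base < 1) stop("cdna coordinate base must be >= 1")
  if (kind != "intronic" && offset != 0L) {
    stop("offset must be 0 for non-intronic coordinates")
  }
  if (kind == "intronic" && offset == 0L) {
    stop("intronic coordinates require a nonzero offset")
  }
  structure(list(kind = kind, base = base, offset = offset,
                 anchor_kind = match.arg(anchor_kind, c("cds", "utr5", "utr3"))),
            class = "cdna_coordinate")
}

# HGVS-style address string for a cdna_coordinate ("-12", "88", "*29", "40+5")
.cdna_addr <- function(co) {
  prefix <- switch(if (co$kind == "intronic") co$anchor_kind else co$kind,
                   cds = "", utr5 = "-", utr3 = "*")
  addr <- paste0(prefix, co$base)
  if (co$kind == "intronic") addr <- paste0(addr, sprintf("%+d", co$offset))
  addr
}

#' @export
print.cdna_coordinate <- function(x, ...) {
  cat("c.", .cdna_addr(x), " [", x$kind, "]\n", sep = "")
  invisible(x)
}

# Scalar sort key in transcript order; utr5 addresses precede cds which
# precede utr3. Intronic offsets contribute a sub-base fraction.
.cdna_key <- function(co) {
  base_key <- switch(if (co$kind == "intronic") co$anchor_kind else co$kind,
                     utr5 = -co$base,
                     cds  = co$base,
                     utr3 = 1e7 + co$base)
  base_key + co$offset / 1e6
}

#' Transcript model
#'
#' Gene/transcript geometry used as the coordinate oracle for the whole
#' pipeline: exon intervals in transcript order, the genomic CDS span
#' (first to last coding base) and, optionally, the spliced CDS
#' sequence. Exons are given in transcript direction: increasing
#' genomic position on the plus strand, decreasing on the minus strand.
#'
#' @param transcript_id Accession text, e.g. `"NM_006565.4"`.
#' @param gene_symbol Gene symbol.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end` (1-based
#'   closed), one row per exon, ordered in transcript direction.
#' @param cds_start,cds_end Genomic positions of the CDS span (min/max;
#'   orientation-independent).
#' @param assembly Assembly label.
#' @param cds_sequence Optional spliced CDS nucleotide string; when
#'   present it must start with ATG, end with a stop codon, contain no
#'   internal stop, and match the summed coding-exon overlap length.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_symbol, chrom, strand, exons,
                             cds_start, cds_end, assembly = "GRCh37",
                             cds_sequence = NULL) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  stopifnot(nrow(exons) >= 1, all(exons$start <= exons$end))
  gstart <- if (strand == "+") exons$start else rev(exons$start)
  gend <- if (strand == "+") exons$end else rev(exons$end)
  if (is.unsorted(gstart, strictly = TRUE) ||
      any(gstart[-1] <= gend[-length(gend)])) {
    stop("exons must be non-overlapping and ordered in transcript direction")
  }
  cds_start <- as.numeric(cds_start); cds_end <- as.numeric(cds_end)
  stopifnot(cds_start <= cds_end)
  in_exon <- function(p) any(exons$start <= p & p <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    stop("CDS span endpoints must fall inside exons")
  }
  model <- structure(
    list(transcript_id = transcript_id, gene_symbol = gene_symbol,
         chrom = chrom, strand = strand, exons = exons,
         cds_start = cds_start, cds_end = cds_end, assembly = assembly,
         cds_sequence = if (is.null(cds_sequence)) NULL else toupper(cds_sequence)),
    class = "transcript_model"
  )
  if (!is.null(model$cds_sequence)) .validate_cds(model)
  model
}

.validate_cds <- function(model) {
  seq <- model$cds_sequence
  ov <- pmin(model$exons$end, model$cds_end) - pmax(model$exons$start, model$cds_start) + 1
  expected <- sum(pmax(ov, 0))
  if (nchar(seq) != expected) {
    stop("cds_sequence length ", nchar(seq),
         " does not match coding-exon overlap total ", expected)
  }
  if (nchar(seq) %% 3 != 0) stop("cds_sequence length must be a multiple of 3")
  if (substr(seq, 1, 3) != "ATG") stop("cds_sequence must start with ATG")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  stops <- codons %in% c("TAA", "TAG", "TGA")
  if (!stops[length(stops)]) stop("cds_sequence must end with a stop codon")
  if (any(stops[-length(stops)])) stop("cds_sequence contains an internal stop codon")
  invisible(model)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript %s (%s, %s strand) %s:%s-%s [%s], %d exons, CDS %s-%s%s\n",
              x$transcript_id, x$gene_symbol, x$strand, x$chrom,
              format(min(x$exons$start), big.mark = ","),
              format(max(x$exons$end), big.mark = ","), x$assembly,
              nrow(x$exons), format(x$cds_start, big.mark = ","),
              format(x$cds_end, big.mark = ","),
              if (is.null(x$cds_sequence)) "" else
                sprintf(", %d nt CDS", nchar(x$cds_sequence))))
  invisible(x)
}

# transcript-direction sign: +1 on plus strand, -1 on minus strand
.strand_sign <- function(model) if (model$strand == "+") 1L else -1L

# Transcript (mRNA) index of a genomic position, or NA if intronic.
.tx_index <- function(model, pos) {
  cum <- 0L
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons$start[i]; e <- model$exons$end[i]
    if (pos >= s && pos <= e) {
      return(cum + if (model$strand == "+") pos - s + 1 else e - pos + 1)
    }
    cum <- cum + (e - s + 1)
  }
  NA_integer_
}

# Genomic position of a transcript index.
.tx_to_genomic <- function(model, t) {
  cum <- 0L
  for (i in seq_len(nrow(model$exons))) {
    len <- model$exons$end[i] - model$exons$start[i] + 1
    if (t <= cum + len) {
      within <- t - cum
      return(if (model$strand == "+") model$exons$start[i] + within - 1
             else model$exons$end[i] - within + 1)
    }
    cum <- cum + len
  }
  stop("transcript index ", t, " beyond transcript extent (", cum, " nt)")
}

.tx_length <- function(model) sum(model$exons$end - model$exons$start + 1)

# Transcript indices of the first and last coding base.
.cds_tx_bounds <- function(model) {
  first <- if (model$strand == "+") model$cds_start else model$cds_end
  last <- if (model$strand == "+") model$cds_end else model$cds_start
  c(first = .tx_index(model, first), last = .tx_index(model, last))
}

.gene_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' Map a genomic position to a cDNA coordinate
#'
#' Coding exonic bases map to `c.N`; 5' UTR bases to `c.-N`; 3' UTR
#' bases to `c.*N`; intronic bases to the nearest exonic anchor with a
#' signed offset (`c.N+M` / `c.N-M`). Equidistant intronic positions
#' are assigned to the upstream-in-transcript exon, as in HGVS.
#'
#' @param model A [transcript_model()].
#' @param pos Genomic position within the gene span.
#' @return A [cdna_coordinate()].
#' @export
genomic_to_cdna <- function(model, pos) {
  span <- .gene_span(model)
  if (pos < span[1] || pos > span[2]) {
    stop("position ", pos, " is outside the transcript span ",
         span[1], "-", span[2])
  }
  t <- .tx_index(model, pos)
  if (!is.na(t)) return(.tx_to_cdna(model, t))
  # intronic: locate flanking exons in transcript order
  sgn <- .strand_sign(model)
  n <- nrow(model$exons)
  for (i in seq_len(n - 1)) {
    up_end <- if (model$strand == "+") model$exons$end[i] else model$exons$start[i]
    dn_start <- if (model$strand == "+") model$exons$start[i + 1] else model$exons$end[i + 1]
    d5 <- (pos - up_end) * sgn
    d3 <- (dn_start - pos) * sgn
    if (d5 > 0 && d3 > 0) {
      if (d5 <= d3) {
        anchor <- .tx_to_cdna(model, .tx_index(model, up_end))
        return(cdna_coordinate("intronic", anchor$base, offset = d5,
                               anchor_kind = anchor$kind))
      } else {
        anchor <- .tx_to_cdna(model, .tx_index(model, dn_start))
        return(cdna_coordinate("intronic", anchor$base, offset = -d3,
                               anchor_kind = anchor$kind))
      }
    }
  }
  stop("position ", pos, " could not be placed in the transcript")
}

.tx_to_cdna <- function(model, t) {
  b <- .cds_tx_bounds(model)
  if (t < b["first"]) {
    cdna_coordinate("utr5", b["first"] - t)
  } else if (t > b["last"]) {
    cdna_coordinate("utr3", t - b["last"])
  } else {
    cdna_coordinate("cds", t - b["first"] + 1)
  }
}

#' Map a cDNA coordinate back to a genomic position
#'
#' Exact inverse of [genomic_to_cdna()] on its image.
#'
#' @param model A [transcript_model()].
#' @param coord A [cdna_coordinate()].
#' @return Genomic position (numeric).
#' @export
cdna_to_genomic <- function(model, coord) {
  stopifnot(inherits(coord, "cdna_coordinate"))
  b <- .cds_tx_bounds(model)
  anchor_kind <- if (coord$kind == "intronic") coord$anchor_kind else coord$kind
  t <- switch(anchor_kind,
              cds  = b["first"] + coord$base - 1,
              utr5 = b["first"] - coord$base,
              utr3 = b["last"] + coord$base)
  if (t < 1 || t > .tx_length(model)) {
    stop("cDNA coordinate c.", .cdna_addr(coord), " beyond transcript extent")
  }
  g <- .tx_to_genomic(model, unname(t))
  g + coord$offset * .strand_sign(model)
}

#' Codon arithmetic for a CDS position
#'
#' @param cds_pos 1-based position within the CDS.
#' @param cds_length Optional CDS length for range checking.
#' @return List with `residue` (1-based residue index, `ceil(pos/3)`)
#'   and `codon_offset` (1, 2 or 3 within the codon).
#' @examples
#' codon_of(1456)  # residue 486, offset 1 (p.Gln486Ter in CTCF)
#' @export
codon_of <- function(cds_pos, cds_length = NULL) {
  cds_pos <- as.numeric(cds_pos)
  if (is.na(cds_pos) || cds_pos < 1 || cds_pos != floor(cds_pos)) {
    stop("cds_pos must be a positive integer")
  }
  if (!is.null(cds_length) && cds_pos > cds_length) {
    stop("cds_pos ", cds_pos, " exceeds CDS length ", cds_length)
  }
  list(residue = ceiling(cds_pos / 3),
       codon_offset = ((cds_pos - 1) %% 3) + 1)
}

#' Region annotation of a genomic position
#'
#' @param model A [transcript_model()].
#' @param pos Genomic position within the gene span.
#' @return One of `"exonic_cds"`, `"utr5"`, `"utr3"`, `"intronic"`.
#' @export
annotate_position <- function(model, pos) {
  co <- genomic_to_cdna(model, pos)
  switch(co$kind, cds = "exonic_cds", utr5 = "utr5", utr3 = "utr3",
         intronic = "intronic")
}
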