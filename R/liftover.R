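#' Parse a UCSC chain file
#'
#' Reads the standard chain format: a `chain` header line
#' (`chain score tName tSize tStrand tStart tEnd qName qSize qStrand
#' qStart qEnd id`) followed by alignment block lines
#' (`size dt dq`, last line `size` only). In this package the chain's
#' "t" side is the *source* assembly of the conversion (e.g. GRCh38 in
#' an hg38-to-hg19 chain) and the "q" side the *target*. Chain
#' coordinates are 0-based half-open and are kept that way inside the
#' alignment objects; the mapping functions convert from/to the 1-based
#' closed convention used everywhere else.
#'
#' @param x Path to a chain file, or a character vector of lines.
#' @return List of `chain_alignment` objects (empty list for an empty
#'   file). Each alignment's block extents are validated against the
#'   declared source/target spans.
#' @export
parse_chain <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines_trim <- trimws(lines)
  chains <- list()
  i <- 1L
  while (i <= length(lines_trim)) {
    if (!nzchar(lines_trim[i]) || startsWith(lines_trim[i], "#")) {
      i <- i + 1L
      next
    }
    f <- strsplit(lines_trim[i], "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12) {
      stop("malformed chain header at line ", i, ": '", lines_trim[i], "'")
    }
    hdr <- list(
      score = as.numeric(f[2]),
      s_name = f[3], s_size = as.numeric(f[4]), s_strand = f[5],
      s_start = as.numeric(f[6]), s_end = as.numeric(f[7]),
      t_name = f[8], t_size = as.numeric(f[9]), t_strand = f[10],
      t_start = as.numeric(f[11]), t_end = as.numeric(f[12]),
      id = if (length(f) >= 13) f[13] else NA_character_
    )
    if (anyNA(c(hdr$score, hdr$s_size, hdr$s_start, hdr$s_end,
                hdr$t_size, hdr$t_start, hdr$t_end))) {
      stop("malformed chain header at line ", i, ": non-numeric field")
    }
    if (hdr$s_strand != "+") {
      stop("chain line ", i, ": source strand must be '+' per the chain spec")
    }
    # block lines
    sizes <- numeric(0); s_gap <- numeric(0); t_gap <- numeric(0)
    i <- i + 1L
    repeat {
      if (i > length(lines_trim)) stop("unexpected end of chain file: missing final block line")
      if (!nzchar(lines_trim[i])) { i <- i + 1L; next }
      b <- suppressWarnings(as.numeric(strsplit(lines_trim[i], "[ \t]+")[[1]]))
      if (anyNA(b) || !length(b) %in% c(1L, 3L)) {
        stop("malformed chain block at line ", i, ": '", lines_trim[i], "'")
      }
      if (any(b < 0)) stop("negative block size/gap at line ", i)
      sizes <- c(sizes, b[1])
      if (length(b) == 3L) {
        s_gap <- c(s_gap, b[2]); t_gap <- c(t_gap, b[3])
        i <- i + 1L
      } else {
        i <- i + 1L
        break
      }
    }
    if (sum(sizes) + sum(s_gap) != hdr$s_end - hdr$s_start) {
      stop("chain extent mismatch on source side for chain ending at line ", i - 1L)
    }
    if (sum(sizes) + sum(t_gap) != hdr$t_end - hdr$t_start) {
      stop("chain extent mismatch on target side for chain ending at line ", i - 1L)
    }
    hdr$blocks <- data.frame(size = sizes,
                             s_gap = c(s_gap, 0), t_gap = c(t_gap, 0))
    chains[[length(chains) + 1L]] <- structure(hdr, class = "chain_alignment")
  }
  chains
}

#' Lift a single position across assemblies
#'
#' @param chains List of `chain_alignment` from [parse_chain()].
#' @param chrom Source chromosome.
#' @param pos Source position, 1-based.
#' @return A list: `mapped = TRUE` with `chrom`, `pos` (1-based),
#'   `strand` on the target assembly, or `mapped = FALSE` with `reason`
#'   `"no_chain"` (no chain covers the position) or `"in_gap"` (the
#'   position falls in an alignment gap). When several chains cover the
#'   position only the highest-scoring one is used.
#' @export
map_position <- function(chains, chrom, pos) {
  pos0 <- pos - 1  # chain space is 0-based half-open
  covering <- Filter(function(ch) ch$s_name == chrom &&
                       pos0 >= ch$s_start && pos0 < ch$s_end, chains)
  if (!length(covering)) {
    return(list(mapped = FALSE, reason = "no_chain"))
  }
  ch <- covering[[which.max(vapply(covering, `[[`, numeric(1), "score"))]]
  s_cur <- ch$s_start; t_cur <- ch$t_start
  for (j in seq_len(nrow(ch$blocks))) {
    size <- ch$blocks$size[j]
    if (pos0 < s_cur + size) {
      t0 <- t_cur + (pos0 - s_cur)
      if (ch$t_strand == "+") {
        return(list(mapped = TRUE, chrom = ch$t_name, pos = t0 + 1,
                    strand = "+", chain_id = ch$id))
      } else {
        # q coordinates on '-' strand are counted from the reverse
        # complement start; reflect to forward-strand 1-based.
        return(list(mapped = TRUE, chrom = ch$t_name,
                    pos = ch$t_size - t0, strand = "-", chain_id = ch$id))
      }
    }
    s_cur <- s_cur + size + ch$blocks$s_gap[j]
    t_cur <- t_cur + size + ch$blocks$t_gap[j]
    if (pos0 < s_cur) return(list(mapped = FALSE, reason = "in_gap"))
  }
  list(mapped = FALSE, reason = "in_gap")
}

#' Lift an interval across assemblies (strict policy)
#'
#' Both endpoints must map through the same chain, on the same target
#' strand, with their order preserved; otherwise the interval is
#' reported unmapped with a reason (`no_chain`, `in_gap`, or `split`
#' when the endpoints land on different chains).
#'
#' @param chains List of `chain_alignment`.
#' @param iv A [genomic_interval()].
#' @param target_assembly Assembly label for the mapped interval.
#' @return A mapped [genomic_interval()] (invisible extra attribute
#'   `strand`), or a list `mapped = FALSE` with `reason`.
#' @export
map_interval <- function(chains, iv, target_assembly = "GRCh37") {
  a <- map_position(chains, iv$chrom, iv$start)
  b <- map_position(chains, iv$chrom, iv$end)
  if (!a$mapped || !b$mapped) {
    reason <- unique(c(if (!a$mapped) a$reason, if (!b$mapped) b$reason))
    return(list(mapped = FALSE, reason = reason[1]))
  }
  if (!identical(a$chain_id, b$chain_id) || !identical(a$chrom, b$chrom)) {
    return(list(mapped = FALSE, reason = "split"))
  }
  if (!identical(a$strand, b$strand)) {
    return(list(mapped = FALSE, reason = "split"))
  }
  lo <- min(a$pos, b$pos); hi <- max(a$pos, b$pos)
  out <- genomic_interval(a$chrom, lo, hi, assembly = target_assembly)
  attr(out, "strand") <- a$strand
  out
}

#' Reverse a chain (swap source and target sides)
#'
#' Utility for reciprocal-mapping checks and for emitting a
#' GRCh37-to-GRCh38 companion of a synthetic chain. Only plus-strand
#' targets are supported.
#'
#' @param ch A `chain_alignment`.
#' @return A `chain_alignment` mapping in the opposite direction.
#' @export
reverse_chain <- function(ch) {
  stopifnot(inherits(ch, "chain_alignment"))
  if (ch$t_strand != "+") stop("reverse_chain supports plus-strand targets only")
  out <- ch
  out[c("s_name", "s_size", "s_strand", "s_start", "s_end")] <-
    ch[c("t_name", "t_size", "t_strand", "t_start", "t_end")]
  out[c("t_name", "t_size", "t_strand", "t_start", "t_end")] <-
    ch[c("s_name", "s_size", "s_strand", "s_start", "s_end")]
  out$blocks <- data.frame(size = ch$blocks$size,
                           s_gap = ch$blocks$t_gap, t_gap = ch$blocks$s_gap)
  out
}

#' Write chain alignments to a file
#'
#' @param chains List of `chain_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$s_name, format(ch$s_size, scientific = FALSE), ch$s_strand,
                     format(ch$s_start, scientific = FALSE),
                     format(ch$s_end, scientific = FALSE),
                     ch$t_name, format(ch$t_size, scientific = FALSE), ch$t_strand,
                     format(ch$t_start, scientific = FALSE),
                     format(ch$t_end, scientific = FALSE),
                     if (is.na(ch$id)) "1" else ch$id), con)
    n <- nrow(ch$blocks)
    if (n > 1) {
      writeLines(paste(ch$blocks$size[-n], ch$blocks$s_gap[-n],
                       ch$blocks$t_gap[-n]), con)
    }
    writeLines(c(format(ch$blocks$size[n], scientific = FALSE), ""), con)
  }
  invisible(path)
}
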