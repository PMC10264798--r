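# Plain-text transcript configuration files: everything needed to
# rebuild a transcript_model (geometry in a key/value + exon-line
# format, CDS sequence in a companion FASTA).

#' Write a transcript model to a config file (+ CDS FASTA)
#'
#' @param model A [transcript_model()].
#' @param path Config file path.
#' @param fasta Optional path for the CDS FASTA; referenced from the
#'   config by file name (resolved relative to the config's directory
#'   on read).
#' @return `path`, invisibly.
#' @export
write_transcript_config <- function(model, path, fasta = NULL) {
  lines <- c(
    paste0("transcript_id\t", model$transcript_id),
    paste0("gene_symbol\t", model$gene_symbol),
    paste0("chrom\t", model$chrom),
    paste0("strand\t", model$strand),
    paste0("assembly\t", model$assembly),
    paste0("cds_start\t", format(model$cds_start, scientific = FALSE)),
    paste0("cds_end\t", format(model$cds_end, scientific = FALSE)))
  if (!is.null(fasta)) {
    if (!is.null(model$cds_sequence)) {
      seq <- model$cds_sequence
      writeLines(c(paste0(">", model$transcript_id, " CDS"),
                   substring(seq, seq(1, nchar(seq), 60),
                             pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))),
                 fasta)
    }
    lines <- c(lines, paste0("cds_fasta\t", basename(fasta)))
  }
  lines <- c(lines, paste("exon",
                          format(model$exons$start, scientific = FALSE, trim = TRUE),
                          format(model$exons$end, scientific = FALSE, trim = TRUE),
                          sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcript model from a config file
#'
#' @param path Config file written by [write_transcript_config()].
#' @return A [transcript_model()].
#' @export
read_transcript_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, character(1), 1)
  get1 <- function(k) {
    i <- which(keys == k)
    if (length(i) != 1) stop("transcript config: expected exactly one '", k,
                             "' line in ", path)
    parts[[i]][2]
  }
  ex <- parts[keys == "exon"]
  if (!length(ex)) stop("transcript config: no exon lines in ", path)
  exons <- data.frame(start = as.numeric(vapply(ex, `[[`, character(1), 2)),
                      end = as.numeric(vapply(ex, `[[`, character(1), 3)))
  cds_seq <- NULL
  if (any(keys == "cds_fasta")) {
    fa <- file.path(dirname(path), get1("cds_fasta"))
    fl <- readLines(fa)
    cds_seq <- paste(fl[!startsWith(fl, ">")], collapse = "")
  }
  transcript_model(
    transcript_id = get1("transcript_id"), gene_symbol = get1("gene_symbol"),
    chrom = get1("chrom"), strand = get1("strand"), exons = exons,
    cds_start = as.numeric(get1("cds_start")),
    cds_end = as.numeric(get1("cds_end")),
    assembly = get1("assembly"), cds_sequence = cds_seq)
}
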