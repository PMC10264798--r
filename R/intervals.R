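#' Genomic interval (1-based, fully closed)
#'
#' All genomic coordinates in this package are 1-based and fully closed:
#' an interval covers every integer position from `start` to `end`
#' inclusive, so its length is `end - start + 1`. Conversions to the
#' 0-based half-open conventions of chain and BED files happen only
#' inside the corresponding readers/writers.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive endpoints; `start <= end`.
#' @param assembly Genome assembly label, `"GRCh37"` or `"GRCh38"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("chr16", 67596310, 67673088)
#' interval_length(gi)  # 76779
#' @export
genomic_interval <- function(chrom, start, end, assembly = "GRCh37") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || start > end) {
    stop("invalid interval: need 1 <= start <= end, got [", start, ", ", end, "]")
  }
  structure(
    list(chrom = as.character(chrom), start = start, end = end,
         assembly = match.arg(assembly, c("GRCh37", "GRCh38"))),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s> %s:%s-%s (%s bp)\n", x$assembly, x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Length of a genomic interval in base pairs
#'
#' @param iv A [genomic_interval()].
#' @return Integer number of base pairs, `end - start + 1`.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1
}
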