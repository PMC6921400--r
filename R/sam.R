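# Minimal SAM v1 emission and a column reader for the package's own output.

sam_header <- function(ref, pg = "varatree") {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref$lengths), unname(ref$lengths)),
    sprintf("@PG\tID:%s\tPN:%s", pg, pg))
}

#' Write SAM records
#'
#' @param records Tibble with the 11 mandatory columns plus `nm`
#'   (qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual).
#' @param path Output path.
#' @param ref A `varef` (for the header).
#' @export
write_sam <- function(records, path, ref) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d\tAS:i:%d",
                   records$qname, records$flag, records$rname, records$pos,
                   records$mapq, records$cigar, records$rnext, records$pnext,
                   records$tlen, records$seq, records$qual, records$nm,
                   -records$nm)
  writeLines(c(sam_header(ref), lines), path)
  invisible(path)
}

#' Read a SAM file produced by this package
#'
#' Parses the mandatory columns and the NM tag. This is a reader for the
#' package's own emission, not a general SAM parser.
#'
#' @param path SAM file path.
#' @return Tibble of records.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:12)
  nm <- suppressWarnings(as.integer(sub("^NM:i:", "", f[[12]])))
  tibble::tibble(qname = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
                 pos = as.integer(f[[4]]), mapq = as.integer(f[[5]]),
                 cigar = f[[6]], rnext = f[[7]], pnext = as.integer(f[[8]]),
                 tlen = as.integer(f[[9]]), seq = f[[10]], qual = f[[11]],
                 nm = nm)
}
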