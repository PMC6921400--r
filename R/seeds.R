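# k-mer seed index with stride sampling and a repeat cap. This replaces a
# unipath-graph seeding stage: seeding is deliberately plain, since the
# variation-aware contribution of the package lives entirely in the
# extension stage.

#' Build a k-mer seed index over a variation-aware reference
#'
#' Indexes every reference position's k-mer (2-bit packed). k-mers occurring
#' more often than `repeat_cap` are flagged and never returned from lookups;
#' windows containing non-ACGT bases are excluded. The reverse strand is
#' handled by reverse-complementing reads at query time.
#'
#' @param ref A `varef`.
#' @param k Seed length (8..31; default 16).
#' @param repeat_cap Maximum occurrence count before a k-mer is flagged.
#' @return A `seed_index` with the packed k-mer table, concatenated site-code
#'   vector and chromosome offsets.
#' @export
build_seed_index <- function(ref, k = 16L, repeat_cap = 64L) {
  stopifnot(k >= 8L, k <= 31L)
  chroms <- names(ref$chroms)
  offs <- cumsum(c(0L, unname(ref$lengths)))[seq_along(chroms)]
  names(offs) <- chroms
  codes <- numeric(0); gpos <- numeric(0)
  for (i in seq_along(chroms)) {
    d <- base_digits(ref$chroms[[chroms[i]]]$seq)
    cd <- kmer_pack(d, k)
    ok <- which(!is.na(cd))
    codes <- c(codes, cd[ok])
    gpos <- c(gpos, offs[i] + ok - 1L)
  }
  dt <- data.table::data.table(code = codes, gpos = as.integer(gpos))
  cnt <- dt[, .N, by = "code"]
  flagged <- cnt$code[cnt$N > repeat_cap]
  if (length(flagged) > 0L) dt <- dt[!dt$code %in% flagged]
  data.table::setkey(dt, code)
  cmask <- unlist(lapply(chroms, function(ch) ref$chroms[[ch]]$mask),
                  use.names = FALSE)
  structure(list(dt = dt, k = as.integer(k),
                 repeat_cap = as.integer(repeat_cap),
                 flagged = flagged,
                 chroms = chroms, offsets = offs,
                 lengths = ref$lengths, total_len = sum(ref$lengths),
                 cmask = cmask),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> k=%d, %s positions, %d flagged k-mer(s)\n",
              x$k, format(nrow(x$dt), big.mark = ","), length(x$flagged)))
  invisible(x)
}

# global position -> chromosome index
gpos_chrom <- function(index, gpos) {
  findInterval(gpos, unname(index$offsets))
}

#' Look up a k-mer's reference positions
#' @param index A `seed_index`.
#' @param kmer k-length string.
#' @return Integer vector of global 0-based positions (empty if absent or
#'   flagged).
#' @export
seed_lookup <- function(index, kmer) {
  d <- base_digits(kmer)
  if (length(d) != index$k || anyNA(d)) return(integer(0))
  code <- sum(d * 4 ^ (index$k - seq_along(d)))
  q <- data.table::data.table(code = code)
  index$dt[q, on = "code", nomatch = NULL, allow.cartesian = TRUE]$gpos
}

#' Collect seed hits for one read on both strands
#'
#' Samples read k-mers at the given stride (plus the final window) and
#' returns all index hits as a tibble of seed hits.
#'
#' @param read Read string (length >= k).
#' @param index A `seed_index`.
#' @param stride Sampling stride (default 8).
#' @return Tibble: `read_off`, `chrom`, `pos` (0-based), `len`, `strand`,
#'   `diag` (global position of the implied read start).
#' @export
collect_seeds <- function(read, index, stride = 8L) {
  rl <- nchar(read)
  if (rl < index$k)
    stop2("varatree_error_short_read", "read shorter than seed length")
  offs <- unique(c(seq(0L, rl - index$k, by = stride), rl - index$k))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else revcomp(read)
    d <- base_digits(s)
    cd <- kmer_pack(d, index$k)[offs + 1L]
    q <- data.table::data.table(code = cd, roff = offs)[!is.na(cd)]
    if (nrow(q) == 0L) next
    m <- index$dt[q, on = "code", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(m) == 0L) next
    ci <- gpos_chrom(index, m$gpos)
    out[[strand]] <- tibble::tibble(
      read_off = m$roff, chrom = index$chroms[ci],
      pos = as.integer(m$gpos - index$offsets[ci]), len = index$k,
      strand = strand, diag = as.integer(m$gpos - m$roff))
  }
  if (length(out) == 0L)
    return(tibble::tibble(read_off = integer(0), chrom = character(0),
                          pos = integer(0), len = integer(0),
                          strand = character(0), diag = integer(0)))
  do.call(rbind, out)
}
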