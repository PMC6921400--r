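# Low-level base/bit encodings shared by all modules.
#
# A reference site is a 4-bit code over {A,C,G,T}: bit 1 = A, 2 = C, 4 = G,
# 8 = T. The reference base's bit is always set; SNP alternates OR extra bits
# in. A read base matches a site iff its own bit is set in the site code, so
# SNP-tolerant matching is a single bitwAnd. Read 'N' encodes to 0 and matches
# nothing; non-ACGT reference sites encode to 15 (all bits) and accept any
# ACGT read base, but are excluded from k-mer seeding.

.BITS <- local({
  v <- integer(256)
  v[utf8ToInt("A") + 1L] <- 1L; v[utf8ToInt("a") + 1L] <- 1L
  v[utf8ToInt("C") + 1L] <- 2L; v[utf8ToInt("c") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- 4L; v[utf8ToInt("g") + 1L] <- 4L
  v[utf8ToInt("T") + 1L] <- 8L; v[utf8ToInt("t") + 1L] <- 8L
  v
})

.DIGITS <- local({
  v <- rep(NA_real_, 256)
  v[utf8ToInt("A") + 1L] <- 0; v[utf8ToInt("a") + 1L] <- 0
  v[utf8ToInt("C") + 1L] <- 1; v[utf8ToInt("c") + 1L] <- 1
  v[utf8ToInt("G") + 1L] <- 2; v[utf8ToInt("g") + 1L] <- 2
  v[utf8ToInt("T") + 1L] <- 3; v[utf8ToInt("t") + 1L] <- 3
  v
})

#' Encode a DNA string as per-base bit codes
#'
#' A/C/G/T (either case) map to bits 1/2/4/8; any other character maps to 0,
#' which matches no site code.
#'
#' @param x A single character string.
#' @return Integer vector of length `nchar(x)`.
#' @keywords internal
base_bits <- function(x) {
  if (!nzchar(x)) return(integer(0))
  .BITS[utf8ToInt(x) + 1L]
}

# 0..3 digit encoding used for k-mer packing; NA for non-ACGT.
base_digits <- function(x) {
  if (!nzchar(x)) return(numeric(0))
  .DIGITS[utf8ToInt(x) + 1L]
}

# Non-reference site codes: for each mask 1..15, which bases match.
.MASK_CHARS <- vapply(0:15, function(m) {
  paste0(c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L],
         collapse = "")
}, character(1))

#' Decode a vector of site codes to their matching base sets
#' @param mask Integer vector of 4-bit site codes (0..15).
#' @return Character vector, e.g. `"CT"` for mask 10.
#' @keywords internal
mask_bases <- function(mask) .MASK_CHARS[mask + 1L]

#' Reverse-complement DNA strings
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 1L) return(revcomp1(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# scalar fast path: avoids S4 construction in per-read loops
revcomp1 <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgtN", "TGCAtgcaN", s))))
}

# Reverse a string without complementing (window reflection for left-side
# extension trees).
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Packed k-mer codes for every start position of a digit vector.
# Returns a double vector of length length(d) - k + 1; windows containing a
# non-ACGT base are NA. Uses a C-level convolution, values < 4^k <= 4^16 are
# exact in doubles.
kmer_pack <- function(d, k) {
  n <- length(d)
  if (n < k) return(numeric(0))
  y <- stats::filter(d, 4 ^ (0:(k - 1)), method = "convolution", sides = 1)
  as.numeric(y[k:n])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
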