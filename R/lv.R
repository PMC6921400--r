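# Landau-Vishkin banded edit distance, plus the full-DP reference
# implementation used as an independent check and for window placement.

#' Classical Landau-Vishkin edit distance (semiglobal)
#'
#' Iterates edit count `e` and diagonal `d`, storing per `(e, d)` the
#' farthest-reaching number of consumed `a` characters: each diagonal is
#' seeded with the maximum of `L[e-1][d] + 1` (mismatch), `L[e-1][d+1] + 1`
#' (insertion into `a`) and `L[e-1][d-1]` (deletion from `b`), then slides
#' along exact character matches. `a` must be fully consumed; `b`'s tail is
#' free (extension semantics). O(e_max * n) cell updates.
#'
#' @param a Query string (fully consumed).
#' @param b Target string (prefix-pinned, free end).
#' @param e_max Maximum edit distance to explore.
#' @return The least `e <= e_max` aligning all of `a`, else `NA_integer_`.
#' @examples
#' lv_edit_distance("GCGTATGC", "GCTATGCAA", 2)  # 1
#' @export
lv_edit_distance <- function(a, b, e_max) {
  stopifnot(e_max >= 0)
  ab <- utf8ToInt(toupper(a)); bb <- utf8ToInt(toupper(b))
  n <- length(ab); m <- length(bb)
  if (n == 0L) return(0L)
  slide <- function(i, j) {
    k <- min(n - i, m - j)
    if (k <= 0L) return(0L)
    bad <- which(ab[(i + 1L):(i + k)] != bb[(j + 1L):(j + k)])
    if (length(bad) == 0L) k else bad[1] - 1L
  }
  prev <- NULL
  for (e in 0:e_max) {
    cur <- rep(-Inf, 2L * e + 1L)
    for (d in (-e):e) {
      best <- if (e == 0L) 0 else {
        g <- function(dd) {
          idx <- dd + e                       # position in prev (d index -e+1..e-1)
          if (idx >= 1L && idx <= 2L * e - 1L) prev[idx] else -Inf
        }
        max(g(d) + 1, g(d + 1) + 1, g(d - 1))
      }
      i <- best
      if (!is.finite(i) || i > n || i + d > m || i + d < 0) next
      i <- i + slide(i, i + d)
      cur[d + e + 1L] <- i
      if (i >= n) return(e)
    }
    prev <- cur
  }
  NA_integer_
}

#' Full dynamic-programming edit distance (oracle)
#'
#' Complete O(nm) Levenshtein matrix, row-vectorized. Substitution cost is
#' the SNP-tolerant site test when `b` is given as site codes, so the same
#' oracle serves plain strings and variant-aware haplotypes.
#'
#' @param a Query string.
#' @param b Target string, or `NULL` when `masks` is given.
#' @param masks Optional integer site codes for the target.
#' @param mode `"semiglobal"` (a global, b prefix-pinned with free end) or
#'   `"global"`.
#' @return Integer edit distance.
#' @export
edit_distance_dp <- function(a, b = NULL, masks = NULL,
                             mode = c("semiglobal", "global")) {
  mode <- match.arg(mode)
  rb <- base_bits(a)
  hm <- if (is.null(masks)) {
    bits <- base_bits(b)
    ifelse(bits == 0L, 15L, bits)
  } else as.integer(masks)
  n <- length(rb); m <- length(hm)
  if (m == 0L) return(n)
  row <- 0:m
  idx <- 0:m
  for (i in seq_len(n)) {
    cost <- as.integer(bitwAnd(rb[i], hm) == 0L)
    tmp <- c(row[1] + 1L, pmin(row[2:(m + 1L)] + 1L, row[1:m] + cost))
    row <- cummin(tmp - idx) + idx
  }
  as.integer(if (mode == "semiglobal") min(row) else row[m + 1L])
}
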