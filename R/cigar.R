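# Restoration of ALT-coordinate alignments (read vs variant-applied
# haplotype) to reference-coordinate CIGAR strings.
#
# The read->haplotype operations are composed with the haplotype->reference
# map induced by the taken variants (M blocks, VI = insertion variant
# consuming haplotype only, VD = deletion variant consuming reference only).
# Canonicalization then collapses adjacent insertion/deletion runs into
# match-or-mismatch M, which reproduces the four restoration rules: a 1 bp
# ALT deletion inside a 1 bp insertion variant cancels to M; a 1 bp ALT
# insertion at a 1 bp deletion junction collapses to M; an ALT deletion
# inside a longer insertion variant leaves a reference insertion; an ALT
# insertion at a longer deletion junction leaves a shorter reference
# deletion plus M (possible mismatches).

parse_cigar <- function(cigar) {
  if (!nzchar(cigar) || cigar == "*")
    return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops))
    stop2("varatree_error_bad_cigar", sprintf("malformed CIGAR '%s'", cigar))
  data.frame(len = lens, op = ops)
}

cigar_string <- function(tab) {
  if (nrow(tab) == 0L) return("*")
  paste0(tab$len, tab$op, collapse = "")
}

merge_ops <- function(ops, lens) {
  keep <- lens > 0L
  ops <- ops[keep]; lens <- lens[keep]
  if (length(ops) <= 1L) return(list(ops = ops, lens = lens))
  grp <- cumsum(c(TRUE, ops[-1] != ops[-length(ops)]))
  list(ops = ops[!duplicated(grp)],
       lens = as.integer(tapply(lens, grp, sum)))
}

# Collapse adjacent I/D (either order) into M(min) followed by the leftover
# op; repeat to fixpoint, re-merging equal neighbours.
canonicalize_ops <- function(ops, lens) {
  repeat {
    m <- merge_ops(ops, lens)
    ops <- m$ops; lens <- m$lens
    hit <- 0L
    if (length(ops) >= 2L) {
      for (i in seq_len(length(ops) - 1L)) {
        if ((ops[i] == "I" && ops[i + 1L] == "D") ||
            (ops[i] == "D" && ops[i + 1L] == "I")) { hit <- i; break }
      }
    }
    if (hit == 0L) return(list(ops = ops, lens = lens))
    a <- lens[hit]; b <- lens[hit + 1L]
    mm <- min(a, b)
    left <- if (a > b) ops[hit] else ops[hit + 1L]
    repl_ops <- c("M", if (a != b) left)
    repl_lens <- c(mm, if (a != b) abs(a - b))
    ops <- c(ops[seq_len(hit - 1L)], repl_ops,
             ops[setdiff(seq_along(ops), seq_len(hit + 1L))])
    lens <- c(lens[seq_len(hit - 1L)], repl_lens,
              lens[setdiff(seq_along(lens), seq_len(hit + 1L))])
  }
}

#' Restore an ALT-coordinate CIGAR to reference coordinates
#'
#' Composes the read-vs-haplotype alignment with the haplotype-vs-reference
#' map of the path's taken variants, canonicalizes (adjacent I/D collapse
#' into match-or-mismatch M; per-base SNP-tolerant matches stay M), strips
#' leading/trailing reference deletions into the position, and reports the
#' leftmost reference base consumed. Soft clips pass through unchanged at the
#' read ends. If the alignment starts inside an insertion variant the
#' reported position is the base after the insertion anchor.
#'
#' @param alt_cigar CIGAR of the read against the realized haplotype
#'   (ops M/I/D/S; must not consume more haplotype than the path provides).
#' @param path A path object (from [enumerate_paths()]) or any list with a
#'   `segs` data frame of `op` in `c("M","VI","VD")` and `len`.
#' @param window The `region_window` the path extends over (its `start`
#'   anchors reference coordinates).
#' @return List with `pos` (0-based leftmost reference base consumed) and
#'   `cigar` (reference-coordinate CIGAR string).
#' @export
compose_ref_cigar <- function(alt_cigar, path, window) {
  alt <- parse_cigar(alt_cigar)
  segs <- path$segs
  hap_avail <- sum(segs$len[segs$op != "VD"])
  hap_need <- sum(alt$len[alt$op %in% c("M", "D")])
  if (hap_need > hap_avail)
    stop2("varatree_error_bad_cigar",
          "ALT cigar consumes more haplotype than the path provides")
  out_ops <- character(0); out_lens <- integer(0)
  emit <- function(op, n) {
    if (n > 0L) { out_ops <<- c(out_ops, op); out_lens <<- c(out_lens, n) }
  }
  si <- 1L
  seg_rem <- if (nrow(segs) > 0L) segs$len[1] else 0L
  consume_hap <- function(n, read_too) {
    while (n > 0L) {
      while (si <= nrow(segs) && (seg_rem == 0L || segs$op[si] == "VD")) {
        if (segs$op[si] == "VD" && seg_rem > 0L) emit("D", seg_rem)
        si <<- si + 1L
        seg_rem <<- if (si <= nrow(segs)) segs$len[si] else 0L
      }
      if (si > nrow(segs))
        stop2("varatree_error_bad_cigar", "haplotype exhausted in composition")
      t <- min(n, seg_rem)
      if (segs$op[si] == "M") emit(if (read_too) "M" else "D", t)
      else emit(if (read_too) "I" else "", t)   # VI: read->I, alt D -> nothing
      seg_rem <<- seg_rem - t
      n <- n - t
    }
  }
  for (i in seq_len(nrow(alt))) {
    op <- alt$op[i]; n <- alt$len[i]
    if (op == "S" || op == "I") emit(op, n)
    else if (op == "M") consume_hap(n, TRUE)
    else if (op == "D") consume_hap(n, FALSE)
    else stop2("varatree_error_bad_cigar",
               sprintf("unsupported ALT cigar op '%s'", op))
  }
  keep <- out_ops != ""
  can <- canonicalize_ops(out_ops[keep], out_lens[keep])
  ops <- can$ops; lens <- can$lens
  # leading/trailing reference deletions move into the position
  pos <- window$start
  while (length(ops) > 0L && ops[1] == "D") {
    pos <- pos + lens[1]; ops <- ops[-1]; lens <- lens[-1]
  }
  # position skips leading soft clip / insertion (no reference consumed)
  while (length(ops) > 1L && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  if (sum(lens[ops %in% c("M", "D")]) < 0L)
    stop2("varatree_error_bad_cigar", "negative reference span")
  list(pos = pos, cigar = cigar_string(data.frame(len = lens, op = ops)))
}

#' Arithmetic validation of a CIGAR string
#'
#' Checks run canonicalization (lengths >= 1, no two adjacent equal ops, op
#' set M/I/D/S) and both consumption identities: read-consuming ops (M, I,
#' S) must sum to the read length and reference-consuming ops (M, D) to the
#' reference span.
#'
#' @param cigar CIGAR string.
#' @param read_len Expected read length.
#' @param ref_span Expected reference span.
#' @return Logical.
#' @examples
#' validate_cigar("10M2I10M", 22, 20)  # TRUE
#' @export
validate_cigar <- function(cigar, read_len, ref_span) {
  tab <- tryCatch(parse_cigar(cigar), error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) return(FALSE)
  if (!all(tab$op %in% c("M", "I", "D", "S"))) return(FALSE)
  if (any(tab$len < 1L)) return(FALSE)
  if (nrow(tab) > 1L && any(tab$op[-1] == tab$op[-nrow(tab)])) return(FALSE)
  sum(tab$len[tab$op %in% c("M", "I", "S")]) == read_len &&
    sum(tab$len[tab$op %in% c("M", "D")]) == ref_span
}
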