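# VATR: queue-driven breadth-first traversal of the variation tree.
#
# A frontier entry groups all live paths that sit at the same tree locus with
# the same read cursor; matching against shared node labels is therefore done
# once per entry. The queue processes three entry categories -- plain node
# extension, insertion-allele matching, and variant-end-node resumption --
# and enqueues (i) adjacent successors of an exhausted node, (ii) newly
# reached variants, and (iii) the end node of the current variant. A path
# stops when the next read base fails the SNP-tolerant site test (mismatch),
# when the read is exhausted (ran-to-end), or when its haplotype runs out
# (path-end: the window, including any pseudo node, is consumed).

#' SNP-tolerant maximal match run
#'
#' Length of the longest run `k` such that every read base bit-matches the
#' site code at the same offset of the node label.
#'
#' @param read Read string (or integer bit codes).
#' @param read_off 0-based read offset.
#' @param node_label Integer vector of site codes (or a string, converted).
#' @param node_off 0-based offset into the label.
#' @return Integer run length.
#' @examples
#' match_run("ATGT", 0, c(1L, bitwOr(2L, 8L), 4L, 8L), 0)  # 4: SNP absorbs T
#' @export
match_run <- function(read, read_off, node_label, node_off) {
  rb <- if (is.character(read)) base_bits(read) else as.integer(read)
  lb <- if (is.character(node_label)) base_bits(node_label) else
    as.integer(node_label)
  n <- min(length(rb) - read_off, length(lb) - node_off)
  if (n <= 0L) return(0L)
  bad <- which(bitwAnd(rb[(read_off + 1L):(read_off + n)],
                       lb[(node_off + 1L):(node_off + n)]) == 0L)
  if (length(bad) == 0L) n else bad[1] - 1L
}

# Build frontier entries from per-path states (path id, read_off, hap_off),
# grouping by tree locus + read cursor. Paths whose haplotype is already
# exhausted are reported directly as path-end hits.
make_frontier <- function(tree, states) {
  entries <- list(); direct <- list()
  if (nrow(states) == 0L) return(list(entries = entries, direct = direct))
  key <- character(nrow(states))
  for (i in seq_len(nrow(states))) {
    p <- tree$paths[[as.character(states$path_id[i])]]
    h <- states$hap_off[i]
    if (h >= length(p$hap_masks)) {
      direct[[length(direct) + 1L]] <-
        list(path_id = p$id, read_off = states$read_off[i], hap_off = h,
             reason = "path-end")
      key[i] <- NA_character_
      next
    }
    key[i] <- paste(p$locus_kind[h + 1L], p$locus_id[h + 1L],
                    p$locus_off[h + 1L], states$read_off[i], sep = "|")
  }
  for (k in unique(key[!is.na(key)])) {
    idx <- which(!is.na(key) & key == k)
    i1 <- idx[1]
    p <- tree$paths[[as.character(states$path_id[i1])]]
    h <- states$hap_off[i1]
    kind <- if (p$locus_kind[h + 1L] == 0L) "successor-node" else "new-variant"
    entries[[length(entries) + 1L]] <- list(
      kind = kind,
      node = if (kind == "successor-node") p$locus_id[h + 1L] else NA_integer_,
      node_off = if (kind == "successor-node") p$locus_off[h + 1L] else NA_integer_,
      var = if (kind == "new-variant") p$locus_id[h + 1L] else NA_integer_,
      alt_off = if (kind == "new-variant") p$locus_off[h + 1L] else NA_integer_,
      read_off = states$read_off[i1],
      path_ids = states$path_id[idx],
      hap_offs = states$hap_off[idx])
  }
  list(entries = entries, direct = direct)
}

#' Breadth-first extension of a match frontier over the variation tree
#'
#' Processes the queue to exhaustion. Every live path stops exactly once:
#' with reason `"mismatch"` (next base fails the SNP-tolerant site test,
#' including inside insertion alleles, where matching is exact), `"read-end"`
#' (read fully consumed) or `"path-end"` (haplotype exhausted). Deletion
#' edges consume zero read bases and resume at their end node; insertion
#' edges consume read bases 1:1 against the alternate allele.
#'
#' @param tree A `variation_tree` with paths attached.
#' @param read Read string.
#' @param frontier As built by [make_frontier()] from per-path states, or a
#'   data frame with columns `path_id`, `read_off`, `hap_off`.
#' @return A data frame of hits: `path_id`, `read_off`, `hap_off`, `reason`;
#'   attribute `"ops"` counts match-run segment operations.
#' @export
traverse_extend <- function(tree, read, frontier) {
  if (is.data.frame(frontier)) frontier <- make_frontier(tree, frontier)
  rb <- base_bits(read)
  rlen <- length(rb)
  hits <- frontier$direct
  queue <- frontier$entries
  ops <- 0L
  add_hit <- function(pids, roffs, hoffs, reason) {
    for (j in seq_along(pids))
      hits[[length(hits) + 1L]] <<- list(path_id = pids[j], read_off = roffs[j],
                                         hap_off = hoffs[j], reason = reason)
  }
  requeue <- function(states) {
    f <- make_frontier(tree, states)
    hits <<- c(hits, f$direct)
    queue <<- c(queue, f$entries)
  }
  while (length(queue) > 0L) {
    en <- queue[[1]]; queue <- queue[-1]
    pids <- en$path_ids; hoffs <- en$hap_offs; r <- en$read_off
    if (en$kind == "new-variant") {
      # insertion allele: exact matching (single-bit codes), no SNP lookup
      p1 <- tree$paths[[as.character(pids[1])]]
      vrow <- p1$vars[p1$vars$id == en$var, ][1, ]
      ab <- base_bits(vrow$alt_allele)
      ops <- ops + 1L
      m <- match_run(rb, r, ab, en$alt_off)
      avail <- length(ab) - en$alt_off
      if (m < avail && r + m < rlen) {
        add_hit(pids, rep(r + m, length(pids)), hoffs + m, "mismatch")
      } else if (r + m >= rlen && m < avail) {
        add_hit(pids, rep(rlen, length(pids)), hoffs + m, "read-end")
      } else {
        # allele consumed: resume after the variant ("variant-end-node")
        requeue(data.frame(path_id = pids, read_off = r + m,
                           hap_off = hoffs + m))
      }
      next
    }
    node <- tree$nodes[[en$node]]
    lab <- node$masks
    pos <- en$node_off
    adv <- 0L
    paths <- lapply(pids, function(id) tree$paths[[as.character(id)]])
    repeat {
      depth <- node$off + pos
      # next offset where any live path takes a not-yet-crossed variant
      # within this node (vhap >= current hap offset excludes variants the
      # path has already traversed, e.g. a consumed insertion allele)
      stops <- Inf
      for (pi in seq_along(paths)) {
        p <- paths[[pi]]
        if (nrow(p$vars) > 0L) {
          cand <- p$vars$rel[p$vars$rel >= depth &
                             p$vars$rel < node$off + length(lab) &
                             p$vars$vhap >= hoffs[pi] + adv]
          if (length(cand) > 0L) stops <- min(stops, cand)
        }
      }
      seg_end <- as.integer(min(stops, node$off + length(lab)))
      seg_len <- seg_end - depth
      ops <- ops + 1L
      m <- if (seg_len > 0L) {
        n <- min(rlen - (r + adv), seg_len)
        if (n <= 0L) 0L else {
          bad <- which(bitwAnd(rb[(r + adv + 1L):(r + adv + n)],
                               lab[(pos + 1L):(pos + n)]) == 0L)
          if (length(bad) == 0L) n else bad[1] - 1L
        }
      } else 0L
      adv <- adv + m; pos <- pos + m
      if (r + adv >= rlen) {                       # read exhausted
        add_hit(pids, rep(rlen, length(pids)), hoffs + adv, "read-end")
        break
      }
      if (m < seg_len) {                           # mismatch inside segment
        add_hit(pids, rep(r + adv, length(pids)), hoffs + adv, "mismatch")
        break
      }
      depth <- node$off + pos
      if (is.finite(stops) && depth == stops) {    # variant decision point
        taking <- vapply(seq_along(paths), function(pi) {
          p <- paths[[pi]]
          if (nrow(p$vars) == 0L) return(NA_integer_)
          hit <- p$vars$id[p$vars$rel == depth &
                           p$vars$vhap >= hoffs[pi] + adv]
          if (length(hit) > 0L) hit[1] else NA_integer_
        }, integer(1))
        for (v in unique(taking[!is.na(taking)])) {
          sel <- which(!is.na(taking) & taking == v)
          p1 <- paths[[sel[1]]]
          vrow <- p1$vars[p1$vars$id == v, ][1, ]
          if (vrow$vtype == "INS") {
            queue[[length(queue) + 1L]] <- list(
              kind = "new-variant", node = NA_integer_, node_off = NA_integer_,
              var = v, alt_off = 0L, read_off = r + adv,
              path_ids = pids[sel], hap_offs = hoffs[sel] + adv)
          } else {                                  # DEL: zero read bases
            requeue(data.frame(path_id = pids[sel], read_off = r + adv,
                               hap_off = hoffs[sel] + adv))
          }
        }
        keepi <- which(is.na(taking))
        if (length(keepi) == 0L) break
        pids <- pids[keepi]; hoffs <- hoffs[keepi]; paths <- paths[keepi]
        next
      }
      # node exhausted: requeue by per-path locus; make_frontier regroups
      # into adjacent-successor entries and reports path ends directly
      requeue(data.frame(path_id = pids, read_off = r + adv,
                         hap_off = hoffs + adv))
      break
    }
  }
  out <- if (length(hits) == 0L)
    data.frame(path_id = integer(0), read_off = integer(0),
               hap_off = integer(0), reason = character(0)) else
    data.frame(path_id = vapply(hits, `[[`, integer(1), "path_id"),
               read_off = vapply(hits, function(h) as.integer(h$read_off), integer(1)),
               hap_off = vapply(hits, function(h) as.integer(h$hap_off), integer(1)),
               reason = vapply(hits, `[[`, character(1), "reason"))
  attr(out, "ops") <- ops
  out
}
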