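# VARA: the generalized Landau-Vishkin over a variation tree.
#
# The edit-distance state is a 3-D structure L[e][d] whose cell holds, per
# path id, the farthest (read_off, hap_off) reached with e edits on net
# reference diagonal d (d = read consumed - reference consumed, so read
# insertions push d positive, deletions negative; INDEL edges of the tree
# shift d at zero edit cost because the realized haplotype already contains
# them). Each round seeds every live cell with the three Landau-Vishkin
# moves, then calls the VATR traversal as the innermost extension and keeps,
# per (path id, d), the longest extension for the next round. A candidate is
# emitted whenever a path consumes the entire read.

#' Configuration for variation-aware extension
#'
#' @param e_max Maximum edit distance; default `ceiling(error_budget *
#'   read_length)` computed per read.
#' @param error_budget Fraction of the read length allowed as novel edits
#'   when `e_max` is `NULL` (default 0.06: Illumina error plus small
#'   unindexed variants).
#' @param large_len Length (bp) from which an INDEL counts as a "large"
#'   variant for the pruning heuristic.
#' @param max_large_per_100bp Pruning rate: a path is terminated once it
#'   carries more than `ceiling(max_large_per_100bp * read_len / 100)` large
#'   variants.
#' @param path_cap Hard cap on enumerated paths per tree.
#' @param max_variants_per_path Cap on INDELs combined on one path.
#' @param exhaustive Continue to `e_max` even after the first emission.
#' @return A list of class `vara_config`.
#' @export
vara_config <- function(e_max = NULL, error_budget = 0.06, large_len = 4L,
                        max_large_per_100bp = 3L, path_cap = 256L,
                        max_variants_per_path = 5L, exhaustive = FALSE) {
  structure(list(e_max = e_max, error_budget = error_budget,
                 large_len = as.integer(large_len),
                 max_large_per_100bp = as.integer(max_large_per_100bp),
                 path_cap = as.integer(path_cap),
                 max_variants_per_path = as.integer(max_variants_per_path),
                 exhaustive = isTRUE(exhaustive)),
            class = "vara_config")
}

#' Path pruning heuristic
#'
#' Terminates a path once its edit distance would exceed `e_max` or it
#' carries too many large variants (default rate: 3 per 100 bp of read).
#'
#' @param path_state List with `e`, `taken_lens` (lengths of INDELs taken so
#'   far) and `read_len`.
#' @param cfg A [vara_config()]; `cfg$e_max` must be set.
#' @return `TRUE` if the path should be terminated.
#' @export
prune_path <- function(path_state, cfg) {
  if (!is.null(cfg$e_max) && path_state$e > cfg$e_max) return(TRUE)
  nlarge <- sum(path_state$taken_lens >= cfg$large_len)
  nlarge > ceiling(cfg$max_large_per_100bp * path_state$read_len / 100)
}

#' Per-(path, diagonal) longest-extension selection
#'
#' Keeps, for every (path id, d) pair, the hit with the longest extension;
#' ties broken by smaller resume cursor (`hap_off`), then smaller path id.
#'
#' @param hits Data frame with columns `path_id`, `d`, `read_off`, `hap_off`.
#' @return The surviving rows, one per (path id, d).
#' @export
select_longest <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  o <- order(hits$path_id, hits$d, -hits$read_off, hits$hap_off)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h[c("path_id", "d")]), , drop = FALSE]
}

# ids of a path's variants crossed by an extension reaching hap_off
# (insertions count as soon as entered; deletions once strictly passed).
crossed_vars <- function(p, hap_off) {
  if (nrow(p$vars) == 0L) return(p$vars[0, ])
  cr <- ifelse(p$vars$vtype == "INS", p$vars$vhap < hap_off,
               p$vars$vhap < hap_off)
  p$vars[cr, , drop = FALSE]
}

# ALT-coordinate CIGAR (read vs realized haplotype) from the edit-event
# trace; mismatches stay M.
build_alt_cigar <- function(events, read_len) {
  ops <- character(0); lens <- integer(0)
  push <- function(op, n) {
    if (n <= 0L) return(invisible())
    k <- length(ops)
    if (k > 0L && ops[k] == op) lens[k] <<- lens[k] + n
    else { ops <<- c(ops, op); lens <<- c(lens, n) }
  }
  r <- 0L
  for (ev in events) {
    push("M", ev[2] - r)
    r <- ev[2]
    if (ev[1] == 1L) { push("M", 1L); r <- r + 1L }       # mismatch
    else if (ev[1] == 2L) { push("I", 1L); r <- r + 1L }  # read insertion
    else push("D", 1L)                                    # haplotype deletion
  }
  push("M", read_len - r)
  paste0(lens, ops, collapse = "")
}

#' Variation-aware alignment of a read against a variation tree
#'
#' Runs the generalized Landau-Vishkin iteration with the VATR breadth-first
#' traversal as the innermost extension. The read start is pinned to the tree
#' root (semiglobal extension); the far ends of both read and haplotypes are
#' free. Known INDEL edges shift the reference diagonal at zero edit cost;
#' novel differences are charged unit Levenshtein costs. Stops at the least
#' `e` with at least one full-read alignment unless `cfg$exhaustive`.
#'
#' @param tree A `variation_tree` (paths are enumerated on demand).
#' @param read Read string (non-empty).
#' @param cfg A [vara_config()].
#' @return A list of candidate alignments sorted by (e, number of taken
#'   variants, path id); each has `path_id`, `e`, `d`, `cigar` (ALT
#'   coordinates), `hap_consumed`, `var_ids`, `window`. Attributes: `"ops"`
#'   (VATR segment-operation counter), `"pruned"` (TRUE if any path was
#'   pruned), `"e_max"`.
#' @export
vara_align <- function(tree, read, cfg = vara_config()) {
  if (!nzchar(read))
    stop2("varatree_error_empty_read", "read must be non-empty")
  if (is.null(tree$paths))
    tree <- set_paths(tree, enumerate_paths(tree, cfg$max_variants_per_path,
                                            cfg$path_cap))
  rlen <- nchar(read)
  e_max <- cfg$e_max %||% as.integer(ceiling(cfg$error_budget * rlen))
  cfg$e_max <- e_max
  paths <- tree$paths
  refcons <- lapply(paths, `[[`, "refcons")
  hap_len <- vapply(paths, function(p) length(p$hap_masks), integer(1))
  names(hap_len) <- names(paths)
  ops_total <- 0L
  pruned_any <- FALSE
  emitted <- list()

  d_of <- function(pid, r, h) r - refcons[[as.character(pid)]][h + 1L]

  run_layer <- function(seeds) {
    # seeds: list of states (path_id, read_off, hap_off, events), unique per
    # (path, d); returns the new states and emissions
    new_states <- list()
    emits <- list()
    finish <- function(st) {
      emits[[length(emits) + 1L]] <<- st
    }
    # immediate emissions: read already consumed by the seeding step
    live <- list()
    for (st in seeds) {
      if (st$read_off >= rlen) finish(st) else live[[length(live) + 1L]] <- st
    }
    if (length(live) > 0L) {
      bydf <- data.frame(
        path_id = vapply(live, `[[`, integer(1), "path_id"),
        read_off = vapply(live, `[[`, integer(1), "read_off"),
        hap_off = vapply(live, `[[`, integer(1), "hap_off"))
      d <- bydf$read_off - bydf$hap_off     # read-vs-haplotype diagonal
      for (dd in unique(d)) {
        sel <- which(d == dd)
        hits <- traverse_extend(tree, read, bydf[sel, , drop = FALSE])
        ops_total <<- ops_total + attr(hits, "ops")
        for (j in seq_len(nrow(hits))) {
          si <- sel[match(hits$path_id[j], bydf$path_id[sel])]
          st <- live[[si]]
          st$read_off <- hits$read_off[j]
          st$hap_off <- hits$hap_off[j]
          if (hits$reason[j] == "read-end" ||
              (hits$reason[j] == "path-end" && st$read_off >= rlen)) {
            finish(st)
          } else {
            new_states[[length(new_states) + 1L]] <- st
          }
        }
      }
    }
    list(states = new_states, emits = emits)
  }

  # merge on the read-vs-haplotype diagonal: two states of one path on the
  # same haplotype diagonal share their future, so only the longest
  # extension survives. (The reference-relative d reported on candidates
  # additionally carries the net displacement of the taken variant edges; it
  # is not injective over traversal states inside insertion alleles and so
  # cannot serve as the merge key.)
  dedup_states <- function(states) {
    if (length(states) <= 1L) return(states)
    keyed <- new.env(parent = emptyenv())
    for (st in states) {
      k <- paste0(st$path_id, "|", st$read_off - st$hap_off)
      old <- keyed[[k]]
      if (is.null(old) || st$read_off > old$read_off)
        keyed[[k]] <- st
    }
    as.list(keyed)
  }

  # e = 0: all paths pinned at the root
  seeds0 <- lapply(paths, function(p)
    list(path_id = p$id, read_off = 0L, hap_off = 0L, events = list()))
  layer <- run_layer(unname(seeds0))
  states <- dedup_states(layer$states)
  record_emits <- function(emits, e) {
    for (st in emits)
      emitted[[length(emitted) + 1L]] <<-
        c(st, list(e = e, d = d_of(st$path_id, st$read_off, st$hap_off)))
  }
  record_emits(layer$emits, 0L)

  e <- 0L
  while ((length(emitted) == 0L || cfg$exhaustive) && e < e_max &&
         length(states) > 0L) {
    e <- e + 1L
    seeds <- list()
    for (st in states) {
      p <- paths[[as.character(st$path_id)]]
      taken <- crossed_vars(p, st$hap_off)
      if (prune_path(list(e = e, taken_lens = taken$len, read_len = rlen),
                     cfg)) { pruned_any <- TRUE; next }
      r <- st$read_off; h <- st$hap_off
      if (r < rlen && h < hap_len[[as.character(st$path_id)]])
        seeds[[length(seeds) + 1L]] <- list(
          path_id = st$path_id, read_off = r + 1L, hap_off = h + 1L,
          events = c(st$events, list(c(1L, r, h))))
      if (r < rlen)
        seeds[[length(seeds) + 1L]] <- list(
          path_id = st$path_id, read_off = r + 1L, hap_off = h,
          events = c(st$events, list(c(2L, r, h))))
      if (h < hap_len[[as.character(st$path_id)]])
        seeds[[length(seeds) + 1L]] <- list(
          path_id = st$path_id, read_off = r, hap_off = h + 1L,
          events = c(st$events, list(c(3L, r, h))))
    }
    seeds <- dedup_states(seeds)
    layer <- run_layer(seeds)
    states <- dedup_states(layer$states)
    record_emits(layer$emits, e)
  }

  cands <- lapply(emitted, function(st) {
    p <- paths[[as.character(st$path_id)]]
    taken <- crossed_vars(p, st$hap_off)
    list(path_id = st$path_id, e = st$e, d = st$d,
         cigar = build_alt_cigar(st$events, rlen),
         hap_consumed = st$hap_off, var_ids = taken$id,
         n_vars = nrow(taken), window = p$window)
  })
  if (length(cands) > 0L) {
    o <- order(vapply(cands, `[[`, integer(1), "e"),
               vapply(cands, `[[`, integer(1), "n_vars"),
               vapply(cands, `[[`, integer(1), "path_id"))
    cands <- cands[o]
    # one candidate per path id (the best)
    cands <- cands[!duplicated(vapply(cands, `[[`, integer(1), "path_id"))]
  }
  structure(cands, ops = ops_total, pruned = pruned_any, e_max = e_max,
            states = states, class = "vara_alignments")
}

#' @export
print.vara_alignments <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<vara_alignments> no full-read alignment within e_max\n")
    return(invisible(x))
  }
  cat(sprintf("<vara_alignments> %d candidate(s); best e = %d\n",
              length(x), x[[1]]$e))
  for (c in x[seq_len(min(5L, length(x)))])
    cat(sprintf("  path %d  e=%d d=%+d  %s  variants: %s\n", c$path_id, c$e,
                c$d, c$cigar,
                if (c$n_vars == 0L) "-" else paste(c$var_ids, collapse = ",")))
  invisible(x)
}
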