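# The variation tree: a per-seed pseudo-trie over local extension windows.
#
# Shared prefixes of the window sequences (compared as (site code, ref base)
# pairs) merge into maximal shared nodes, radix-trie style. SNPs live inside
# the 4-bit site codes of node labels and never branch the tree; only INDELs
# create optional variant edges. Haplotype paths -- one choice of
# non-overlapping INDELs per window -- are enumerated up-front with unique
# ids; paths realizing identical sequences are deduplicated keeping the
# smallest id, with all source windows retained as provenance.

#' Construct a local extension window over a variation-aware reference
#'
#' @param ref A `varef`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open reference interval; clamped to the
#'   chromosome with attribute `"truncated"` set when clamping occurred.
#' @param side `"right"` or `"left"` of the seed.
#' @param strand `"+"` or `"-"`.
#' @return A `region_window` list carrying the decoded site codes.
#' @export
region_window <- function(ref, chrom, start, end, side = "right",
                          strand = "+") {
  len <- .chrom(ref, chrom)
  s <- max(0L, as.integer(start)); e <- min(length(len$mask), as.integer(end))
  if (s >= e)
    stop2("varatree_error_empty_window", "empty extension window")
  w <- list(chrom = chrom, start = s, end = e, side = side, strand = strand,
            masks = len$mask[(s + 1L):e],
            seq = substr(len$seq, s + 1L, e))
  attr(w, "truncated") <- (s != start || e != end)
  class(w) <- "region_window"
  w
}

# A window from raw sequence (tests / reflected windows).
window_from_seq <- function(seq, start = 0L, chrom = "w", masks = NULL,
                            side = "right", strand = "+") {
  seq <- toupper(seq)
  bits <- base_bits(seq)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(start) + nchar(seq), side = side,
                 strand = strand,
                 masks = if (is.null(masks)) ifelse(bits == 0L, 15L, bits)
                         else as.integer(masks),
                 seq = seq),
            class = "region_window")
}

empty_variants <- function() {
  variant_records(character(0), integer(0), character(0), character(0),
                  character(0))
}

#' Build a variation tree over one or more extension windows
#'
#' Inserts each window's site-code sequence into a radix trie (children
#' ordered alphabetically by leading reference base; nodes are maximal shared
#' fragments), then attaches every variant overlapping a window to the
#' node(s) covering its position in that window. A deletion whose end lies
#' beyond the window creates a pseudo node holding the out-of-window deleted
#' reference bases. With no variants and one window the tree degenerates to a
#' linear chain.
#'
#' @param windows A `region_window` or list of them (same side of one seed).
#' @param variants Variant table in absolute reference coordinates (INDELs;
#'   SNPs are already folded into the window site codes). Variants outside
#'   every window are dropped with a message.
#' @return An object of class `variation_tree`.
#' @export
build_tree <- function(windows, variants = empty_variants()) {
  if (inherits(windows, "region_window")) windows <- list(windows)
  if (length(windows) == 0L)
    stop2("varatree_error_empty_window", "at least one window is required")
  nodes <- list()
  new_node <- function(parent, off, masks, seq, is_pseudo = FALSE) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, off = as.integer(off),
                         masks = as.integer(masks), seq = seq,
                         children = integer(0), ends = integer(0),
                         variants = NULL, is_pseudo = is_pseudo)
    id
  }
  root <- new_node(0L, 0L, integer(0), "")

  insert_window <- function(w_id, masks, seq) {
    cur <- root; pos <- 0L; W <- length(masks)
    chars <- strsplit(seq, "")[[1]]
    repeat {
      if (pos == W) { nodes[[cur]]$ends <<- c(nodes[[cur]]$ends, w_id); return(invisible()) }
      kids <- nodes[[cur]]$children
      nxt <- 0L
      for (k in kids) {
        if (length(nodes[[k]]$masks) > 0L &&
            nodes[[k]]$masks[1] == masks[pos + 1L] &&
            substr(nodes[[k]]$seq, 1L, 1L) == chars[pos + 1L]) { nxt <- k; break }
      }
      if (nxt == 0L) {
        leaf <- new_node(cur, pos, masks[(pos + 1L):W],
                         substr(seq, pos + 1L, W))
        nodes[[cur]]$children <<- order_children(c(kids, leaf))
        nodes[[leaf]]$ends <<- w_id
        return(invisible())
      }
      lab <- nodes[[nxt]]$masks
      labc <- nodes[[nxt]]$seq
      nmax <- min(length(lab), W - pos)
      L <- 0L
      while (L < nmax && lab[L + 1L] == masks[pos + L + 1L] &&
             substr(labc, L + 1L, L + 1L) == chars[pos + L + 1L]) L <- L + 1L
      if (L == length(lab)) { cur <- nxt; pos <- pos + L; next }
      # split nxt at L: intermediate keeps prefix, nxt keeps suffix
      mid <- new_node(cur, pos, lab[seq_len(L)], substr(labc, 1L, L))
      nodes[[cur]]$children <<-
        order_children(replace(kids, kids == nxt, mid))
      nodes[[nxt]]$parent <<- mid
      nodes[[nxt]]$off <<- pos + L
      nodes[[nxt]]$masks <<- lab[(L + 1L):length(lab)]
      nodes[[nxt]]$seq <<- substr(labc, L + 1L, nchar(labc))
      nodes[[mid]]$children <<- nxt
      cur <- mid; pos <- pos + L
    }
  }
  order_children <- function(ids) {
    if (length(ids) <= 1L) return(ids)
    lead <- vapply(ids, function(i) substr(nodes[[i]]$seq, 1L, 1L), character(1))
    leadm <- vapply(ids, function(i) nodes[[i]]$masks[1], integer(1))
    ids[order(lead, leadm)]
  }

  for (i in seq_along(windows))
    insert_window(i, windows[[i]]$masks, windows[[i]]$seq)

  # per-window root-to-end node chain
  win_chains <- vector("list", length(windows))
  for (nid in seq_along(nodes)) {
    for (w in nodes[[nid]]$ends) {
      chain <- integer(0); cur <- nid
      while (cur != 0L && cur != root) { chain <- c(cur, chain); cur <- nodes[[cur]]$parent }
      win_chains[[w]] <- chain
    }
  }
  if (any(vapply(win_chains, is.null, logical(1))))
    stop2("varatree_error_internal", "window chain resolution failed")

  # attach variants per window (window-relative rel = pos - start)
  dropped <- 0L
  win_vars <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    if (nrow(variants) == 0L) {
      win_vars[[w]] <- cbind(variants, rel = integer(0)); next
    }
    span <- ifelse(variants$vtype == "INS", 0L, variants$len)
    ok <- variants$chrom == win$chrom &
      variants$pos >= win$start & variants$pos < win$end &
      ifelse(variants$vtype == "INS", TRUE, TRUE)
    vt <- variants[ok, , drop = FALSE]
    vt$rel <- vt$pos - win$start
    vt <- vt[order(vt$rel, vt$id), , drop = FALSE]
    win_vars[[w]] <- vt
  }
  in_any <- if (nrow(variants) == 0L) logical(0) else
    Reduce(`|`, lapply(seq_along(windows), function(w)
      variants$id %in% win_vars[[w]]$id), rep(FALSE, nrow(variants)))
  dropped <- sum(!in_any)
  if (dropped > 0L)
    message(sprintf("build_tree: dropped %d variant(s) outside every window", dropped))

  node_cover <- function(chain, rel) {
    # node in chain covering window-relative offset rel (label position)
    for (nid in chain) {
      o <- nodes[[nid]]$off; l <- length(nodes[[nid]]$masks)
      if (rel >= o && rel < o + l) return(c(nid, rel - o))
    }
    c(NA_integer_, NA_integer_)
  }

  # attach + pseudo nodes for deletions running past the window end
  for (w in seq_along(windows)) {
    vt <- win_vars[[w]]
    if (nrow(vt) == 0L) next
    W <- length(windows[[w]]$masks)
    resume_node <- integer(nrow(vt)); resume_off <- integer(nrow(vt))
    for (i in seq_len(nrow(vt))) {
      rel <- vt$rel[i]
      cov <- node_cover(win_chains[[w]], min(rel, W - 1L))
      att <- tibble::tibble(window = w, node_off = cov[2] + (rel - min(rel, W - 1L)),
                            var_id = vt$id[i], vtype = vt$vtype[i],
                            len = vt$len[i], rel = rel)
      nodes[[cov[1]]]$variants <- rbind(nodes[[cov[1]]]$variants, att)
      if (vt$vtype[i] == "DEL") {
        dend <- rel + vt$len[i]
        if (dend < W) {
          rc <- node_cover(win_chains[[w]], dend)
          resume_node[i] <- rc[1]; resume_off[i] <- rc[2]
        } else if (dend == W) {
          resume_node[i] <- 0L; resume_off[i] <- 0L   # window exhausted
        } else {
          # pseudo node with the out-of-window deleted reference bases
          over <- substr(vt$ref_allele[i], W - rel + 1L, vt$len[i])
          tail_node <- win_chains[[w]][length(win_chains[[w]])]
          ps <- new_node(tail_node, W, base_bits(over), over, is_pseudo = TRUE)
          nodes[[tail_node]]$children <-
            order_children(c(nodes[[tail_node]]$children, ps))
          resume_node[i] <- 0L; resume_off[i] <- 0L
        }
      } else {
        rc <- if (rel < W) node_cover(win_chains[[w]], rel) else c(0L, 0L)
        resume_node[i] <- rc[1]; resume_off[i] <- rc[2]
      }
    }
    vt$resume_node <- resume_node; vt$resume_off <- resume_off
    win_vars[[w]] <- vt
  }

  structure(list(nodes = nodes, root = root, windows = windows,
                 win_chains = win_chains, win_vars = win_vars,
                 variants = variants, paths = NULL),
            class = "variation_tree")
}

#' @export
print.variation_tree <- function(x, ...) {
  cat(sprintf("<variation_tree> %d node(s), %d window(s), %d variant(s)%s\n",
              length(x$nodes) - 1L, length(x$windows),
              sum(vapply(x$win_vars, nrow, integer(1))),
              if (is.null(x$paths)) "" else
                sprintf(", %d path(s)", length(x$paths))))
  invisible(x)
}

#' Dump a variation tree as plain text (one node per line)
#' @param tree A `variation_tree`.
#' @return Character vector of lines `id parent off label [variants]`.
#' @export
tree_dump <- function(tree) {
  vapply(tree$nodes, function(n) {
    vs <- if (is.null(n$variants)) "" else
      paste0(" [", paste(sprintf("%s:%d@%d", n$variants$vtype,
                                 n$variants$var_id, n$variants$node_off),
                         collapse = " "), "]")
    sprintf("%d\t%d\t%d\t%s%s%s", n$id, n$parent, n$off,
            if (nzchar(n$seq)) n$seq else ".",
            if (n$is_pseudo) "*" else "", vs)
  }, character(1))
}

# Realize one haplotype: window w with the variant rows `vars` applied.
# Returns hap string/masks, per-base locus (node/ins), ref consumption
# prefix sums, hap->ref map and M/VI/VD segments for CIGAR composition.
realize_path <- function(tree, w, vars) {
  win <- tree$windows[[w]]
  W <- length(win$masks)
  chain <- tree$win_chains[[w]]
  loc_node <- integer(W); loc_off <- integer(W)
  for (nid in chain) {
    o <- tree$nodes[[nid]]$off; l <- length(tree$nodes[[nid]]$masks)
    if (l > 0L) { loc_node[(o + 1L):(o + l)] <- nid; loc_off[(o + 1L):(o + l)] <- 0L:(l - 1L) }
  }
  hap_masks <- integer(0); hap_chars <- character(0)
  lk <- integer(0); li <- integer(0); lo <- integer(0)  # locus kind/id/off
  h2r <- integer(0)                                     # abs ref pos or NA
  segs <- list()
  refcons <- 0
  rc <- numeric(0)                                      # refcons after each hap base
  t <- 0L
  add_m <- function(from, to) {
    if (to <= from) return(invisible())
    n <- to - from
    hap_masks <<- c(hap_masks, win$masks[(from + 1L):to])
    hap_chars <<- c(hap_chars, strsplit(substr(win$seq, from + 1L, to), "")[[1]])
    lk <<- c(lk, rep(0L, n)); li <<- c(li, loc_node[(from + 1L):to])
    lo <<- c(lo, loc_off[(from + 1L):to])
    h2r <<- c(h2r, win$start + from:(to - 1L))
    rc <<- c(rc, refcons + seq_len(n))
    refcons <<- refcons + n
    segs[[length(segs) + 1L]] <<- list(op = "M", len = n)
  }
  vhap <- integer(nrow(vars))   # hap offset where each variant applies
  if (nrow(vars) > 0L) {
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      if (v$rel < t) stop2("varatree_error_internal", "overlapping variants on one path")
      add_m(t, v$rel)
      vhap[i] <- length(lk)
      if (v$vtype == "INS") {
        a <- strsplit(v$alt_allele, "")[[1]]
        hap_masks <- c(hap_masks, base_bits(v$alt_allele))
        hap_chars <- c(hap_chars, a)
        lk <- c(lk, rep(1L, v$len)); li <- c(li, rep(v$id, v$len))
        lo <- c(lo, 0L:(v$len - 1L))
        h2r <- c(h2r, rep(NA_integer_, v$len))
        rc <- c(rc, rep(refcons, v$len))
        segs[[length(segs) + 1L]] <- list(op = "VI", len = v$len)
        t <- v$rel
      } else {                                          # DEL
        segs[[length(segs) + 1L]] <- list(op = "VD", len = v$len)
        refcons <- refcons + v$len
        t <- v$rel + v$len
        if (t >= W) { t <- W; break }
      }
    }
  }
  add_m(t, W)
  seg_tab <- if (length(segs) == 0L)
    data.frame(op = character(0), len = integer(0)) else
    data.frame(op = vapply(segs, `[[`, character(1), "op"),
               len = vapply(segs, `[[`, integer(1), "len"))
  vars$vhap <- vhap
  list(hap = paste0(hap_chars, collapse = ""), hap_masks = hap_masks,
       locus_kind = lk, locus_id = li, locus_off = lo,
       hap2ref = h2r, refcons = c(0, rc), segs = seg_tab, vars2 = vars)
}

#' Enumerate the haplotype paths of a variation tree
#'
#' Per window, every subset of its attached INDELs with pairwise
#' non-overlapping reference intervals (and at most `max_variants_per_path`
#' members) defines one path. Ids are assigned deterministically: windows in
#' input order; within a window, a depth-first recursion over variants sorted
#' by position (ties by variant id) that explores the variant-free branch
#' before the variant-taking branch — so the all-reference path of window 1
#' always has id 1. Paths realizing identical haplotype strings are
#' deduplicated keeping the smallest id; their source windows are merged into
#' the survivor's provenance.
#'
#' @param tree A `variation_tree`.
#' @param max_variants_per_path Cap on INDELs combined on one path.
#' @param path_cap Hard cap on enumerated paths before deduplication;
#'   exceeding it raises `varatree_error_path_overflow` (callers should
#'   prune, e.g. lower `max_variants_per_path`).
#' @return Named list of path objects (names are ids as strings).
#' @export
enumerate_paths <- function(tree, max_variants_per_path = 5L,
                            path_cap = 256L) {
  paths <- list()
  next_id <- 1L
  for (w in seq_along(tree$windows)) {
    vt <- tree$win_vars[[w]]
    sets <- list(integer(0))
    if (nrow(vt) > 0L) {
      sets <- list()
      recurse <- function(i, chosen) {
        if (length(sets) > path_cap)
          stop2("varatree_error_path_overflow",
                "path enumeration exceeded the configured cap; prune variants")
        if (i > nrow(vt)) { sets[[length(sets) + 1L]] <<- chosen; return(invisible()) }
        recurse(i + 1L, chosen)                          # variant-free step first
        v <- vt[i, ]
        compatible <- TRUE
        if (length(chosen) > 0L) {
          ch <- vt[match(chosen, vt$id), ]
          s1 <- v$rel; e1 <- s1 + ifelse(v$vtype == "INS", 0L, v$len)
          s2 <- ch$rel; e2 <- s2 + ifelse(ch$vtype == "INS", 0L, ch$len)
          overl <- (s1 < e2 & e1 > s2) |
            (v$vtype == "INS" & ch$vtype == "INS" & s1 == s2) |
            (v$vtype == "INS" & ch$vtype != "INS" & s1 > s2 & s1 < e2) |
            (v$vtype != "INS" & ch$vtype == "INS" & s2 > s1 & s2 < e1)
          compatible <- !any(overl)
        }
        if (compatible && length(chosen) < max_variants_per_path)
          recurse(i + 1L, c(chosen, v$id))
      }
      recurse(1L, integer(0))
    }
    for (set in sets) {
      vars <- vt[vt$id %in% set, , drop = FALSE]         # already rel-sorted
      r <- realize_path(tree, w, vars)
      p <- c(list(id = next_id, window = w, var_ids = vars$id,
                  vars = r$vars2, provenance = w), r[names(r) != "vars2"])
      paths[[as.character(next_id)]] <- p
      next_id <- next_id + 1L
    }
  }
  # dedup identical realized sequences, keep smallest id
  haps <- vapply(paths, `[[`, character(1), "hap")
  keep <- !duplicated(haps)
  for (i in which(!keep)) {
    j <- which(haps == haps[i])[1]
    paths[[j]]$provenance <- unique(c(paths[[j]]$provenance, paths[[i]]$window))
  }
  paths[keep]
}

#' Realized haplotype of one path
#'
#' @param tree A `variation_tree` with paths attached (see
#'   [enumerate_paths()]; [vara_align()] attaches them automatically).
#' @param path_id Integer path id.
#' @return List with `seq` (realized haplotype string), `masks` (site codes,
#'   insertion bases as exact single-bit codes) and `map` (per-base absolute
#'   reference position, `NA` inside insertions).
#' @export
path_sequence <- function(tree, path_id) {
  p <- tree$paths[[as.character(path_id)]]
  if (is.null(p))
    stop2("varatree_error_unknown_path", sprintf("unknown path id %s", path_id))
  list(seq = p$hap, masks = p$hap_masks, map = p$hap2ref)
}

set_paths <- function(tree, paths) { tree$paths <- paths; tree }
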