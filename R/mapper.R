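# End-to-end paired-end mapping: batch seeding and SNP-tolerant diagonal
# extension for the easy majority of reads, variation-aware VARA extension
# for reads that plain extension cannot explain (mainly INDEL-spanning
# reads), insert-size mate anchoring for ends without seeds, optimal pair
# selection and SAM emission.

#' Mapper configuration
#'
#' @param k,stride,repeat_cap Seed index parameters.
#' @param e_max Maximum edit distance per end; `NULL` = per-read
#'   `ceiling(error_budget * read_len)`.
#' @param error_budget Edit budget fraction when `e_max` is `NULL`.
#' @param g Mismatch budget of plain extension before the variation-aware
#'   path is invoked; `NULL` = `e_max`.
#' @param margin Extra window length (bp) so deletions can finish beyond the
#'   read span.
#' @param insert_mean,insert_sd,w Insert-size model: proper pairs must fall
#'   within `mean +/- w*sd` (plus `insert_slack` for spanned INDELs).
#' @param insert_slack Extra insert tolerance (bp) for INDEL-spanning pairs.
#' @param mapq_cap Maximum mapping quality.
#' @param max_cand Candidate loci kept per end.
#' @param large_len,max_large_per_100bp,path_cap,max_variants_per_path
#'   Passed to [vara_config()].
#' @return List of class `map_config`.
#' @export
map_config <- function(k = 16L, stride = 8L, repeat_cap = 64L,
                       e_max = NULL, error_budget = 0.06, g = NULL,
                       margin = 50L, insert_mean = 500, insert_sd = 25,
                       w = 4, insert_slack = 50L, mapq_cap = 60L,
                       max_cand = 8L, large_len = 4L,
                       max_large_per_100bp = 3L, path_cap = 256L,
                       max_variants_per_path = 5L) {
  structure(as.list(environment()), class = "map_config")
}

emax_for <- function(cfg, rl) {
  cfg$e_max %||% as.integer(ceiling(cfg$error_budget * rl))
}

vcfg_for <- function(cfg, e_max) {
  vara_config(e_max = e_max, large_len = cfg$large_len,
              max_large_per_100bp = cfg$max_large_per_100bp,
              path_cap = cfg$path_cap,
              max_variants_per_path = cfg$max_variants_per_path)
}

#' Decide whether an end needs variation-aware extension
#'
#' Plain SNP-tolerant diagonal extension handles an end whose best candidate
#' locus explains the full read with at most `min(e_max, g)` mismatches;
#' anything else (no seed hits, or more unexplained bases, typically from a
#' spanned INDEL) enters the VARA path.
#'
#' @param best_nmis Mismatch count of the best candidate diagonal
#'   (`NA` if the end has no seed hits).
#' @param e_max Edit budget for the read.
#' @param g Optional stricter mismatch budget.
#' @return Logical.
#' @export
needs_vara <- function(best_nmis, e_max, g = NULL) {
  is.na(best_nmis) || best_nmis > min(e_max, g %||% e_max)
}

#' Anchor windows for an unseeded mate
#'
#' For each hit of the mapped end, the expected window of the mate under the
#' insert model: `[pos + mean - w*sd - read_len, pos + mean + w*sd +
#' read_len]` downstream of a forward hit (mirrored upstream of a reverse
#' hit), clamped to the chromosome; the mate is expected on the opposite
#' strand.
#'
#' @param hits Tibble with `chrom`, `pos` (0-based leftmost), `strand`.
#' @param insert_model List with `mean`, `sd`, `w`.
#' @param read_len Mate read length.
#' @param lengths Named chromosome lengths (for clamping).
#' @return Tibble of windows: `chrom`, `start`, `end`, `strand` (expected
#'   mate strand).
#' @export
anchor_mate <- function(hits, insert_model, read_len, lengths = NULL) {
  mean <- insert_model$mean; sd <- insert_model$sd
  w <- insert_model$w %||% 4
  lo <- mean - w * sd - read_len; hi <- mean + w * sd + read_len
  start <- ifelse(hits$strand == "+", hits$pos + lo,
                  hits$pos + read_len - 1L - hi)
  end <- ifelse(hits$strand == "+", hits$pos + hi,
                hits$pos + read_len - 1L - lo)
  out <- tibble::tibble(chrom = hits$chrom,
                        start = as.integer(pmax(0, floor(start))),
                        end = as.integer(ceiling(end)),
                        strand = ifelse(hits$strand == "+", "-", "+"))
  if (!is.null(lengths))
    out$end <- pmin(out$end, as.integer(lengths[out$chrom]))
  out[out$end - out$start >= read_len, , drop = FALSE]
}

# Realize a linear window (site codes + sequence) with a sorted set of
# non-overlapping variants applied; the standalone analogue of a tree path.
realize_linear <- function(masks, seq, vars) {
  W <- length(masks)
  ops <- character(0); lens <- integer(0)
  hap <- character(0)
  refcons <- 0L
  rc <- integer(0)
  vhap <- integer(nrow(vars))
  t <- 0L
  add2 <- function(op, n, piece = NULL) {
    if (n <= 0L) return(invisible())
    ops <<- c(ops, op); lens <<- c(lens, n)
    if (op == "M") {
      hap <<- c(hap, piece); rc <<- c(rc, refcons + seq_len(n))
      refcons <<- refcons + n
    } else if (op == "VI") {
      hap <<- c(hap, piece); rc <<- c(rc, rep(refcons, n))
    } else refcons <<- refcons + n
  }
  if (nrow(vars) > 0L) {
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      add2("M", v$rel - t, strsplit(substr(seq, t + 1L, v$rel), "")[[1]])
      vhap[i] <- length(hap)
      if (v$vtype == "INS") {
        add2("VI", v$len, strsplit(v$alt_allele, "")[[1]])
        t <- v$rel
      } else {
        add2("VD", v$len)
        t <- v$rel + v$len
        if (t >= W) { t <- W; break }
      }
    }
  }
  add2("M", W - t, strsplit(substr(seq, t + 1L, W), "")[[1]])
  vars$vhap <- vhap
  list(hap = paste0(hap, collapse = ""), refcons = c(0L, rc),
       segs = data.frame(op = ops, len = lens), vars = vars)
}

rev_ops <- function(tab) tab[rev(seq_len(nrow(tab))), , drop = FALSE]

append_ops <- function(...) {
  tab <- do.call(rbind, list(...))
  m <- merge_ops(tab$op, tab$len)
  data.frame(op = m$ops, len = m$lens)
}

# Reflect a window's variants for left-side extension (sequence reversed,
# not complemented): a deletion [r, r+L) maps to [W-r-L, W-r); an insertion
# before base r maps to before base W-r; allele strings are reversed.
reflect_variants <- function(vars, W) {
  if (nrow(vars) == 0L) return(vars)
  rel2 <- ifelse(vars$vtype == "INS", W - vars$rel,
                 W - vars$rel - vars$len)
  out <- vars
  out$rel <- as.integer(rel2)
  out$ref_allele <- str_rev(vars$ref_allele)
  out$alt_allele <- str_rev(vars$alt_allele)
  out <- out[out$rel >= 0L & out$rel < W, , drop = FALSE]
  out[order(out$rel, out$id), , drop = FALSE]
}

# Best partial extension from leftover VARA states (for soft-clip fallback).
vara_best_partial <- function(a) {
  sts <- attr(a, "states")
  if (is.null(sts) || length(sts) == 0L) return(NULL)
  ro <- vapply(sts, `[[`, integer(1), "read_off")
  ne <- vapply(sts, function(s) length(s$events), integer(1))
  o <- order(-ro, ne)
  st <- sts[[o[1]]]
  list(read_off = st$read_off, hap_off = st$hap_off,
       e = length(st$events), events = st$events, path_id = st$path_id)
}

# One side of a seed: build window + tree, run VARA, return per-candidate
# (e, consumed hap, taken original-coordinate variant rows, alt op table,
# clip length). `reflected` = left side.
extend_side <- function(side_read, chrom, win_start, win_end, ref, alt_index,
                        vcfg, reflected = FALSE) {
  n <- nchar(side_read)
  if (n == 0L)
    return(list(list(e = 0L, vars = NULL, alt = NULL, clip = 0L,
                     hap_consumed = 0L, win_start = win_start,
                     win_end = win_end)))
  win <- region_window(ref, chrom, win_start, win_end)
  win_start <- win$start; win_end <- win$end
  W <- win_end - win_start
  vt <- variants_in_window(alt_index, chrom, win_start, win_end)
  vt <- vt[vt$pos >= win_start &
             vt$pos + ifelse(vt$vtype == "INS", 0L, vt$len) <= win_end, ,
           drop = FALSE]
  vt$rel <- vt$pos - win_start
  full_clip <- list(e = 0L, vars = NULL, alt = NULL, clip = n,
                    hap_consumed = 0L, win_start = win_start,
                    win_end = win_end)
  pack <- tryCatch({
    if (reflected) {
      wobj <- window_from_seq(str_rev(win$seq), start = 0L,
                              masks = rev(win$masks))
      vt2 <- reflect_variants(vt, W)
      vrec <- if (nrow(vt2) == 0L) empty_variants() else
        variant_records(rep("w", nrow(vt2)), vt2$rel, vt2$vtype,
                        vt2$ref_allele, vt2$alt_allele, id = vt2$id)
      tr <- build_tree(wobj, vrec)
      tr <- set_paths(tr, enumerate_paths(tr, vcfg$max_variants_per_path,
                                          vcfg$path_cap))
      list(tree = tr, res = vara_align(tr, str_rev(side_read), vcfg))
    } else {
      vrec <- if (nrow(vt) == 0L) empty_variants() else
        variant_records(rep(chrom, nrow(vt)), vt$pos, vt$vtype,
                        vt$ref_allele, vt$alt_allele, id = vt$id)
      tr <- build_tree(win, vrec)
      tr <- set_paths(tr, enumerate_paths(tr, vcfg$max_variants_per_path,
                                          vcfg$path_cap))
      list(tree = tr, res = vara_align(tr, side_read, vcfg))
    }
  }, varatree_error = function(e) NULL)
  if (is.null(pack)) return(list(full_clip))
  res <- pack$res
  out <- list()
  for (cand in res[seq_len(min(3L, length(res)))]) {
    vars <- vt[vt$id %in% cand$var_ids, , drop = FALSE]
    out[[length(out) + 1L]] <- list(
      e = cand$e, vars = vars, alt = parse_cigar(cand$cigar), clip = 0L,
      hap_consumed = cand$hap_consumed, win_start = win_start,
      win_end = win_end)
  }
  if (length(out) == 0L) {
    # no full-side alignment within e_max: clip the unexplained tail of the
    # best partial extension
    bp <- vara_best_partial(res)
    if (!is.null(bp) && bp$read_off > 0L) {
      p <- pack$tree$paths[[as.character(bp$path_id)]]
      taken <- crossed_vars(p, bp$hap_off)
      out[[1L]] <- list(
        e = bp$e, vars = vt[vt$id %in% taken$id, , drop = FALSE],
        alt = parse_cigar(build_alt_cigar(bp$events, bp$read_off)),
        clip = n - bp$read_off, hap_consumed = bp$hap_off,
        win_start = win_start, win_end = win_end)
    } else out <- list(full_clip)
  }
  out
}

#' Variation-aware extension around one seed
#'
#' Extends a seed hit exactly along its diagonal (SNP-tolerant), builds a
#' left and a right extension window around the exact block (window length =
#' unmatched read length plus a margin for deletions), fetches the regional
#' INDELs, builds one variation tree per side (the left side on reflected
#' coordinates so the seed-adjacent end stays pinned), runs [vara_align()]
#' on each side and splices side results with the exact block into
#' whole-read candidates restored to reference coordinates.
#'
#' @param seed List/row with `chrom`, `pos` (0-based), `read_off`; typically
#'   a [collect_seeds()] row.
#' @param read Read string (already reverse-complemented for - strand
#'   seeds).
#' @param ref A `varef`.
#' @param alt_index An `altseq_index`.
#' @param cfg A [map_config()].
#' @return List of candidates sorted by `e`: each with `chrom`, `pos`
#'   (0-based leftmost reference base), `cigar` (reference CIGAR), `e`,
#'   `n_vars`, `clipped`.
#' @export
extend_with_vara <- function(seed, read, ref, alt_index, cfg = map_config()) {
  rl <- nchar(read)
  chrom <- seed$chrom
  clen <- unname(ref$lengths[chrom])
  diag <- seed$pos - seed$read_off
  e_max <- emax_for(cfg, rl)
  vcfg <- vcfg_for(cfg, e_max)
  rb <- base_bits(read)
  lo <- max(0L, -diag); hi <- min(rl, clen - diag)   # read span inside chrom
  if (hi - lo < 1L) return(list())
  mask <- .chrom(ref, chrom)$mask
  mm <- which(bitwAnd(rb[(lo + 1L):hi], mask[(diag + lo + 1L):(diag + hi)]) == 0L) + lo
  # maximal clean run containing the seed (fallback: longest clean run)
  bounds <- c(lo, mm, hi)
  runs <- data.frame(s = c(lo, mm), e = c(mm - 1L, hi))
  runs$len <- runs$e - runs$s
  runs <- runs[runs$len > 0L, , drop = FALSE]
  if (nrow(runs) == 0L) return(list())
  inseed <- runs$s <= seed$read_off & runs$e >= seed$read_off + 1L
  ri <- if (any(inseed) && max(runs$len[inseed]) >= min(cfg$k, 16L))
    which(inseed)[which.max(runs$len[inseed])] else which.max(runs$len)
  s <- runs$s[ri]; e <- runs$e[ri]
  # back the exact block off a little: chance matches at a variant junction
  # must not push the extension window past the variant's position
  back <- min(6L, max(0L, (e - s - 4L) %/% 2L))
  s <- s + back; e <- e - back
  left <- extend_side(substr(read, 1L, s), chrom,
                      diag + s - (s + cfg$margin), diag + s,
                      ref, alt_index, vcfg, reflected = TRUE)
  right <- extend_side(substr(read, e + 1L, rl), chrom,
                       diag + e, diag + rl + cfg$margin,
                       ref, alt_index, vcfg, reflected = FALSE)
  cands <- list()
  for (cl in left) for (cr in right) {
    et <- cl$e + cr$e
    if (et > e_max) next
    cand <- tryCatch(
      splice_candidate(cl, cr, s, e, chrom, diag, read, ref),
      varatree_error = function(err) NULL)
    if (!is.null(cand)) { cand$e <- et; cands[[length(cands) + 1L]] <- cand }
  }
  if (length(cands) == 0L) return(list())
  o <- order(vapply(cands, `[[`, integer(1), "e"),
             vapply(cands, function(c) c$n_vars, integer(1)))
  cands <- cands[o]
  keys <- vapply(cands, function(c) paste(c$pos, c$cigar), character(1))
  cands[!duplicated(keys)]
}

# Assemble a whole-read candidate from left/right side results plus the
# exact seed block, and restore it to a reference CIGAR.
splice_candidate <- function(cl, cr, s, e, chrom, diag, read, ref) {
  rl <- nchar(read)
  # left side: aligned suffix of the original-orientation haplotype
  lvars <- cl$vars
  comb_start <- diag + s
  lead_clip <- cl$clip
  lalt <- NULL
  if (!is.null(cl$alt) && cl$hap_consumed + 0L >= 0L && s > 0L) {
    lw_masks_len <- cl$win_end - cl$win_start
    lv <- if (is.null(lvars) || nrow(lvars) == 0L) {
      ev <- empty_variants(); ev$rel <- integer(0); ev
    } else lvars[order(lvars$rel), , drop = FALSE]
    seqL <- substr(.chrom(ref, chrom)$seq, cl$win_start + 1L, cl$win_end)
    lin <- realize_linear(.chrom(ref, chrom)$mask[(cl$win_start + 1L):cl$win_end],
                          seqL, lv)
    H <- nchar(lin$hap)
    start_hap <- H - cl$hap_consumed
    if (start_hap < 0L)
      stop2("varatree_error_bad_cigar", "left extension over-consumed")
    # trim variants to the aligned suffix; shorten a straddling insertion
    lv2 <- lin$vars
    keep <- logical(nrow(lv2))
    if (nrow(lv2) > 0L) {
      for (i in seq_len(nrow(lv2))) {
        v <- lv2[i, ]
        if (v$vtype == "INS") {
          if (v$vhap + v$len <= start_hap) next
          if (v$vhap < start_hap) {      # partial leading insertion
            keepn <- v$vhap + v$len - start_hap
            lv2$alt_allele[i] <- substr(v$alt_allele, v$len - keepn + 1L, v$len)
            lv2$len[i] <- keepn
          }
          keep[i] <- TRUE
        } else keep[i] <- v$vhap > start_hap
      }
    }
    lv2 <- lv2[keep, , drop = FALSE]
    refstart_rel <- lin$refcons[start_hap + 1L]
    comb_start <- cl$win_start + refstart_rel
    lalt <- rev_ops(cl$alt)
    lvars <- lv2
  } else if (s > 0L) {
    lead_clip <- s                        # whole left side clipped
    lvars <- NULL
  }
  rvars <- cr$vars
  tail_clip <- cr$clip
  comb_end <- cr$win_end
  if (is.null(cr$alt) && rl - e > 0L) tail_clip <- rl - e
  # combined variant set in combined-window coordinates
  vcols <- c("chrom", "pos", "vtype", "ref_allele", "alt_allele", "len", "id")
  vs <- list()
  if (!is.null(lvars) && nrow(lvars) > 0L) {
    lvars$pos <- cl$win_start + lvars$rel
    vs[[1]] <- lvars[, vcols, drop = FALSE]
  }
  if (!is.null(rvars) && nrow(rvars) > 0L) {
    rvars$pos <- cr$win_start + rvars$rel
    vs[[length(vs) + 1L]] <- rvars[, vcols, drop = FALSE]
  }
  comb_end <- max(comb_end, comb_start + 1L)
  ch <- .chrom(ref, chrom)
  comb_end <- min(comb_end, length(ch$mask))
  vars <- if (length(vs) == 0L) {
    ev <- empty_variants(); ev$rel <- integer(0); ev
  } else {
    t <- do.call(rbind, vs)
    t$rel <- t$pos - comb_start
    t[order(t$rel), , drop = FALSE]
  }
  lin_c <- realize_linear(ch$mask[(comb_start + 1L):comb_end],
                          substr(ch$seq, comb_start + 1L, comb_end), vars)
  alt <- append_ops(
    if (lead_clip > 0L) data.frame(op = "S", len = lead_clip),
    lalt,
    data.frame(op = "M", len = e - s),
    cr$alt,
    if (tail_clip > 0L) data.frame(op = "S", len = tail_clip))
  # terminal insertions become soft clips at the free ends
  if (nrow(alt) > 0L && alt$op[nrow(alt)] == "I") alt$op[nrow(alt)] <- "S"
  if (nrow(alt) > 0L && alt$op[1] == "I") alt$op[1] <- "S"
  alt <- append_ops(alt)
  res <- compose_ref_cigar(cigar_string(alt), list(segs = lin_c$segs),
                           list(start = comb_start))
  nv <- if (is.null(lvars)) 0L else nrow(lvars)
  nv <- nv + if (is.null(rvars)) 0L else nrow(rvars)
  list(chrom = chrom, pos = res$pos, cigar = res$cigar,
       n_vars = as.integer(nv),
       clipped = grepl("S", res$cigar, fixed = TRUE))
}
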