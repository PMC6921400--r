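# The batch mapping engine: vectorized candidate generation for all reads at
# once, then a per-pair slow path (VARA extension / mate rescue) for the
# remainder.

read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines) %/% 4L
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  names(seqs) <- sub("\\s.*$", "", sub("^@", "", lines[seq(1L, by = 4L,
                                                           length.out = n)]))
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  list(seq = seqs, qual = quals)
}

cigar_ref_span <- function(cigar) {
  if (grepl("^[0-9]+M$", cigar))                 # fast path: all-M
    return(as.integer(sub("M", "", cigar, fixed = TRUE)))
  tab <- parse_cigar(cigar)
  sum(tab$len[tab$op %in% c("M", "D")])
}

# Vectorized candidate generation: sampled k-mer lookup on both strands,
# diagonal voting, then SNP-tolerant mismatch counting per candidate.
batch_candidates <- function(seqs, index, cfg) {
  rl_v <- nchar(seqs)
  stopifnot(length(unique(rl_v)) == 1L)   # simulator emits uniform lengths
  rl <- rl_v[1]
  k <- index$k
  starts0 <- c(0L, cumsum(rl_v))[seq_along(seqs)]
  offs <- unique(c(seq(0L, rl - k, by = cfg$stride), rl - k))
  empty <- data.table::data.table(read_i = integer(0), strand = character(0),
                                  gdiag = integer(0), votes = integer(0),
                                  nmis = integer(0))
  res <- list()
  bits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") unname(seqs) else revcomp(unname(seqs))
    big <- paste(s, collapse = "")
    bits[[strand]] <- base_bits(big)
    codes <- kmer_pack(base_digits(big), k)
    gidx <- rep(starts0, each = length(offs)) + offs
    q <- data.table::data.table(code = codes[gidx + 1L],
                                read_i = rep(seq_along(s),
                                             each = length(offs)),
                                roff = rep(offs, times = length(s)))
    q <- q[!is.na(q$code)]
    if (nrow(q) == 0L) next
    m <- index$dt[q, on = "code", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(m) == 0L) next
    m[, `:=`(gdiag = as.integer(gpos - roff))]
    cand <- m[, list(votes = .N), by = c("read_i", "gdiag")]
    cand[, `:=`(strand = strand)]
    res[[strand]] <- cand
  }
  cand <- data.table::rbindlist(res)
  if (nrow(cand) == 0L) return(empty)
  boundaries <- c(unname(index$offsets), index$total_len)
  ci <- findInterval(cand$gdiag, boundaries)
  ok <- cand$gdiag >= 0L & ci >= 1L & ci <= length(index$chroms) &
    (cand$gdiag + rl) <= boundaries[ci + 1L]
  cand <- cand[ok]
  if (nrow(cand) == 0L) return(empty)
  data.table::setorderv(cand, c("read_i", "votes"), c(1L, -1L))
  cand <- cand[cand[, list(rk = seq_len(.N)), by = "read_i"]$rk <= cfg$max_cand]
  # mismatch counting in chunks
  nmis <- integer(nrow(cand))
  for (strand in c("+", "-")) {
    rows <- which(cand$strand == strand)
    if (length(rows) == 0L) next
    step <- max(1L, 2000000L %/% rl)
    for (i0 in seq(1L, length(rows), by = step)) {
      rr <- rows[i0:min(i0 + step - 1L, length(rows))]
      ridx <- rep(starts0[cand$read_i[rr]], each = rl) + seq_len(rl)
      gidx <- rep(cand$gdiag[rr], each = rl) + seq_len(rl)
      v <- bitwAnd(bits[[strand]][ridx], index$cmask[gidx]) == 0L
      nmis[rr] <- as.integer(colSums(matrix(v, nrow = rl)))
    }
  }
  cand[, `:=`(nmis = nmis)]
  cand
}

# SAM flag helpers -----------------------------------------------------------

pair_flags <- function(first, mapped, mate_mapped, strand, mate_strand,
                       proper) {
  f <- 1L + (if (first) 64L else 128L)
  if (proper) f <- f + 2L
  if (!mapped) f <- f + 4L
  if (!mate_mapped) f <- f + 8L
  if (mapped && strand == "-") f <- f + 16L
  if (mate_mapped && mate_strand == "-") f <- f + 32L
  f
}

blank_record <- function(qname, first, seq, qual) {
  list(qname = qname, flag = pair_flags(first, FALSE, FALSE, "+", "+", FALSE),
       rname = "*", pos = 0L, mapq = 0L, cigar = "*", rnext = "*",
       pnext = 0L, tlen = 0L, seq = seq, qual = qual, nm = 0L)
}

one_record <- function(qname, first, cand, mate, mapq, proper, seq, qual) {
  # cand/mate: list(chrom, pos (0-based), strand, cigar) or NULL
  if (is.null(cand)) {
    r <- blank_record(qname, first, seq, qual)
    if (!is.null(mate)) {
      r$flag <- pair_flags(first, FALSE, TRUE, "+", mate$strand, FALSE)
      r$rname <- mate$chrom; r$pos <- mate$pos + 1L
      r$rnext <- "="; r$pnext <- mate$pos + 1L
    }
    return(r)
  }
  sq <- if (cand$strand == "-") revcomp(seq) else seq
  ql <- if (cand$strand == "-") str_rev(qual) else qual
  mate_mapped <- !is.null(mate)
  tlen <- 0L
  rnext <- "*"; pnext <- 0L
  if (mate_mapped && mate$chrom == cand$chrom) {
    rnext <- "="; pnext <- mate$pos + 1L
    s1 <- cand$pos; e1 <- cand$pos + cigar_ref_span(cand$cigar)
    s2 <- mate$pos; e2 <- mate$pos + cigar_ref_span(mate$cigar)
    span <- max(e1, e2) - min(s1, s2)
    tlen <- if (s1 < s2 || (s1 == s2 && first)) span else -span
  } else if (mate_mapped) {
    rnext <- mate$chrom; pnext <- mate$pos + 1L
  }
  list(qname = qname,
       flag = pair_flags(first, TRUE, mate_mapped, cand$strand,
                         if (mate_mapped) mate$strand else "+", proper),
       rname = cand$chrom, pos = cand$pos + 1L, mapq = as.integer(mapq),
       cigar = cand$cigar, rnext = rnext, pnext = pnext,
       tlen = as.integer(tlen), seq = sq, qual = ql, nm = cand$e %||% 0L)
}

#' Select the optimal pair among candidate alignments of both ends
#'
#' The best pair minimizes the summed edit distance subject to proper
#' orientation (opposite strands, forward end leftmost) and an insert size
#' within `mean +/- w*sd` (+ slack). Mapping quality is derived from the gap
#' between best and second-best pair scores (`40*(e2-e1)/max(1,e2)`, capped;
#' 0 on ties). Falls back to independent per-end selection when no proper
#' combination exists, and to mate-unmapped / both-unmapped records.
#'
#' @param cand1,cand2 Tibbles of per-end candidates (`chrom`, `pos` 0-based,
#'   `strand`, `e`, `cigar`), possibly empty/NULL.
#' @param insert_model List with `mean`, `sd`, `w`, `slack`.
#' @param qname Read name.
#' @param seq1,seq2,qual1,qual2 Read sequences and qualities (as in FASTQ,
#'   original orientation).
#' @param mapq_cap Maximum mapping quality.
#' @return List of two SAM record lists.
#' @export
select_optimal <- function(cand1, cand2, insert_model, qname,
                           seq1, seq2, qual1, qual2, mapq_cap = 60L) {
  n1 <- if (is.null(cand1)) 0L else nrow(cand1)
  n2 <- if (is.null(cand2)) 0L else nrow(cand2)
  if (n1 == 0L && n2 == 0L)
    return(list(blank_record(qname, TRUE, seq1, qual1),
                blank_record(qname, FALSE, seq2, qual2)))
  mk <- function(tab, i) if (is.null(tab) || i > nrow(tab)) NULL else
    list(chrom = tab$chrom[i], pos = tab$pos[i], strand = tab$strand[i],
         cigar = tab$cigar[i], e = tab$e[i])
  gap_mapq <- function(e1, e2) {
    if (is.na(e2)) return(mapq_cap)
    if (e2 <= e1) return(0L)
    min(mapq_cap, as.integer(round(40 * (e2 - e1) / max(1, e2))))
  }
  if (n1 > 0L && n2 > 0L) {
    combos <- expand.grid(i = seq_len(n1), j = seq_len(n2))
    sc <- rep(NA_real_, nrow(combos))
    for (r in seq_len(nrow(combos))) {
      a <- combos$i[r]; b <- combos$j[r]
      if (cand1$chrom[a] != cand2$chrom[b]) next
      if (cand1$strand[a] == cand2$strand[b]) next
      fwd <- if (cand1$strand[a] == "+") a else b
      if (cand1$strand[a] == "+") {
        fs <- cand1$pos[a]; re <- cand2$pos[b] + cigar_ref_span(cand2$cigar[b])
      } else {
        fs <- cand2$pos[b]; re <- cand1$pos[a] + cigar_ref_span(cand1$cigar[a])
      }
      ins <- re - fs
      if (ins < 0) next
      if (abs(ins - insert_model$mean) >
          insert_model$w * insert_model$sd + (insert_model$slack %||% 50)) next
      sc[r] <- cand1$e[a] + cand2$e[b]
    }
    if (any(!is.na(sc))) {
      o <- order(sc, na.last = TRUE)
      best <- o[1]
      e1 <- sc[best]
      e2 <- if (sum(!is.na(sc)) > 1L) sc[o[2]] else NA_real_
      mq <- gap_mapq(e1, e2)
      c1 <- mk(cand1, combos$i[best]); c2 <- mk(cand2, combos$j[best])
      return(list(
        one_record(qname, TRUE, c1, c2, mq, TRUE, seq1, qual1),
        one_record(qname, FALSE, c2, c1, mq, TRUE, seq2, qual2)))
    }
  }
  # no proper combination: best per end independently
  pick <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0L) return(list(NULL, 0L))
    o <- order(tab$e)
    mq <- gap_mapq(tab$e[o[1]],
                   if (nrow(tab) > 1L) tab$e[o[2]] else NA_real_)
    list(mk(tab, o[1]), mq)
  }
  p1 <- pick(cand1); p2 <- pick(cand2)
  list(one_record(qname, TRUE, p1[[1]], p2[[1]], p1[[2]], FALSE, seq1, qual1),
       one_record(qname, FALSE, p2[[1]], p1[[1]], p2[[2]], FALSE, seq2, qual2))
}

# Diagonal scan of an anchor window for an unseeded mate (vectorized over
# offsets via the DP-free mismatch count per diagonal).
rescue_scan <- function(read, window, ref, alt_index, cfg) {
  rl <- nchar(read)
  s <- if (window$strand == "-") revcomp(read) else read
  rb <- base_bits(s)
  ch <- .chrom(ref, window$chrom)
  lo <- max(0L, window$start); hi <- min(length(ch$mask), window$end)
  if (hi - lo < rl) return(NULL)
  offsets <- lo:(hi - rl)
  nm <- vapply(offsets, function(o)
    sum(bitwAnd(rb, ch$mask[(o + 1L):(o + rl)]) == 0L), integer(1))
  best <- which.min(nm)
  e_max <- emax_for(cfg, rl)
  if (nm[best] <= e_max) {
    return(tibble::tibble(chrom = window$chrom, pos = offsets[best],
                          strand = window$strand, e = as.integer(nm[best]),
                          cigar = paste0(rl, "M")))
  }
  va <- extend_with_vara(list(chrom = window$chrom, pos = offsets[best],
                              read_off = 0L), s, ref, alt_index, cfg)
  if (length(va) == 0L) return(NULL)
  tibble::tibble(chrom = va[[1]]$chrom, pos = va[[1]]$pos,
                 strand = window$strand, e = va[[1]]$e, cigar = va[[1]]$cigar)
}

#' Map paired-end reads and emit SAM
#'
#' The full pipeline: batch k-mer seeding and SNP-tolerant diagonal
#' extension for both ends of every pair, proper-pair selection by summed
#' edit distance under the insert model, then a per-pair slow path — VARA
#' variation-aware extension for ends plain extension cannot explain and
#' insert-distance mate anchoring for unseeded ends — and SAM emission with
#' restored reference CIGARs.
#'
#' @param vindex List with `ref`, `alt_index` and optionally `seed_index`
#'   (built on demand), e.g. from [integrate_variants()] or [load_index()].
#' @param fq1,fq2 FASTQ paths or named character vectors of read sequences.
#' @param out_sam Optional output SAM path.
#' @param cfg A [map_config()].
#' @return Tibble of SAM records (invisibly written to `out_sam` if given)
#'   with attribute `"stats"` (per-stage counters).
#' @export
map_reads <- function(vindex, fq1, fq2, out_sam = NULL, cfg = map_config()) {
  ref <- vindex$ref; alt_index <- vindex$alt_index
  index <- vindex$seed_index %||%
    build_seed_index(ref, cfg$k, cfg$repeat_cap)
  if (is.character(fq1) && length(fq1) == 1L && file.exists(fq1)) {
    r1 <- read_fastq(fq1); r2 <- read_fastq(fq2)
    seqs1 <- r1$seq; quals1 <- r1$qual
    seqs2 <- r2$seq; quals2 <- r2$qual
  } else {
    seqs1 <- fq1; seqs2 <- fq2
    quals1 <- strrep("I", nchar(seqs1)); quals2 <- strrep("I", nchar(seqs2))
  }
  stopifnot(length(seqs1) == length(seqs2))
  n <- length(seqs1)
  qnames <- names(seqs1) %||% sprintf("rd%06d", seq_len(n))
  rl1 <- nchar(seqs1[1]); rl2 <- nchar(seqs2[1])
  e_max1 <- emax_for(cfg, rl1); e_max2 <- emax_for(cfg, rl2)
  imodel <- list(mean = cfg$insert_mean, sd = cfg$insert_sd, w = cfg$w,
                 slack = cfg$insert_slack)
  stats <- c(pairs = n, plain_pairs = 0L, vara_ends = 0L, rescued_ends = 0L,
             unmapped_ends = 0L, softclip_records = 0L)

  cand1 <- batch_candidates(seqs1, index, cfg)
  cand2 <- batch_candidates(seqs2, index, cfg)
  boundaries <- c(unname(index$offsets), index$total_len)
  loc <- function(cand) {
    ci <- findInterval(cand$gdiag, boundaries)
    cand$chrom <- index$chroms[ci]
    cand$pos <- as.integer(cand$gdiag - index$offsets[ci])
    cand
  }
  cand1 <- loc(cand1); cand2 <- loc(cand2)

  # fast path: both ends have a full-length diagonal within budget and a
  # proper pairing exists
  v1 <- cand1[cand1$nmis <= e_max1]
  v2 <- cand2[cand2$nmis <= e_max2]
  data.table::setorderv(v1, c("read_i", "nmis"))
  data.table::setorderv(v2, c("read_i", "nmis"))
  v1 <- v1[v1[, list(rk = seq_len(.N)), by = "read_i"]$rk <= 4L]
  v2 <- v2[v2[, list(rk = seq_len(.N)), by = "read_i"]$rk <= 4L]
  P <- merge(v1, v2, by = "read_i", allow.cartesian = TRUE,
             suffixes = c("1", "2"))
  if (nrow(P) > 0L) {
    P <- P[P$chrom1 == P$chrom2 & P$strand1 != P$strand2]
  }
  emitted <- rep(FALSE, n)
  records <- vector("list", 2L * n)
  if (nrow(P) > 0L) {
    fwd1 <- P$strand1 == "+"
    fs <- ifelse(fwd1, P$pos1, P$pos2)
    re <- ifelse(fwd1, P$pos2 + rl2, P$pos1 + rl1)
    ins <- re - fs
    P <- P[ins >= 0 & abs(ins - cfg$insert_mean) <=
             cfg$w * cfg$insert_sd + cfg$insert_slack]
  }
  if (nrow(P) > 0L) {
    P$score <- P$nmis1 + P$nmis2
    data.table::setorderv(P, c("read_i", "score"))
    firsts <- !duplicated(P$read_i)
    bestP <- P[firsts]
    seconds <- P[!firsts]
    sec <- seconds[!duplicated(seconds$read_i)]
    second_score <- sec$score[match(bestP$read_i, sec$read_i)]
    mapq <- ifelse(is.na(second_score), cfg$mapq_cap,
                   ifelse(second_score <= bestP$score, 0L,
                          pmin(cfg$mapq_cap,
                               as.integer(round(40 * (second_score - bestP$score) /
                                                  pmax(1, second_score))))))
    for (r in seq_len(nrow(bestP))) {
      i <- bestP$read_i[r]
      c1 <- list(chrom = bestP$chrom1[r], pos = bestP$pos1[r],
                 strand = bestP$strand1[r], cigar = paste0(rl1, "M"),
                 e = bestP$nmis1[r])
      c2 <- list(chrom = bestP$chrom2[r], pos = bestP$pos2[r],
                 strand = bestP$strand2[r], cigar = paste0(rl2, "M"),
                 e = bestP$nmis2[r])
      records[[2L * i - 1L]] <- one_record(qnames[i], TRUE, c1, c2, mapq[r],
                                           TRUE, seqs1[i], quals1[i])
      records[[2L * i]] <- one_record(qnames[i], FALSE, c2, c1, mapq[r],
                                      TRUE, seqs2[i], quals2[i])
      emitted[i] <- TRUE
    }
    stats["plain_pairs"] <- sum(emitted)
  }

  # slow path
  slow <- which(!emitted)
  vara_cache <- list(ref = ref, alt = alt_index)
  end_cands <- function(i, end) {
    cand <- if (end == 1L) cand1 else cand2
    seqs <- if (end == 1L) seqs1 else seqs2
    e_max <- if (end == 1L) e_max1 else e_max2
    rl <- if (end == 1L) rl1 else rl2
    rows <- cand[cand$read_i == i]
    out <- NULL
    if (nrow(rows) > 0L) {
      viable <- rows[rows$nmis <= e_max]
      if (nrow(viable) > 0L) {
        data.table::setorderv(viable, "nmis")
        out <- tibble::tibble(chrom = viable$chrom, pos = viable$pos,
                              strand = viable$strand,
                              e = as.integer(viable$nmis),
                              cigar = paste0(rl, "M"))
      } else {
        data.table::setorderv(rows, "nmis")
        stats["vara_ends"] <<- stats["vara_ends"] + 1L
        for (r in seq_len(min(2L, nrow(rows)))) {
          rd <- if (rows$strand[r] == "-") revcomp(seqs[i]) else seqs[i]
          va <- extend_with_vara(
            list(chrom = rows$chrom[r], pos = rows$pos[r], read_off = 0L),
            rd, ref, alt_index, cfg)
          if (length(va) > 0L) {
            add <- tibble::tibble(
              chrom = vapply(va, `[[`, character(1), "chrom"),
              pos = vapply(va, function(x) as.integer(x$pos), integer(1)),
              strand = rows$strand[r],
              e = vapply(va, function(x) as.integer(x$e), integer(1)),
              cigar = vapply(va, `[[`, character(1), "cigar"))
            out <- if (is.null(out)) add else rbind(out, add)
          }
        }
        if (!is.null(out)) out <- out[order(out$e), , drop = FALSE][
          seq_len(min(4L, nrow(out))), , drop = FALSE]
      }
    }
    out
  }
  for (i in slow) {
    c1 <- end_cands(i, 1L)
    c2 <- end_cands(i, 2L)
    # mate rescue for a seedless end
    if (is.null(c1) && !is.null(c2)) {
      wins <- anchor_mate(tibble::tibble(chrom = c2$chrom[1], pos = c2$pos[1],
                                         strand = c2$strand[1]),
                          imodel, rl1, ref$lengths)
      if (nrow(wins) > 0L) {
        c1 <- rescue_scan(seqs1[i], as.list(wins[1, ]), ref, alt_index, cfg)
        if (!is.null(c1)) stats["rescued_ends"] <- stats["rescued_ends"] + 1L
      }
    } else if (is.null(c2) && !is.null(c1)) {
      wins <- anchor_mate(tibble::tibble(chrom = c1$chrom[1], pos = c1$pos[1],
                                         strand = c1$strand[1]),
                          imodel, rl2, ref$lengths)
      if (nrow(wins) > 0L) {
        c2 <- rescue_scan(seqs2[i], as.list(wins[1, ]), ref, alt_index, cfg)
        if (!is.null(c2)) stats["rescued_ends"] <- stats["rescued_ends"] + 1L
      }
    }
    rec <- select_optimal(c1, c2, imodel, qnames[i], seqs1[i], seqs2[i],
                          quals1[i], quals2[i], cfg$mapq_cap)
    records[[2L * i - 1L]] <- rec[[1]]
    records[[2L * i]] <- rec[[2]]
  }

  tab <- data.table::rbindlist(records)
  out <- tibble::as_tibble(tab)
  stats["unmapped_ends"] <- sum(bitwAnd(out$flag, 4L) > 0L)
  stats["softclip_records"] <- sum(grepl("S", out$cigar, fixed = TRUE))
  attr(out, "stats") <- stats
  if (!is.null(out_sam)) write_sam(out, out_sam, ref)
  out
}
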