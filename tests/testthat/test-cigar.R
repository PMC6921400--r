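# Reference-coordinate CIGAR restoration.

# --- base-correspondence oracle -------------------------------------------
# Expands the composition to per-base (read, ref) entries and applies the
# same leftmost insertion/deletion pairing the restoration rules describe,
# independently of the run-length op algebra used in production.

oracle_entries <- function(alt_tab, vars, W, win_start) {
  # haplotype base -> ref position (NA for inserted bases), plus deleted ref
  # positions attached before each hap index
  href <- integer(0); gap_before <- list()
  t <- 0L; ref <- win_start
  push_gap <- function(refs) {
    k <- length(href) + 1L
    gap_before[[k]] <<- c(if (k <= length(gap_before)) gap_before[[k]], refs)
  }
  if (nrow(vars) > 0L) {
    for (i in seq_len(nrow(vars))) {
      v <- vars[i, ]
      n <- v$rel - t
      if (n > 0L) { href <- c(href, ref + seq_len(n) - 1L); ref <- ref + n; t <- v$rel }
      if (v$vtype == "INS") href <- c(href, rep(NA_integer_, v$len))
      else { push_gap(ref + seq_len(v$len) - 1L); ref <- ref + v$len; t <- t + v$len
             if (t >= W) { t <- W; break } }
    }
  }
  if (W - t > 0L) href <- c(href, ref + seq_len(W - t) - 1L)
  gaps_at <- function(h) if (h + 1L <= length(gap_before)) gap_before[[h + 1L]] else NULL
  ent <- list(); r <- 0L; h <- 0L
  emit <- function(r, j, s = FALSE) ent[[length(ent) + 1L]] <<- list(r = r, j = j, s = s)
  flushed <- logical(length(href) + 1L)
  flush_gap <- function() {
    if (!flushed[h + 1L]) {
      for (j in gaps_at(h)) emit(NA_integer_, j)
      flushed[h + 1L] <<- TRUE
    }
  }
  for (i in seq_len(nrow(alt_tab))) {
    op <- alt_tab$op[i]
    for (k in seq_len(alt_tab$len[i])) {
      if (op == "S") emit(r <- r + 1L, NA_integer_, s = TRUE)
      else if (op == "I") emit(r <- r + 1L, NA_integer_)
      else if (op == "M") { flush_gap(); h <- h + 1L; emit(r <- r + 1L, href[h]) }
      else { flush_gap(); h <- h + 1L; if (!is.na(href[h])) emit(NA_integer_, href[h]) }
    }
  }
  # greedy leftmost pairing of adjacent read-only / ref-only runs, blocked by
  # aligned pairs and soft clips
  out <- list(); pr <- list(); pj <- list()
  flush_pending <- function() {
    np <- min(length(pr), length(pj))
    for (k in seq_len(np)) out[[length(out) + 1L]] <<- list(r = pr[[k]]$r, j = pj[[k]]$j, s = FALSE)
    for (k in seq_len(length(pr) - np) + np) out[[length(out) + 1L]] <<- pr[[k]]
    for (k in seq_len(length(pj) - np) + np) out[[length(out) + 1L]] <<- pj[[k]]
    pr <<- list(); pj <<- list()
  }
  for (e in ent) {
    if (!is.na(e$r) && (e$s || !is.na(e$j))) { flush_pending(); out[[length(out) + 1L]] <- e }
    else if (!is.na(e$r)) pr[[length(pr) + 1L]] <- e
    else pj[[length(pj) + 1L]] <- e
  }
  flush_pending()
  # leading / trailing unaligned reference positions move into the position
  while (length(out) > 0L && is.na(out[[1]]$r)) out <- out[-1]
  while (length(out) > 0L && is.na(out[[length(out)]]$r)) out <- out[-length(out)]
  out
}

replay_entries <- function(pos, cigar) {
  tab <- varatree:::parse_cigar(cigar)
  out <- list(); r <- 0L; j <- pos
  for (i in seq_len(nrow(tab))) {
    op <- tab$op[i]
    for (k in seq_len(tab$len[i])) {
      if (op == "M") { out[[length(out) + 1L]] <- list(r = r <- r + 1L, j = j, s = FALSE); j <- j + 1L }
      else if (op == "I") out[[length(out) + 1L]] <- list(r = r <- r + 1L, j = NA_integer_, s = FALSE)
      else if (op == "D") { out[[length(out) + 1L]] <- list(r = NA_integer_, j = j, s = FALSE); j <- j + 1L }
      else out[[length(out) + 1L]] <- list(r = r <- r + 1L, j = NA_integer_, s = TRUE)
    }
  }
  out
}

entdf <- function(x) data.frame(r = vapply(x, `[[`, integer(1), "r"),
                                j = vapply(x, `[[`, integer(1), "j"),
                                s = vapply(x, `[[`, logical(1), "s"))

test_that("identity composition passes through unchanged", {
  p <- list(segs = data.frame(op = "M", len = 20L))
  res <- compose_ref_cigar("20M", p, list(start = 500L))
  expect_equal(res$pos, 500L)
  expect_equal(res$cigar, "20M")
})

test_that("the four restoration rule cases compose as specified", {
  # 1: 1bp ALT deletion inside a 1bp insertion variant -> plain M
  p1 <- list(segs = data.frame(op = c("M", "VI", "M"), len = c(10L, 1L, 10L)))
  expect_equal(compose_ref_cigar("10M1D10M", p1, list(start = 0L))$cigar, "20M")
  # 2: 1bp ALT insertion at a 1bp deletion junction -> match-or-mismatch M
  p2 <- list(segs = data.frame(op = c("M", "VD", "M"), len = c(10L, 1L, 10L)))
  expect_equal(compose_ref_cigar("10M1I10M", p2, list(start = 0L))$cigar, "21M")
  # 3: ALT deletion inside a longer insertion variant -> reference insertion
  p3 <- list(segs = data.frame(op = c("M", "VI", "M"), len = c(10L, 5L, 10L)))
  expect_equal(compose_ref_cigar("10M3D12M", p3, list(start = 0L))$cigar,
               "10M2I10M")
  # 4: ALT insertion at a longer deletion junction -> shorter deletion + M
  p4 <- list(segs = data.frame(op = c("M", "VD", "M"), len = c(10L, 5L, 10L)))
  expect_equal(compose_ref_cigar("10M2I10M", p4, list(start = 0L))$cigar,
               "12M3D10M")
})

test_that("length mismatches raise named errors", {
  p <- list(segs = data.frame(op = "M", len = 10L))
  expect_error(compose_ref_cigar("12M", p, list(start = 0L)),
               class = "varatree_error_bad_cigar")
})

test_that("validate_cigar checks both consumption identities", {
  expect_true(validate_cigar("20M", 20L, 20L))
  expect_true(validate_cigar("10M2I10M", 22L, 20L))
  expect_false(validate_cigar("10M1D", 11L, 11L))
  expect_false(validate_cigar("10M10M", 20L, 20L))   # non-canonical runs
  expect_false(validate_cigar("5M3H", 5L, 5L))       # op outside M/I/D/S
  expect_true(validate_cigar("3S17M", 20L, 17L))
})

test_that("random compositions reproduce the base correspondence", {
  set.seed(61)
  for (it in 1:500) {
    W <- sample(40:120, 1)
    start <- sample(0:5000, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), W, replace = TRUE),
                 collapse = "")
    nv <- sample(0:3, 1)
    vars <- empty_variants(); vars$rel <- integer(0)
    if (nv > 0) {
      pos <- sort(sample(seq(5L, W - 12L), nv))
      pos <- pos[c(TRUE, diff(pos) >= 12L)]
      nv <- length(pos)
      vt <- sample(c("INS", "DEL"), nv, replace = TRUE)
      len <- sample(1:6, nv, replace = TRUE)
      vars <- vrec(pos, vt, ifelse(vt == "DEL",
                                   substring(seq, pos + 1L, pos + len), ""),
                   ifelse(vt == "INS", strrep("G", len), ""))
      vars$rel <- vars$pos
    }
    lin <- varatree:::realize_linear(
      ifelse(varatree:::base_bits(seq) == 0L, 15L,
             varatree:::base_bits(seq)), seq, vars)
    hap_len <- nchar(lin$hap)
    # random ALT alignment over the haplotype
    ops <- character(0); lens <- integer(0); hap_left <- hap_len
    if (runif(1) < 0.2) { ops <- "S"; lens <- sample(1:5, 1) }
    repeat {
      op <- sample(c("M", "I", "D"), 1, prob = c(0.7, 0.15, 0.15))
      n <- if (op == "M") sample(1:20, 1) else sample(1:3, 1)
      if (op != "I") n <- min(n, hap_left)
      if (n > 0L && (length(ops) == 0L || ops[length(ops)] != op)) {
        ops <- c(ops, op); lens <- c(lens, n)
        if (op != "I") hap_left <- hap_left - n
      }
      if (hap_left == 0L || (length(ops) > 3L && runif(1) < 0.25)) break
    }
    if (ops[length(ops)] == "D") { ops <- ops[-length(ops)]; lens <- lens[-length(lens)] }
    if (length(ops) == 0L || all(ops %in% c("S", "D"))) next
    if (runif(1) < 0.2 && ops[length(ops)] != "S") {
      ops <- c(ops, "S"); lens <- c(lens, sample(1:5, 1))
    }
    alt_tab <- data.frame(op = ops, len = lens)
    alt <- varatree:::cigar_string(alt_tab)
    res <- compose_ref_cigar(alt, list(segs = lin$segs), list(start = start))
    got <- entdf(replay_entries(res$pos, res$cigar))
    want <- entdf(oracle_entries(alt_tab, vars, W, start))
    expect_equal(got, want)
    # arithmetic identities always hold
    read_len <- sum(lens[ops %in% c("M", "I", "S")])
    expect_true(validate_cigar(res$cigar, read_len,
                               sum(got$j >= 0, na.rm = TRUE)))
  }
})
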