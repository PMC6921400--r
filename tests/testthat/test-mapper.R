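# Seed index, seeding, VARA invocation policy, mate anchoring, pair
# selection, SAM emission.

test_that("the seed index retrieves k-mer positions and honors the repeat cap", {
  ref <- load_reference(c(c = "ACGTACGTACGTACGT"))
  idx <- build_seed_index(ref, k = 8L)
  expect_equal(seed_lookup(idx, "ACGTACGT"), c(0L, 4L, 8L))
  expect_equal(seed_lookup(idx, "TTTTTTTT"), integer(0))
  idx2 <- build_seed_index(ref, k = 8L, repeat_cap = 2L)
  expect_equal(seed_lookup(idx2, "ACGTACGT"), integer(0))  # flagged
  expect_error(build_seed_index(ref, k = 4L))
})

test_that("collect_seeds hits both strands and skips N-containing k-mers", {
  set.seed(81)
  g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  ref <- load_reference(c(chr = g))
  idx <- build_seed_index(ref)
  read <- substr(g, 501, 600)
  hits <- collect_seeds(read, idx)
  expect_true(any(hits$strand == "+" & hits$diag == 500L))
  rc_hits <- collect_seeds(revcomp(read), idx)
  expect_true(any(rc_hits$strand == "-" & rc_hits$diag == 500L))
  expect_equal(nrow(collect_seeds(strrep("N", 100L), idx)), 0L)
  expect_error(collect_seeds("ACGT", idx),
               class = "varatree_error_short_read")
  # a central mismatch still leaves flanking seeds
  rd2 <- read; substr(rd2, 50, 50) <- chartr("ACGT", "CATG", substr(rd2, 50, 50))
  expect_true(any(collect_seeds(rd2, idx)$diag == 500L))
})

test_that("needs_vara triggers on unexplained ends only", {
  expect_false(needs_vara(0L, 6L))           # perfect end
  expect_false(needs_vara(1L, 6L))           # one mismatch within budget
  expect_true(needs_vara(30L, 6L))           # INDEL-shifted tail
  expect_true(needs_vara(NA_integer_, 6L))   # no seeds at all
  expect_true(needs_vara(4L, 6L, g = 2L))    # stricter budget
})

test_that("extend_with_vara recovers planted INDELs at zero cost", {
  set.seed(82)
  g <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
             collapse = "")
  ref <- load_reference(c(chr = g))
  # 3bp deletion at 2000, 7bp insertion at 2600
  vars <- vrec(c(2000L, 2600L), c("DEL", "INS"),
               c(substr(g, 2001L, 2003L), ""), c("", "TTACCGA"),
               chrom = "chr")
  iv <- integrate_variants(ref, vars)
  # read spanning the deletion: 40 bases left, 60 right
  rd_del <- paste0(substr(g, 1961L, 2000L), substr(g, 2004L, 2063L))
  cand <- extend_with_vara(list(chrom = "chr", pos = 1960L, read_off = 0L),
                           rd_del, iv$ref, iv$alt_index, map_config())
  expect_equal(cand[[1]]$e, 0L)
  expect_equal(cand[[1]]$pos, 1960L)
  expect_equal(cand[[1]]$cigar, "40M3D60M")
  # read spanning the insertion
  rd_ins <- paste0(substr(g, 2551L, 2600L), "TTACCGA",
                   substr(g, 2601L, 2643L))
  cand2 <- extend_with_vara(list(chrom = "chr", pos = 2550L, read_off = 0L),
                            rd_ins, iv$ref, iv$alt_index, map_config())
  expect_equal(cand2[[1]]$e, 0L)
  expect_equal(cand2[[1]]$pos, 2550L)
  expect_equal(cand2[[1]]$cigar, "50M7I43M")
  # seed covering the whole read: single candidate at e = 0
  rd_exact <- substr(g, 1001L, 1100L)
  cand3 <- extend_with_vara(list(chrom = "chr", pos = 1000L, read_off = 0L),
                            rd_exact, iv$ref, iv$alt_index, map_config())
  expect_equal(cand3[[1]]$e, 0L)
  expect_equal(cand3[[1]]$cigar, "100M")
  # seed at the chromosome start: left window truncates but alignment holds
  rd_edge <- substr(g, 1L, 100L)
  cand4 <- extend_with_vara(list(chrom = "chr", pos = 20L, read_off = 20L),
                            rd_edge, iv$ref, iv$alt_index, map_config())
  expect_equal(cand4[[1]]$pos, 0L)
  expect_equal(cand4[[1]]$e, 0L)
})

test_that("anchor_mate windows follow the insert model arithmetic", {
  im <- list(mean = 500, sd = 25, w = 4)
  w <- anchor_mate(tibble::tibble(chrom = "c", pos = 10000L, strand = "+"),
                   im, 100L)
  expect_equal(w$start, 10000L + 500L - 100L - 100L)
  expect_equal(w$end, 10000L + 500L + 100L + 100L)
  expect_equal(w$strand, "-")
  # zero spread: window width is twice the read length
  w0 <- anchor_mate(tibble::tibble(chrom = "c", pos = 10000L, strand = "+"),
                    list(mean = 500, sd = 0, w = 4), 100L)
  expect_equal(w0$end - w0$start, 200L)
  # reverse-strand hit mirrors upstream
  wr <- anchor_mate(tibble::tibble(chrom = "c", pos = 10000L, strand = "-"),
                    im, 100L)
  expect_equal(wr$strand, "+")
  expect_lt(wr$end, 10000L + 100L)
})

test_that("select_optimal emits proper flags, tlen and mapq conventions", {
  im <- list(mean = 500, sd = 25, w = 4, slack = 50)
  c1 <- tibble::tibble(chrom = "c", pos = 1000L, strand = "+", e = 0L,
                       cigar = "100M")
  c2 <- tibble::tibble(chrom = "c", pos = 1400L, strand = "-", e = 0L,
                       cigar = "100M")
  rec <- select_optimal(c1, c2, im, "q1", strrep("A", 100), strrep("C", 100),
                        strrep("I", 100), strrep("I", 100))
  expect_equal(rec[[1]]$flag, 99L)
  expect_equal(rec[[2]]$flag, 147L)
  expect_equal(rec[[1]]$mapq, 60L)
  expect_equal(rec[[1]]$tlen, 500L)
  expect_equal(rec[[2]]$tlen, -500L)
  expect_equal(rec[[2]]$seq, revcomp(strrep("C", 100)))
  # ambiguous: two equal-score pairings give mapq 0
  c1b <- rbind(c1, tibble::tibble(chrom = "c", pos = 5000L, strand = "+",
                                  e = 0L, cigar = "100M"))
  c2b <- rbind(c2, tibble::tibble(chrom = "c", pos = 5400L, strand = "-",
                                  e = 0L, cigar = "100M"))
  rec2 <- select_optimal(c1b, c2b, im, "q2", strrep("A", 100),
                         strrep("C", 100), strrep("I", 100), strrep("I", 100))
  expect_equal(rec2[[1]]$mapq, 0L)
  # one end missing: mate-unmapped convention
  rec3 <- select_optimal(c1, NULL, im, "q3", strrep("A", 100),
                         strrep("C", 100), strrep("I", 100), strrep("I", 100))
  expect_equal(bitwAnd(rec3[[1]]$flag, 8L), 8L)
  expect_equal(bitwAnd(rec3[[2]]$flag, 4L), 4L)
  expect_equal(rec3[[2]]$rname, "c")
  expect_equal(rec3[[2]]$tlen, 0L)
  # both missing
  rec4 <- select_optimal(NULL, NULL, im, "q4", "A", "C", "I", "I")
  expect_equal(rec4[[1]]$flag, 77L)
  expect_equal(rec4[[2]]$flag, 141L)
})

test_that("a small end-to-end run maps every read to its truth position", {
  cfg <- sim_config(genome_len = 20000L, n_pairs = 300L, seed = 83L,
                    snp_rate = 2e-3, ins_rate = 5e-4, del_rate = 5e-4,
                    error_rate = 0)
  g <- simulate_genome(cfg)
  vars <- simulate_variants(g, cfg)
  sim <- simulate_reads(g, vars, cfg)
  iv <- integrate_variants(load_reference(g), vars)
  sam <- map_reads(iv, sim$fq1, sim$fq2)
  m <- evaluate_alignments(sam, sim$truth)
  expect_equal(m$accuracy, 100)
  expect_equal(m$unmapped, 0L)
  expect_equal(m$softclip, 0L)
  # every emitted record passes CIGAR and reference-bounds validation
  mapped <- sam[bitwAnd(sam$flag, 4L) == 0L, ]
  for (i in seq_len(nrow(mapped))) {
    span <- varatree:::cigar_ref_span(mapped$cigar[i])
    expect_true(validate_cigar(mapped$cigar[i], nchar(mapped$seq[i]), span))
    expect_gte(mapped$pos[i], 1L)
    expect_lte(mapped$pos[i] - 1L + span, 20000L)
  }
  # pairs share qname and reciprocal flags
  expect_equal(sum(bitwAnd(sam$flag, 64L) > 0L),
               sum(bitwAnd(sam$flag, 128L) > 0L))
  # SAM round-trip through the writer/reader
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, f, iv$ref)
  back <- read_sam(f)
  expect_equal(back$pos, sam$pos)
  expect_equal(back$cigar, sam$cigar)
  expect_equal(back$nm, sam$nm)
})

test_that("mate rescue places an unseeded end through the insert model", {
  set.seed(84)
  g <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  ref <- load_reference(c(chr = g))
  iv <- integrate_variants(ref, empty_variants())
  win <- tibble::tibble(chrom = "chr", start = 5300L, end = 5800L,
                        strand = "-")
  rd <- revcomp(substr(g, 5501L, 5600L))
  cand <- varatree:::rescue_scan(rd, as.list(win[1, ]), iv$ref,
                                 iv$alt_index, map_config())
  expect_equal(cand$pos, 5500L)
  expect_equal(cand$e, 0L)
})
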