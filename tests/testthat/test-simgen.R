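# Synthetic data generation and evaluation.

test_that("generators are deterministic under the seed", {
  cfg <- sim_config(genome_len = 5000L, n_pairs = 50L, seed = 7L)
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
  g <- simulate_genome(cfg)
  v1 <- simulate_variants(g, cfg); v2 <- simulate_variants(g, cfg)
  expect_identical(v1, v2)
  s1 <- simulate_reads(g, v1, cfg); s2 <- simulate_reads(g, v1, cfg)
  expect_identical(s1$fq1, s2$fq1)
  expect_identical(s1$truth, s2$truth)
  expect_error(simulate_genome(sim_config(genome_len = 0L)))
})

test_that("genome composition is uniform within binomial bounds", {
  cfg <- sim_config(genome_len = 100000L, seed = 9L)
  g <- simulate_genome(cfg)
  gc <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / nchar(g[[1]])
  expect_gt(gc, 0.45); expect_lt(gc, 0.55)
})

test_that("variant planting respects rates, spacing and reference alleles", {
  cfg <- sim_config(genome_len = 100000L, snp_rate = 1e-3, ins_rate = 1e-4,
                    del_rate = 1e-4, seed = 10L)
  g <- simulate_genome(cfg)
  vars <- simulate_variants(g, cfg)
  nsnp <- sum(vars$vtype == "SNP")
  expect_gt(nsnp, 100 - 3 * sqrt(100)); expect_lt(nsnp, 100 + 3 * sqrt(100))
  # REF alleles always match the genome slice
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    span <- if (v$vtype == "INS") 0L else v$len
    if (span > 0L)
      expect_equal(substr(g[[v$chrom]], v$pos + 1L, v$pos + span),
                   v$ref_allele)
  }
  expect_true(all(diff(vars$pos) >= 25L))
  expect_true(all(vars$len <= cfg$indel_max_len))
  # zero rates: no variants
  cfg0 <- sim_config(genome_len = 10000L, snp_rate = 0, ins_rate = 0,
                     del_rate = 0)
  expect_equal(nrow(simulate_variants(simulate_genome(cfg0), cfg0)), 0L)
})

test_that("error-free variant-free reads are exact reference substrings", {
  cfg <- sim_config(genome_len = 20000L, n_pairs = 200L, error_rate = 0,
                    snp_rate = 0, ins_rate = 0, del_rate = 0, seed = 11L)
  g <- simulate_genome(cfg)
  sim <- simulate_reads(g, empty_variants(), cfg)
  for (i in seq_len(50L)) {
    t <- sim$truth[i, ]
    r1 <- if (t$strand1 == "-") revcomp(sim$fq1[[t$read_id]]) else
      sim$fq1[[t$read_id]]
    expect_equal(r1, substr(g[[t$chrom]], t$pos1, t$pos1 + 99L))
  }
})

test_that("variant-spanning reads carry the spanned ids in truth", {
  cfg <- sim_config(genome_len = 30000L, n_pairs = 400L, error_rate = 0,
                    snp_rate = 0, ins_rate = 2e-3, del_rate = 2e-3,
                    seed = 12L)
  g <- simulate_genome(cfg)
  vars <- simulate_variants(g, cfg)
  sim <- simulate_reads(g, vars, cfg)
  spanned <- unique(unlist(strsplit(c(sim$truth$vars1, sim$truth$vars2), ",")))
  spanned <- as.integer(spanned[spanned != ""])
  expect_gt(length(spanned), 0L)
  # a read listing a DEL id must bridge the deletion: its reference span
  # around the truth position contains the deleted interval
  dels <- vars[vars$vtype == "DEL" & vars$id %in% spanned, ]
  if (nrow(dels) > 0L) {
    v <- dels[1, ]
    hit1 <- grepl(paste0("(^|,)", v$id, "($|,)"), sim$truth$vars1)
    hit <- sim$truth[hit1, ][1, ]
    expect_lte(hit$pos1 - 1L, v$pos + v$len)
    expect_gte(hit$pos1 - 1L + 100L + v$len, v$pos)
  }
})

test_that("observed insert sizes match the model within CLT bounds", {
  cfg <- sim_config(genome_len = 50000L, n_pairs = 10000L, error_rate = 0,
                    snp_rate = 0, ins_rate = 0, del_rate = 0, seed = 13L)
  g <- simulate_genome(cfg)
  sim <- simulate_reads(g, empty_variants(), cfg)
  lefts <- pmin(sim$truth$pos1, sim$truth$pos2)
  rights <- pmax(sim$truth$pos1, sim$truth$pos2) + 100L
  expect_lt(abs(mean(rights - lefts) - 500), 3)
  expect_lt(abs(sd(rights - lefts) - 25), 3)
})

test_that("FASTA/FASTQ/VCF/truth files round-trip", {
  cfg <- sim_config(genome_len = 8000L, n_pairs = 30L, seed = 14L,
                    snp_rate = 1e-3, ins_rate = 5e-4, del_rate = 5e-4)
  g <- simulate_genome(cfg)
  vars <- simulate_variants(g, cfg)
  sim <- simulate_reads(g, vars, cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  fq <- withr::local_tempfile(fileext = ".fq")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(g, fa)
  expect_equal(decode_reference(load_reference(fa), "chr1"), g[["chr1"]])
  write_fastq(sim$fq1, fq)
  back <- varatree:::read_fastq(fq)
  expect_equal(back$seq, sim$fq1)
  write_vcf(vars, g, vcf)
  vback <- read_vcf_variants(vcf)
  expect_equal(vback[c("chrom", "pos", "vtype", "ref_allele", "alt_allele")],
               vars[c("chrom", "pos", "vtype", "ref_allele", "alt_allele")])
  write_truth(sim$truth, tsv)
  expect_equal(read_truth(tsv), sim$truth)
})

test_that("the evaluator scores perfect, shifted and unmapped SAMs", {
  cfg <- sim_config(genome_len = 10000L, n_pairs = 40L, seed = 15L,
                    snp_rate = 0, ins_rate = 0, del_rate = 0, error_rate = 0)
  g <- simulate_genome(cfg)
  sim <- simulate_reads(g, empty_variants(), cfg)
  mk <- function(pos_shift, flag_extra = 0L) {
    t <- sim$truth
    rbind(
      tibble::tibble(qname = t$read_id,
                     flag = ifelse(t$strand1 == "-", 83L, 99L) + flag_extra,
                     rname = t$chrom, pos = t$pos1 + pos_shift, mapq = 60L,
                     cigar = "100M", rnext = "=", pnext = t$pos2, tlen = 500L,
                     seq = "*", qual = "*", nm = 0L),
      tibble::tibble(qname = t$read_id,
                     flag = ifelse(t$strand2 == "-", 147L, 163L) + flag_extra,
                     rname = t$chrom, pos = t$pos2 + pos_shift, mapq = 60L,
                     cigar = "100M", rnext = "=", pnext = t$pos1, tlen = -500L,
                     seq = "*", qual = "*", nm = 0L))
  }
  perfect <- evaluate_alignments(mk(0L), sim$truth)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$unmapped, 0L)
  expect_equal(perfect$softclip, 0L)
  # tolerance boundary: shift by tolerance passes, tolerance+1 fails all
  expect_equal(evaluate_alignments(mk(10L), sim$truth)$accuracy, 100)
  expect_equal(evaluate_alignments(mk(11L), sim$truth)$accuracy, 0)
  # all-unmapped SAM
  un <- mk(0L); un$flag <- ifelse(bitwAnd(un$flag, 64L) > 0L, 77L, 141L)
  mu <- evaluate_alignments(un, sim$truth)
  expect_equal(mu$accuracy, 0)
  expect_equal(mu$unmapped, 80L)
  bad <- mk(0L); bad$qname[1] <- "nonexistent"
  expect_error(evaluate_alignments(bad, sim$truth),
               class = "varatree_error_truth_mismatch")
})

test_that("the MHC-like preset concentrates variants in a dense sub-region", {
  cfg <- sim_config(genome_len = 50000L, mhc_like = TRUE, seed = 16L,
                    snp_rate = 1e-3, ins_rate = 1e-4, del_rate = 1e-4)
  g <- simulate_genome(cfg)
  vars <- simulate_variants(g, cfg)
  counts <- table(cut(vars$pos, breaks = seq(0, 50000, by = 5000)))
  expect_gt(max(counts), 3 * stats::median(counts))
})

test_that("random tree instances are well-formed", {
  set.seed(17)
  for (it in 1:20) {
    inst <- random_tree_instance()
    expect_gte(length(inst$tree$paths), 1L)
    expect_gte(nchar(inst$read), 10L)
    expect_lte(inst$n_edits, inst$e_max)
  }
})
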