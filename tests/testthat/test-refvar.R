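# Variation-aware reference: 4-bit encoding, SNP folding, INDEL side index.

test_that("loading encodes bases as single-bit site codes and round-trips", {
  ref <- load_reference(c(c = "ACGT"))
  expect_equal(ref$chroms$c$mask, c(1L, 2L, 4L, 8L))
  expect_equal(decode_reference(ref, "c"), "ACGT")
  # case folding
  ref2 <- load_reference(c(c = "acgt"))
  expect_equal(ref2$chroms$c$mask, c(1L, 2L, 4L, 8L))
  expect_equal(decode_reference(ref2, "c"), "ACGT")
})

test_that("non-ACGT reference bases are permissive codes that still decode", {
  ref <- load_reference(c(c = "ACNGT"))
  expect_equal(ref$chroms$c$mask[3], 15L)
  expect_equal(decode_reference(ref, "c"), "ACNGT")
  # permissive on the reference side, strict on the read side
  expect_true(base_match("A", 15L))
  expect_false(base_match("N", 15L))
})

test_that("malformed FASTA inputs are rejected with named errors", {
  expect_error(load_reference(character(0)), class = "varatree_error_bad_fasta")
  expect_error(load_reference(c(a = "ACGT", a = "ACGT")),
               class = "varatree_error_duplicate_seqnames")
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(load_reference(f), class = "varatree_error_empty_fasta")
})

test_that("SNPs are OR-ed into site codes; INDELs go to the side index", {
  ref <- load_reference(c(c = "ACGT"))
  iv <- integrate_variants(ref, vrec(1L, "SNP", "C", "T", chrom = "c"))
  expect_equal(iv$ref$chroms$c$mask[2], bitwOr(2L, 8L))
  # reference base never changes
  expect_equal(decode_reference(iv$ref, "c"), "ACGT")

  ref8 <- load_reference(c(c = "ACGTACGT"))
  v <- vrec(c(2L, 5L), c("DEL", "INS"), c("GTA", ""), c("", "GG"),
            chrom = "c")
  iv2 <- integrate_variants(ref8, v)
  expect_equal(iv2$ref$chroms$c$mask, base_bits("ACGTACGT"))
  got <- variants_in_window(iv2$alt_index, "c", 0L, 8L)
  expect_equal(got$id, c(1L, 2L))
  # no variants: unchanged reference, empty index
  iv3 <- integrate_variants(ref8, empty_variants())
  expect_equal(iv3$ref$chroms$c$mask, ref8$chroms$c$mask)
  expect_equal(nrow(variants_in_window(iv3$alt_index, "c", 0L, 8L)), 0L)
})

test_that("overlapping SNPs merge and mismatching records are rejected", {
  ref <- load_reference(c(c = "ACGT"))
  v <- vrec(c(1L, 1L, 2L), c("SNP", "SNP", "SNP"), c("C", "C", "T"),
            c("T", "G", "A"), chrom = "c")   # third has wrong ref allele
  expect_message(iv <- integrate_variants(ref, v), "rejected 1")
  expect_equal(attr(iv, "rejected"), 1L)
  expect_equal(iv$ref$chroms$c$mask[2], bitwOr(bitwOr(2L, 8L), 4L))
  expect_equal(iv$ref$chroms$c$mask[3], 4L)
})

test_that("SNP-tolerant base matching follows the bit test", {
  expect_true(base_match("T", bitwOr(2L, 8L)))
  expect_false(base_match("G", bitwOr(2L, 8L)))
  expect_true(base_match("A", 1L))
  expect_false(base_match("N", 1L))
})

test_that("window queries are half-open and match a linear-scan oracle", {
  g <- strrep("ACGT", 20)
  ref <- load_reference(c(c = g))
  v <- vrec(c(10L, 30L), c("DEL", "INS"), c(substr(g, 11L, 15L), ""),
            c("", "TT"), chrom = "c")
  iv <- integrate_variants(ref, v)
  # DEL [10,15) overlaps [12,20)
  expect_equal(variants_in_window(iv$alt_index, "c", 12L, 20L)$id, 1L)
  # INS at 30 excluded from [0,30) (half-open), included from [30,31)
  expect_equal(nrow(variants_in_window(iv$alt_index, "c", 0L, 30L)), 1L)
  expect_equal(variants_in_window(iv$alt_index, "c", 30L, 31L)$id, 2L)
  expect_error(variants_in_window(iv$alt_index, "zz", 0L, 5L),
               class = "varatree_error_unknown_chrom")

  # randomized agreement with a brute-force scan
  set.seed(71)
  for (it in 1:1000) {
    L <- 200L
    n <- sample(0:8, 1)
    vars <- if (n > 0) {
      pos <- sort(sample(0:(L - 20L), n))
      pos <- pos[c(TRUE, diff(pos) >= 12L)][seq_len(min(n, sum(c(TRUE, diff(pos) >= 12L))))]
      n <- length(pos)
      vt <- sample(c("INS", "DEL"), n, replace = TRUE)
      len <- sample(1:6, n, replace = TRUE)
      vrec(pos, vt, ifelse(vt == "DEL", strrep("A", len), ""),
           ifelse(vt == "INS", strrep("C", len), ""), chrom = "c")
    } else empty_variants()
    refL <- load_reference(c(c = strrep("A", L)))
    iv <- suppressMessages(integrate_variants(refL, vars))
    s <- sample(0:(L - 2L), 1); e <- sample((s + 1L):L, 1)
    got <- variants_in_window(iv$alt_index, "c", s, e)$id
    span <- if (nrow(vars)) ifelse(vars$vtype == "INS", 0L, vars$len) else integer(0)
    acc <- attr(iv, "rejected")
    keepv <- vars[!logical(nrow(vars)), ]
    exp <- keepv$id[(keepv$pos < e) &
                      ifelse(span == 0L, keepv$pos >= s,
                             keepv$pos + span > s)]
    expect_equal(got, sort(exp))
  }
})

test_that("VCF round-trip normalizes anchored INDELs and splits ALTs", {
  g <- c(chr1 = "ACGTACGTACGTACGTACGTACGTACGTACGT")
  vars <- vrec(c(3L, 10L, 20L), c("SNP", "INS", "DEL"),
               c("T", "", substr(g, 21L, 23L)), c("A", "GGA", ""),
               chrom = "chr1")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vars, g, f)
  back <- read_vcf_variants(f)
  expect_equal(back$pos, vars$pos)
  expect_equal(back$vtype, vars$vtype)
  expect_equal(back$ref_allele, vars$ref_allele)
  expect_equal(back$alt_allele, vars$alt_allele)
  # multi-allelic line splits into independent records
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t4\t.\tT\tA,C\t.\tPASS\t."), f2)
  multi <- read_vcf_variants(f2)
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$alt_allele, c("A", "C"))
})

test_that("index serialization round-trips with a version header", {
  g <- strrep("ACGTAAGG", 10)
  ref <- load_reference(c(c = g))
  iv <- integrate_variants(ref, vrec(5L, "DEL", substr(g, 6L, 8L), "",
                                     chrom = "c"))
  f <- withr::local_tempfile(fileext = ".rds")
  save_index(iv, f)
  back <- load_index(f)
  expect_equal(decode_reference(back$ref, "c"), decode_reference(ref, "c"))
  expect_equal(variants_in_window(back$alt_index, "c", 0L, 80L)$id, 1L)
  saveRDS(list(format = "other"), f)
  expect_error(load_index(f), class = "varatree_error_bad_index")
})

test_that("random FASTA round-trips through encode/decode with variants", {
  set.seed(5)
  for (it in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 300,
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    ref <- load_reference(c(x = s))
    expect_equal(decode_reference(ref, "x"), s)
    snp_at <- which(strsplit(s, "")[[1]] == "A")[1:3]
    snp_at <- snp_at[!is.na(snp_at)]
    if (length(snp_at)) {
      v <- vrec(snp_at - 1L, rep("SNP", length(snp_at)),
                rep("A", length(snp_at)), rep("G", length(snp_at)),
                chrom = "x")
      iv <- integrate_variants(ref, v)
      expect_equal(decode_reference(iv$ref, "x"), s)
    }
  }
})
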