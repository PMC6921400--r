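# Synthetic data generation and alignment evaluation.
#
# The simulator emulates the study design used to benchmark variation-aware
# mapping: a random genome, a planted variant set written as a VCF, and
# Illumina-like paired-end reads drawn from the VARIANT-APPLIED genome (so
# variant-spanning reads are the stress case) with truth positions lifted
# back to original reference coordinates.

#' Simulation configuration
#'
#' @param genome_len Total genome length (bp).
#' @param n_chrom Number of chromosomes (equal split).
#' @param snp_rate,ins_rate,del_rate Per-base planting rates.
#' @param indel_geom_p Success probability of the geometric INDEL length
#'   distribution (lengths capped at `indel_max_len`).
#' @param indel_max_len Maximum INDEL length.
#' @param read_len Read length (bp).
#' @param n_pairs Number of read pairs.
#' @param insert_mean,insert_sd Outer insert size model (bp).
#' @param error_rate Per-base substitution error rate.
#' @param mhc_like If `TRUE`, add a 5 kb sub-region with 10x variant density
#'   (a desk-scale analogue of a dense, complex region such as the MHC).
#' @param seed RNG seed; identical seeds give identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 200000L, n_chrom = 1L,
                       snp_rate = 1e-3, ins_rate = 1e-4, del_rate = 1e-4,
                       indel_geom_p = 0.25, indel_max_len = 20L,
                       read_len = 100L, n_pairs = 20000L,
                       insert_mean = 500, insert_sd = 25,
                       error_rate = 0.002, mhc_like = FALSE, seed = 1L) {
  stopifnot(genome_len > 0, n_chrom >= 1, read_len > 0, n_pairs >= 0,
            insert_mean > 0, insert_sd >= 0,
            snp_rate >= 0, snp_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1, error_rate >= 0, error_rate < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a uniform random genome
#'
#' @param cfg A [sim_config()].
#' @return Named character vector of chromosome sequences (chr1, chr2, ...);
#'   write with [write_fasta()].
#' @export
simulate_genome <- function(cfg) {
  if (cfg$genome_len <= 0)
    stop2("varatree_error_bad_config", "genome_len must be positive")
  set.seed(cfg$seed)
  per <- rep(cfg$genome_len %/% cfg$n_chrom, cfg$n_chrom)
  per[1] <- per[1] + cfg$genome_len %% cfg$n_chrom
  g <- vapply(per, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  names(g) <- paste0("chr", seq_len(cfg$n_chrom))
  g
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

rgeom_capped <- function(n, p, cap) pmin(stats::rgeom(n, p) + 1L, cap)

#' Plant non-overlapping variants on a genome
#'
#' Draws SNP/INS/DEL positions at the configured rates (minimum spacing 25 bp
#' between variant reference spans so no two INDELs interact on one read
#' path more than the tree can express), with geometric INDEL lengths. In
#' `mhc_like` mode a 5 kb sub-region of chromosome 1 receives 10x density.
#'
#' @param genome Named character vector from [simulate_genome()].
#' @param cfg A [sim_config()].
#' @return A tibble of variant records; write with [write_vcf()].
#' @export
simulate_variants <- function(genome, cfg) {
  set.seed(cfg$seed + 1L)
  out <- list()
  nid <- 1L
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    lo <- 60L; hi <- L - 90L
    if (hi <= lo) next
    rate <- cfg$snp_rate + cfg$ins_rate + cfg$del_rate
    dense_lo <- dense_hi <- -1L
    n <- stats::rpois(1, rate * (hi - lo))
    pos <- sort(sample(lo:hi, min(n, hi - lo), replace = FALSE))
    if (cfg$mhc_like && ch == names(genome)[1] && hi - lo > 10000L) {
      dense_lo <- lo + (hi - lo) %/% 2L
      dense_hi <- min(hi, dense_lo + 5000L)
      n2 <- stats::rpois(1, 9 * rate * (dense_hi - dense_lo))
      pos <- sort(unique(c(pos, sample(dense_lo:dense_hi,
                                       min(n2, dense_hi - dense_lo)))))
    }
    if (length(pos) == 0L) next
    # enforce 25 bp spacing
    keep <- c(TRUE, diff(pos) >= 25L)
    while (!all(keep)) { pos <- pos[keep]; keep <- c(TRUE, diff(pos) >= 25L) }
    n <- length(pos)
    probs <- c(cfg$snp_rate, cfg$ins_rate, cfg$del_rate)
    vt <- sample(c("SNP", "INS", "DEL"), n, replace = TRUE, prob = probs)
    lens <- ifelse(vt == "SNP", 1L,
                   rgeom_capped(n, cfg$indel_geom_p, cfg$indel_max_len))
    refA <- character(n); altA <- character(n)
    for (i in seq_len(n)) {
      if (vt[i] == "SNP") {
        rb <- substr(genome[[ch]], pos[i] + 1L, pos[i] + 1L)
        refA[i] <- rb
        altA[i] <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      } else if (vt[i] == "INS") {
        refA[i] <- ""
        altA[i] <- paste(sample(c("A", "C", "G", "T"), lens[i],
                                replace = TRUE), collapse = "")
      } else {
        refA[i] <- substr(genome[[ch]], pos[i] + 1L, pos[i] + lens[i])
        altA[i] <- ""
      }
    }
    t <- variant_records(rep(ch, n), pos, vt, refA, altA,
                         id = nid - 1L + seq_len(n))
    nid <- nid + n
    out[[ch]] <- t
  }
  if (length(out) == 0L) return(empty_variants())
  do.call(rbind, out)
}

#' Write a variant table as a VCF 4.2 file
#'
#' Anchorless internal records are converted back to anchored VCF notation
#' (INS: REF = anchor base, ALT = anchor + inserted; DEL: REF = anchor +
#' deleted, ALT = anchor) with 1-based positions.
#'
#' @param variants Variant tibble.
#' @param genome Named character vector (for anchor bases).
#' @param path Output path.
#' @export
write_vcf <- function(variants, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(nrow(variants))
  if (nrow(variants) > 0L) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (v$vtype == "SNP") {
        p1 <- v$pos + 1L; ref <- v$ref_allele; alt <- v$alt_allele
      } else {
        anchor <- substr(genome[[v$chrom]], v$pos, v$pos)  # base before, 1-based
        p1 <- v$pos
        if (v$vtype == "INS") { ref <- anchor; alt <- paste0(anchor, v$alt_allele) }
        else { ref <- paste0(anchor, v$ref_allele); alt <- anchor }
      }
      lines[i] <- sprintf("%s\t%d\tvar%d\t%s\t%s\t.\tPASS\t.",
                          v$chrom, p1, v$id, ref, alt)
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# Apply variants to one chromosome; returns the haplotype string, M-block
# liftover tables and per-variant haplotype intervals.
apply_variants_chrom <- function(seq, vars) {
  vars <- vars[order(vars$pos), , drop = FALSE]
  pieces <- character(0)
  ref_cur <- 0L; hap_cur <- 0L
  blk_ref <- integer(0); blk_hap <- integer(0); blk_len <- integer(0)
  v_hs <- integer(nrow(vars)); v_he <- integer(nrow(vars))
  add_block <- function(rs, len) {
    if (len <= 0L) return(invisible())
    pieces[[length(pieces) + 1L]] <<- substr(seq, rs + 1L, rs + len)
    blk_ref <<- c(blk_ref, rs); blk_hap <<- c(blk_hap, hap_cur)
    blk_len <<- c(blk_len, len)
    hap_cur <<- hap_cur + len
  }
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    add_block(ref_cur, v$pos - ref_cur)
    if (v$vtype == "SNP") {
      pieces[[length(pieces) + 1L]] <- v$alt_allele
      blk_ref <- c(blk_ref, v$pos); blk_hap <- c(blk_hap, hap_cur)
      blk_len <- c(blk_len, 1L)
      v_hs[i] <- hap_cur; hap_cur <- hap_cur + 1L; v_he[i] <- hap_cur
      ref_cur <- v$pos + 1L
    } else if (v$vtype == "INS") {
      v_hs[i] <- hap_cur
      pieces[[length(pieces) + 1L]] <- v$alt_allele
      hap_cur <- hap_cur + v$len
      v_he[i] <- hap_cur
      ref_cur <- v$pos
    } else {
      v_hs[i] <- hap_cur; v_he[i] <- hap_cur
      ref_cur <- v$pos + v$len
    }
  }
  add_block(ref_cur, nchar(seq) - ref_cur)
  list(hap = paste0(pieces, collapse = ""),
       blk_ref = blk_ref, blk_hap = blk_hap, blk_len = blk_len,
       var_hs = v_hs, var_he = v_he)
}

# Lift haplotype positions to original reference coordinates: the reference
# position of the first reference-aligned base at or after hap position h.
lift_to_ref <- function(h, blocks) {
  i <- findInterval(h, blocks$blk_hap)
  i <- pmax(i, 1L)
  within <- h < blocks$blk_hap[i] + blocks$blk_len[i]
  ref <- ifelse(within, blocks$blk_ref[i] + (h - blocks$blk_hap[i]),
                ifelse(i < length(blocks$blk_ref),
                       blocks$blk_ref[pmin(i + 1L, length(blocks$blk_ref))],
                       NA_integer_))
  as.integer(ref)
}

#' Simulate Illumina-like paired-end reads with truth records
#'
#' Fragments are drawn from the variant-applied genome with normal insert
#' sizes; each pair has one forward and one reverse-complement end in FR
#' orientation (which physical end is read 1 is randomized). Per-base
#' substitution errors are i.i.d. at `cfg$error_rate`; qualities are
#' constant. Truth positions are the 1-based original-reference coordinates
#' of the leftmost reference-aligned base of each end, with the ids of
#' spanned variants recorded.
#'
#' @param genome Named character vector.
#' @param variants Variant tibble (as from [simulate_variants()]).
#' @param cfg A [sim_config()].
#' @return List with `fq1`, `fq2` (named character vectors of read
#'   sequences) and `truth` (tibble: read id, per-end chrom, 1-based pos,
#'   strand, spanned variant ids).
#' @export
simulate_reads <- function(genome, variants, cfg) {
  set.seed(cfg$seed + 2L)
  applied <- lapply(names(genome), function(ch)
    apply_variants_chrom(genome[[ch]],
                         variants[variants$chrom == ch, , drop = FALSE]))
  names(applied) <- names(genome)
  hap_lens <- vapply(applied, function(a) nchar(a$hap), numeric(1))
  n <- cfg$n_pairs
  chrom_idx <- sample.int(length(genome), n, replace = TRUE,
                          prob = hap_lens / sum(hap_lens))
  frag <- as.integer(round(stats::rnorm(n, cfg$insert_mean, cfg$insert_sd)))
  frag <- pmax(frag, cfg$read_len)
  # rejected draws (insert beyond chromosome) are resampled
  for (it in 1:50) {
    bad <- frag > hap_lens[chrom_idx]
    if (!any(bad)) break
    chrom_idx[bad] <- sample.int(length(genome), sum(bad), replace = TRUE,
                                 prob = hap_lens / sum(hap_lens))
    frag[bad] <- pmax(as.integer(round(stats::rnorm(sum(bad), cfg$insert_mean,
                                                    cfg$insert_sd))),
                      cfg$read_len)
  }
  start <- integer(n)
  for (ci in unique(chrom_idx)) {
    sel <- chrom_idx == ci
    start[sel] <- as.integer(floor(stats::runif(sum(sel)) *
                                     (hap_lens[ci] - frag[sel] + 1)))
  }
  rl <- cfg$read_len
  seq_fwd <- character(n); seq_rev <- character(n)
  pos_fwd <- integer(n); pos_rev <- integer(n)
  vars_fwd <- character(n); vars_rev <- character(n)
  for (ci in seq_along(applied)) {
    sel <- which(chrom_idx == ci)
    if (length(sel) == 0L) next
    a <- applied[[ci]]
    s1 <- start[sel]; s2 <- start[sel] + frag[sel] - rl
    seq_fwd[sel] <- substring(a$hap, s1 + 1L, s1 + rl)
    seq_rev[sel] <- revcomp(substring(a$hap, s2 + 1L, s2 + rl))
    pos_fwd[sel] <- lift_to_ref(s1, a)
    pos_rev[sel] <- lift_to_ref(s2, a)
    cv <- variants[variants$chrom == names(applied)[ci], , drop = FALSE]
    if (nrow(cv) > 0L) {
      vr <- IRanges::IRanges(start = a$var_hs + 1L,
                             end = pmax(a$var_he, a$var_hs + 1L))
      ov1 <- IRanges::findOverlaps(IRanges::IRanges(s1 + 1L, s1 + rl), vr)
      ov2 <- IRanges::findOverlaps(IRanges::IRanges(s2 + 1L, s2 + rl), vr)
      agg <- function(ov) {
        m <- tapply(cv$id[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov),
                    function(x) paste(sort(x), collapse = ","))
        out <- character(length(sel)); out[as.integer(names(m))] <- m
        out
      }
      vars_fwd[sel] <- agg(ov1); vars_rev[sel] <- agg(ov2)
    }
  }
  # sequencing errors: i.i.d. substitutions
  if (cfg$error_rate > 0) {
    inject <- function(seqs) {
      nerr <- stats::rbinom(1, length(seqs) * rl, cfg$error_rate)
      if (nerr == 0L) return(seqs)
      at <- sample.int(length(seqs) * rl, nerr)
      ri <- (at - 1L) %/% rl + 1L; off <- (at - 1L) %% rl + 1L
      for (k in seq_len(nerr)) {
        old <- substr(seqs[ri[k]], off[k], off[k])
        substr(seqs[ri[k]], off[k], off[k]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
      seqs
    }
    seq_fwd <- inject(seq_fwd); seq_rev <- inject(seq_rev)
  }
  # randomize which physical end is read 1
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ids <- sprintf("rd%06d", seq_len(n))
  fq1 <- ifelse(flip, seq_rev, seq_fwd)
  fq2 <- ifelse(flip, seq_fwd, seq_rev)
  names(fq1) <- ids; names(fq2) <- ids
  truth <- tibble::tibble(
    read_id = ids,
    chrom = names(genome)[chrom_idx],
    pos1 = ifelse(flip, pos_rev, pos_fwd) + 1L,
    strand1 = ifelse(flip, "-", "+"),
    vars1 = ifelse(flip, vars_rev, vars_fwd),
    pos2 = ifelse(flip, pos_fwd, pos_rev) + 1L,
    strand2 = ifelse(flip, "+", "-"),
    vars2 = ifelse(flip, vars_fwd, vars_rev))
  list(fq1 = fq1, fq2 = fq2, truth = truth)
}

#' Write reads as FASTQ (constant qualities)
#' @param reads Named character vector.
#' @param path Output path.
#' @param qual Quality character (default "I", Q40).
#' @export
write_fastq <- function(reads, path, qual = "I") {
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n",
                    vapply(nchar(reads), function(n)
                      strrep(qual, n), character(1))), path)
  invisible(path)
}

#' Write / read truth records as TSV
#' @param truth Truth tibble from [simulate_reads()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tibble::as_tibble(utils::read.delim(path, colClasses = c(
    read_id = "character", chrom = "character", vars1 = "character",
    vars2 = "character")))
}

#' Random variation-tree instance for algorithmic validation
#'
#' Draws a local window (50-200 bp by default) from a random genome, plants
#' 0-5 non-overlapping variants, builds the variation tree with enumerated
#' paths, and samples a read as a prefix slice of a random haplotype path
#' with up to `e_max` random edits planted. The minimal alignment distance of
#' such an instance can be computed independently by full-DP Levenshtein over
#' the enumerated path sequences ([edit_distance_dp()]).
#'
#' @param win_range Window length range.
#' @param max_vars Maximum planted variants.
#' @param read_range Read slice length range.
#' @param edit_frac `e_max = ceiling(edit_frac * read length)`.
#' @return List with `tree` (paths enumerated), `read`, `e_max`, `n_edits`.
#' @export
random_tree_instance <- function(win_range = c(50L, 200L), max_vars = 5L,
                                 read_range = c(30L, 80L),
                                 edit_frac = 0.1) {
  W <- sample(win_range[1]:win_range[2], 1)
  genome <- paste(sample(c("A", "C", "G", "T"), W + 60L, replace = TRUE),
                  collapse = "")
  ref <- load_reference(c(chr = genome))
  nv <- sample(0:max_vars, 1)
  vars <- empty_variants()
  if (nv > 0) {
    pos <- sort(sample(seq(2L, W - 10L), nv))
    if (nv > 1 && any(diff(pos) < 12L)) pos <- pos[c(TRUE, diff(pos) >= 12L)]
    nv <- length(pos)
    vt <- sample(c("SNP", "INS", "DEL"), nv, replace = TRUE)
    refA <- character(nv); altA <- character(nv)
    for (i in seq_len(nv)) {
      if (vt[i] == "SNP") {
        rb <- substr(genome, pos[i] + 1L, pos[i] + 1L)
        refA[i] <- rb
        altA[i] <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      } else if (vt[i] == "INS") {
        L <- sample(1:8, 1); refA[i] <- ""
        altA[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                         collapse = "")
      } else {
        L <- sample(1:8, 1)
        refA[i] <- substr(genome, pos[i] + 1L, pos[i] + L); altA[i] <- ""
      }
    }
    vars <- variant_records(rep("chr", nv), pos, vt, refA, altA)
  }
  iv <- integrate_variants(ref, vars)
  win <- region_window(iv$ref, "chr", 0L, W)
  tree <- build_tree(win, variants_in_window(iv$alt_index, "chr", 0L, W))
  tree <- set_paths(tree, enumerate_paths(tree, path_cap = 4096L))
  p <- tree$paths[[sample(length(tree$paths), 1)]]
  rl <- min(nchar(p$hap), sample(read_range[1]:read_range[2], 1))
  read <- substr(p$hap, 1L, rl)
  e_max <- as.integer(ceiling(edit_frac * rl))
  ne <- sample(0:e_max, 1)
  for (k in seq_len(ne)) {
    op <- sample(1:3, 1); i <- sample(nchar(read), 1)
    if (op == 1L) substr(read, i, i) <- sample(c("A", "C", "G", "T"), 1)
    else if (op == 2L && nchar(read) > 10L)
      read <- paste0(substr(read, 1L, i - 1L),
                     substr(read, i + 1L, nchar(read)))
    else read <- paste0(substr(read, 1L, i),
                        sample(c("A", "C", "G", "T"), 1),
                        substr(read, i + 1L, nchar(read)))
  }
  list(tree = tree, read = read, e_max = e_max, n_edits = ne)
}

#' Evaluate alignments against simulation truth
#'
#' An end counts as accurate when its record is mapped on the correct
#' chromosome and strand with `|pos - true pos| <= tolerance`. Soft-clipped
#' count is the number of records whose CIGAR contains S.
#'
#' @param sam A SAM record tibble (from [map_reads()]) or a SAM file path.
#' @param truth Truth tibble or TSV path.
#' @param tolerance Position tolerance in bp (default 10).
#' @return A tibble with `accuracy` (percent of ends), `unmapped` (ends),
#'   `softclip` (records), `n_ends`.
#' @export
evaluate_alignments <- function(sam, truth, tolerance = 10L) {
  if (is.character(sam)) sam <- read_sam(sam)
  if (is.character(truth)) truth <- read_truth(truth)
  rec <- sam[bitwAnd(sam$flag, 256L) == 0L & bitwAnd(sam$flag, 2048L) == 0L, ]
  first <- bitwAnd(rec$flag, 64L) > 0L
  m <- match(rec$qname, truth$read_id)
  if (anyNA(m))
    stop2("varatree_error_truth_mismatch",
          "SAM contains read ids absent from the truth table")
  tchrom <- truth$chrom[m]
  tpos <- ifelse(first, truth$pos1[m], truth$pos2[m])
  tstrand <- ifelse(first, truth$strand1[m], truth$strand2[m])
  unmapped <- bitwAnd(rec$flag, 4L) > 0L
  strand <- ifelse(bitwAnd(rec$flag, 16L) > 0L, "-", "+")
  ok <- !unmapped & rec$rname == tchrom & strand == tstrand &
    abs(rec$pos - tpos) <= tolerance
  n_soft <- sum(!unmapped & grepl("S", rec$cigar, fixed = TRUE))
  tibble::tibble(accuracy = 100 * mean(ok),
                 unmapped = sum(unmapped),
                 softclip = n_soft,
                 n_ends = nrow(rec))
}
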