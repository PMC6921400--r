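# Variation-aware reference: SNPs folded into 4-bit site codes, INDELs held
# in a positional side index ("ALT-seq" style).
#
# Coordinates are 0-based half-open everywhere inside the package; VCF input
# is converted once on read, SAM output converts back at the boundary.

#' Load a reference genome into the 4-bit site-code representation
#'
#' Each base becomes a 4-bit site code whose only set bit is the reference
#' base. Non-ACGT characters (N, IUPAC codes) are encoded permissively with
#' all four bits set, are excluded from k-mer seeding, and decode back to the
#' original (uppercased) character.
#'
#' @param fasta_source Path to a FASTA file, or a named character vector of
#'   sequences (for programmatic construction).
#' @return An object of class `varef`: per-chromosome site-code vectors plus
#'   the uppercased sequence, with `lengths(ref)` giving chromosome lengths.
#' @examples
#' ref <- load_reference(c(chr1 = "ACGTACGT"))
#' lengths(ref)
#' @export
load_reference <- function(fasta_source) {
  if (is.character(fasta_source) && is.null(names(fasta_source)) &&
      length(fasta_source) == 1L && file.exists(fasta_source)) {
    dss <- Biostrings::readDNAStringSet(fasta_source)
    seqs <- as.character(dss)
    names(seqs) <- sub("\\s.*$", "", names(dss))
  } else if (is.character(fasta_source) && !is.null(names(fasta_source))) {
    seqs <- fasta_source
  } else {
    stop2("varatree_error_bad_fasta",
          "fasta_source must be a FASTA path or a named character vector")
  }
  if (length(seqs) == 0L)
    stop2("varatree_error_empty_fasta", "no sequences in FASTA input")
  if (anyDuplicated(names(seqs)))
    stop2("varatree_error_duplicate_seqnames",
          "duplicate sequence names in FASTA input")
  if (any(!nzchar(seqs)))
    stop2("varatree_error_empty_fasta", "zero-length sequence in FASTA input")
  chroms <- lapply(seqs, function(s) {
    s <- toupper(s)
    bits <- base_bits(s)
    mask <- ifelse(bits == 0L, 15L, bits)
    list(seq = s, mask = as.integer(mask))
  })
  structure(list(chroms = chroms,
                 lengths = vapply(chroms, function(c) length(c$mask),
                                  integer(1))),
            class = "varef")
}

#' @export
lengths.varef <- function(x, use.names = TRUE) x$lengths

#' @export
print.varef <- function(x, ...) {
  snps <- sum(vapply(x$chroms, function(c) {
    bits <- base_bits(c$seq)
    sum(c$mask != bits & c$mask != 15L)
  }, numeric(1)))
  cat(sprintf("<varef> %d sequence(s), %s bp, %d SNP-augmented site(s)\n",
              length(x$chroms), format(sum(x$lengths), big.mark = ","),
              as.integer(snps)))
  invisible(x)
}

#' Decode the reference base string of a chromosome (round-trip check)
#' @param ref A `varef`.
#' @param chrom Chromosome name.
#' @return Uppercased reference string.
#' @export
decode_reference <- function(ref, chrom) {
  .chrom(ref, chrom)$seq
}

.chrom <- function(ref, chrom) {
  c <- ref$chroms[[chrom]]
  if (is.null(c))
    stop2("varatree_error_unknown_chrom", sprintf("unknown chromosome '%s'", chrom))
  c
}

stop2 <- function(class, msg) {
  stop(structure(class = c(class, "varatree_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Construct a table of variant records
#'
#' Builds the internal variant representation: 0-based anchorless records.
#' SNPs have `ref_allele`/`alt_allele` of length 1; INS records have an empty
#' reference span at `pos` and `alt_allele` of length `len`; DEL records
#' delete `len` = `nchar(ref_allele)` bases starting at `pos`.
#'
#' @param chrom,pos,vtype,ref_allele,alt_allele Parallel vectors; `pos` is
#'   0-based, `vtype` in `c("SNP","INS","DEL")`.
#' @param id Optional stable integer ids (assigned sequentially if missing).
#' @return A tibble with one row per variant.
#' @export
variant_records <- function(chrom, pos, vtype, ref_allele, alt_allele,
                            id = NULL) {
  vtype <- toupper(vtype)
  stopifnot(all(vtype %in% c("SNP", "INS", "DEL")))
  len <- ifelse(vtype == "SNP", 1L,
         ifelse(vtype == "INS", nchar(alt_allele), nchar(ref_allele)))
  bad <- (vtype == "SNP" & (nchar(ref_allele) != 1L | nchar(alt_allele) != 1L |
                             ref_allele == alt_allele)) |
         (vtype == "INS" & (nchar(ref_allele) != 0L | len <= 0L)) |
         (vtype == "DEL" & (nchar(alt_allele) != 0L | len <= 0L))
  if (any(bad))
    stop2("varatree_error_bad_variant",
          sprintf("%d malformed variant record(s)", sum(bad)))
  tibble::tibble(
    chrom = unname(as.character(chrom)), pos = unname(as.integer(pos)),
    vtype = unname(vtype),
    ref_allele = unname(toupper(ref_allele)),
    alt_allele = unname(toupper(alt_allele)),
    len = unname(as.integer(len)),
    id = if (is.null(id)) seq_along(vtype) else unname(as.integer(id)))
}

#' Read variants from a VCF file
#'
#' Parses a VCF 4.x file (genotype columns ignored), splits multi-allelic
#' lines into independent records, and normalizes anchored INDEL notation
#' (REF=A ALT=ATT) into anchorless INS/DEL records at the base after the
#' anchor. Records with non-ACGT alleles or complex (non SNP/INS/DEL)
#' substitutions are skipped with a message.
#'
#' @param vcf_path Path to an uncompressed or gzipped VCF file.
#' @return A tibble of variant records (see [variant_records()]).
#' @export
read_vcf_variants <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix)))       # single-row VCF
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0L) {
    return(variant_records(character(0), integer(0), character(0),
                           character(0), character(0)))
  }
  chrom <- character(0); pos <- integer(0); vtype <- character(0)
  refa <- character(0); alta <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    p1 <- as.integer(fix[i, "POS"])          # 1-based VCF
    for (alt in strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]) {
      if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
        skipped <- skipped + 1L; next
      }
      if (nchar(ref) == 1L && nchar(alt) == 1L) {
        if (ref == alt) { skipped <- skipped + 1L; next }
        chrom <- c(chrom, fix[i, "CHROM"]); pos <- c(pos, p1 - 1L)
        vtype <- c(vtype, "SNP"); refa <- c(refa, ref); alta <- c(alta, alt)
        next
      }
      # strip shared leading anchor
      n <- min(nchar(ref), nchar(alt))
      lcp <- 0L
      while (lcp < n && substr(ref, lcp + 1L, lcp + 1L) ==
                        substr(alt, lcp + 1L, lcp + 1L)) lcp <- lcp + 1L
      r2 <- substr(ref, lcp + 1L, nchar(ref))
      a2 <- substr(alt, lcp + 1L, nchar(alt))
      if (nchar(r2) == 0L && nchar(a2) > 0L) {
        chrom <- c(chrom, fix[i, "CHROM"]); pos <- c(pos, p1 - 1L + lcp)
        vtype <- c(vtype, "INS"); refa <- c(refa, ""); alta <- c(alta, a2)
      } else if (nchar(a2) == 0L && nchar(r2) > 0L) {
        chrom <- c(chrom, fix[i, "CHROM"]); pos <- c(pos, p1 - 1L + lcp)
        vtype <- c(vtype, "DEL"); refa <- c(refa, r2); alta <- c(alta, "")
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  if (skipped > 0L)
    message(sprintf("read_vcf_variants: skipped %d non-simple record(s)", skipped))
  variant_records(chrom, pos, vtype, refa, alta)
}

#' Integrate variants into a variation-aware reference
#'
#' SNP alternate bits are OR-ed into the site code at their position; the
#' reference base bit is never cleared. INS/DEL records are routed untouched
#' into a position-sorted side index queryable by half-open interval. Records
#' whose `ref_allele` does not match the reference are rejected per record
#' and counted.
#'
#' @param ref A `varef` from [load_reference()].
#' @param variants A variant table (see [variant_records()] /
#'   [read_vcf_variants()]).
#' @return A list with elements `ref` (the SNP-augmented `varef`) and
#'   `alt_index` (class `altseq_index`), plus attribute `"rejected"` with the
#'   rejection count.
#' @export
integrate_variants <- function(ref, variants) {
  stopifnot(inherits(ref, "varef"))
  rejected <- 0L
  if (nrow(variants) > 0L) {
    keep <- logical(nrow(variants))
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      ch <- ref$chroms[[v$chrom]]
      span <- if (v$vtype == "INS") 0L else nchar(v$ref_allele)
      ok <- !is.null(ch) && v$pos >= 0L && v$pos + span <= length(ch$mask) &&
        (span == 0L ||
           substr(ch$seq, v$pos + 1L, v$pos + span) == v$ref_allele)
      keep[i] <- ok
    }
    rejected <- sum(!keep)
    if (rejected > 0L)
      message(sprintf("integrate_variants: rejected %d record(s) with reference mismatch",
                      rejected))
    variants <- variants[keep, , drop = FALSE]
  }
  snps <- variants[variants$vtype == "SNP", , drop = FALSE]
  if (nrow(snps) > 0L) {
    for (ch in unique(snps$chrom)) {
      s <- snps[snps$chrom == ch, ]
      bits <- base_bits(paste0(s$alt_allele, collapse = ""))
      idx <- s$pos + 1L
      upd <- tapply(bits, idx, function(b) Reduce(bitwOr, b))
      at <- as.integer(names(upd))
      ref$chroms[[ch]]$mask[at] <-
        bitwOr(ref$chroms[[ch]]$mask[at], as.integer(upd))
    }
  }
  indels <- variants[variants$vtype != "SNP", , drop = FALSE]
  idx <- new_altseq_index(indels, ref$lengths)
  structure(list(ref = ref, alt_index = idx), rejected = rejected)
}

new_altseq_index <- function(indels, lengths) {
  by_chrom <- lapply(names(lengths), function(ch) {
    t <- indels[indels$chrom == ch, , drop = FALSE]
    t <- t[order(t$pos, t$id), , drop = FALSE]
    t$ref_span <- ifelse(t$vtype == "INS", 0L, t$len)
    t
  })
  names(by_chrom) <- names(lengths)
  structure(list(by_chrom = by_chrom, lengths = lengths),
            class = "altseq_index")
}

#' @export
print.altseq_index <- function(x, ...) {
  n <- sum(vapply(x$by_chrom, nrow, integer(1)))
  cat(sprintf("<altseq_index> %d INDEL record(s) on %d sequence(s)\n",
              n, length(x$by_chrom)))
  invisible(x)
}

#' SNP-tolerant base match against a site code
#'
#' True iff the read base's bit is set in the site's 4-bit code. `N` matches
#' nothing.
#'
#' @param read_base Single character (A/C/G/T/N).
#' @param code Integer site code (0..15).
#' @return Logical.
#' @examples
#' base_match("T", bitwOr(2L, 8L))  # site carrying C with a C>T SNP
#' @export
base_match <- function(read_base, code) {
  bitwAnd(base_bits(read_base)[1], as.integer(code)) > 0L
}

#' Query INDEL records overlapping a half-open window
#'
#' Returns exactly the records whose reference span `[pos, pos + span)`
#' overlaps `[start, end)`; insertions (span 0) are treated as attachment
#' points and returned iff `start <= pos < end`. Results are sorted by
#' position, ties by id.
#'
#' @param idx An `altseq_index`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @return Tibble of variant records.
#' @export
variants_in_window <- function(idx, chrom, start, end) {
  t <- idx$by_chrom[[chrom]]
  if (is.null(t))
    stop2("varatree_error_unknown_chrom",
          sprintf("unknown chromosome '%s'", chrom))
  stopifnot(start >= 0, start < end)
  hit <- (t$pos < end) &
    ifelse(t$ref_span == 0L, t$pos >= start, t$pos + t$ref_span > start)
  t[hit, , drop = FALSE]
}

#' Empty the variant knowledge of an index (for ablation runs)
#'
#' Returns the pair `(ref, alt_index)` with all SNP bits stripped back to the
#' reference base and an empty INDEL index, so mapping runs can be compared
#' with and without variant awareness.
#'
#' @param vindex A list with `ref` and `alt_index` as from
#'   [integrate_variants()].
#' @return The same structure with variant knowledge removed.
#' @export
strip_variants <- function(vindex) {
  ref <- vindex$ref
  for (ch in names(ref$chroms)) {
    bits <- base_bits(ref$chroms[[ch]]$seq)
    ref$chroms[[ch]]$mask <- ifelse(bits == 0L, 15L, bits)
  }
  empty <- variant_records(character(0), integer(0), character(0),
                           character(0), character(0))
  list(ref = ref, alt_index = new_altseq_index(empty, ref$lengths))
}

#' Serialize / load a variation-aware index
#'
#' On-disk serialization of the SNP-integrated reference, the INDEL side
#' index and the k-mer seed index, with a format-version header.
#'
#' @param vindex List with `ref`, `alt_index` and optionally `seed_index`.
#' @param path Destination file.
#' @export
save_index <- function(vindex, path) {
  obj <- list(format = "varatree-index", version = 1L,
              ref = vindex$ref, alt_index = vindex$alt_index,
              seed_index = vindex$seed_index)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "varatree-index"))
    stop2("varatree_error_bad_index", "not a varatree index file")
  if (obj$version > 1L)
    stop2("varatree_error_bad_index",
          sprintf("unsupported index format version %d", obj$version))
  obj[c("ref", "alt_index", "seed_index")]
}
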