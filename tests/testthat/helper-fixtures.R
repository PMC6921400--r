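# Shared fixtures: tree construction shortcuts and lazily cached simulation
# datasets for the end-to-end checks.

tree_from <- function(window_seq, variants = empty_variants(), start = 0L,
                      masks = NULL, enumerate = TRUE, ...) {
  w <- window_from_seq(window_seq, start = start, chrom = "w", masks = masks)
  tr <- build_tree(w, variants)
  if (enumerate) tr <- set_paths(tr, enumerate_paths(tr, ...))
  tr
}

vrec <- function(pos, vtype, ref_allele, alt_allele, chrom = "w", id = NULL) {
  variant_records(rep(chrom, length(pos)), pos, vtype, ref_allele,
                  alt_allele, id = id)
}

# apply-variants oracle: realize a haplotype directly by string surgery
apply_vars_oracle <- function(seq, vars) {
  if (nrow(vars) == 0L) return(seq)
  vars <- vars[order(vars$pos), , drop = FALSE]
  out <- ""
  cur <- 0L
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    out <- paste0(out, substr(seq, cur + 1L, v$pos))
    if (v$vtype == "SNP") { out <- paste0(out, v$alt_allele); cur <- v$pos + 1L }
    else if (v$vtype == "INS") { out <- paste0(out, v$alt_allele); cur <- v$pos }
    else cur <- min(nchar(seq), v$pos + v$len)
    if (cur >= nchar(seq)) { cur <- nchar(seq); break }
  }
  paste0(out, substr(seq, cur + 1L, nchar(seq)))
}

# edit cost implied by an ALT cigar, re-verified base by base against the
# realized haplotype (mismatches inside M runs + I/D lengths)
alt_cigar_cost <- function(tab, read_bits, hap_masks) {
  r <- 0L; h <- 0L; cost <- 0L
  for (i in seq_len(nrow(tab))) {
    op <- tab$op[i]; n <- tab$len[i]
    if (op == "M") {
      cost <- cost + sum(bitwAnd(read_bits[(r + 1L):(r + n)],
                                 hap_masks[(h + 1L):(h + n)]) == 0L)
      r <- r + n; h <- h + n
    } else if (op == "I") { cost <- cost + n; r <- r + n }
    else if (op == "D") { cost <- cost + n; h <- h + n }
    else r <- r + n
  }
  as.integer(cost)
}

# brute-force minimum alignment distance over all enumerated paths
brute_min_e <- function(tree, read) {
  min(vapply(tree$paths, function(p)
    edit_distance_dp(read, masks = p$hap_masks), integer(1)))
}

# --- cached simulation runs for the end-to-end acceptance checks ----------

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

sim_dataset <- function(cfg) {
  g <- simulate_genome(cfg)
  vars <- simulate_variants(g, cfg)
  sim <- simulate_reads(g, vars, cfg)
  ref <- load_reference(g)
  iv <- integrate_variants(ref, vars)
  iv$seed_index <- build_seed_index(iv$ref)
  list(cfg = cfg, genome = g, vars = vars, sim = sim, iv = iv)
}

get_sim100 <- function() cached("sim100", sim_dataset(
  sim_config(genome_len = 200000L, n_pairs = 20000L, read_len = 100L,
             seed = 20260101L)))

get_map100 <- function() cached("map100", {
  d <- get_sim100()
  sam <- map_reads(d$iv, d$sim$fq1, d$sim$fq2)
  list(sam = sam, metrics = evaluate_alignments(sam, d$sim$truth))
})
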