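# Shared fixtures, built in code. Everything is seeded; the heavier objects
# are memoised per test session.

tiny_cfg <- function(seed = 101, n_transcripts = 6, ...) {
  sim_config(seed = seed, genome_length = 40000, n_lines = 12,
             n_transcripts = n_transcripts, ...)
}

# a small simulated world: genome with embedded genes, panel, haplotypes
.world_cache <- new.env(parent = emptyenv())
tiny_world <- function(seed = 101) {
  key <- as.character(seed)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- tiny_cfg(seed)
  g0 <- sim_genome(cfg)
  tr <- sim_transcripts(g0, cfg)
  panel <- normalize_variants(sim_variants(tr$genome, cfg), tr$genome)
  w <- list(cfg = cfg, genome = tr$genome, transcripts = tr$transcripts,
            panel = panel)
  .world_cache[[key]] <- w
  w
}

# hand-built variant panel on an explicit genome
make_panel <- function(genome, pos, ref, alt, carriers, n_lines,
                       type = NULL) {
  tb <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_along(pos)),
    contig = "sim1", pos = as.integer(pos), ref = ref, alt = alt,
    nd = nchar(ref), ni = nchar(alt),
    type = type %||% ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snp", "other"),
    carriers = carriers, n_carriers = lengths(carriers))
  varcis:::new_variant_panel(tb, n_lines = n_lines,
                             genome_length = nchar(genome), contig = "sim1")
}

`%||%` <- rlang::`%||%`

# one-row site tibble for direct association testing
make_site <- function(line_allele, scores = NULL, min_lines = 3L) {
  ids <- sort(unique(line_allele))
  counts <- as.integer(table(factor(line_allele, levels = ids)))
  tibble::tibble(
    site_id = "siteX",
    alleles = list(tibble::tibble(
      allele_id = ids, n_lines = counts,
      score = scores %||% as.numeric(ids),
      included = counts >= min_lines)),
    line_allele = list(as.integer(line_allele)))
}

normalize_one_wrap <- function(pos, ref, alt, g) {
  varcis:::normalize_one(as.integer(pos), ref, alt, as.character(g))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive enumeration of group-label assignments (independent KW oracle)
enumerate_assignments <- function(sizes) {
  res <- list()
  rec <- function(remaining, sizes_left, labels) {
    if (!length(sizes_left)) {
      res[[length(res) + 1L]] <<- labels
      return(invisible())
    }
    for (cc in utils::combn(remaining, sizes_left[[1]], simplify = FALSE)) {
      l2 <- labels
      l2[cc] <- length(sizes_left)
      rec(setdiff(remaining, cc), sizes_left[-1], l2)
    }
  }
  rec(seq_len(sum(sizes)), sizes, integer(sum(sizes)))
  res
}

# exact permutation p-value of the Kruskal-Wallis H statistic
exact_kw_p <- function(y, g) {
  H_of <- function(gg) {
    r <- rank(y)
    S <- tapply(r, gg, sum)
    nk <- table(gg)
    n <- sum(nk)
    12 / (n * (n + 1)) * sum(S^2 / nk) - 3 * (n + 1)
  }
  hobs <- H_of(g)
  hs <- vapply(enumerate_assignments(as.integer(table(g))), H_of, numeric(1))
  list(p = mean(hs >= hobs - 1e-12), h_all = hs, h_obs = hobs)
}
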