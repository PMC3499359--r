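#' Simulate paired-end short reads from a haplotype
#'
#' Uniform fragment starts, Gaussian insert sizes, forward/reverse mate
#' orientation and i.i.d. per-base substitution errors. Every read records its
#' true origin (haplotype coordinate, mate, strand), so placement and
#' genotyping accuracy can be measured against planted truth.
#'
#' @param haplotype Character scalar source sequence.
#' @param config A [sim_config()].
#' @param line Label stored in the `line` column (and in FASTQ names).
#' @return Tibble with one row per read: `read_id`, `line`, `pair`, `mate`
#'   (1 or 2), `seq`, `hap_start` (1-based position of the read's first base
#'   on the source haplotype, always on the forward strand), `strand`,
#'   `insert`, `n_errors`.
#' @export
sim_reads <- function(haplotype, config, line = "line_1") {
  stopifnot(inherits(config, "sim_config"))
  L <- nchar(haplotype)
  rl <- config$read_length
  if (rl >= L) abort("read length must be smaller than the sequence")
  if (config$insert_mean < rl) abort("insert size must be at least one read length")
  with_substream(config$seed, "reads", line, code = {
    n_pairs <- max(1L, round(config$coverage * L / (2 * rl)))
    ins <- as.integer(pmax(rl, pmin(L, round(stats::rnorm(n_pairs,
                                                          config$insert_mean,
                                                          config$insert_sd)))))
    start <- vapply(ins, function(s) sample.int(L - s + 1L, 1L), integer(1))
    s1 <- start
    s2 <- start + ins - rl
    r1 <- substring(haplotype, s1, s1 + rl - 1L)
    r2 <- revcomp(substring(haplotype, s2, s2 + rl - 1L))
    pair_id <- sprintf("%s_rd%06d", line, seq_len(n_pairs))
    tb <- tibble(
      read_id = c(paste0(pair_id, "/1"), paste0(pair_id, "/2")),
      line = line,
      pair = rep(pair_id, 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      seq = c(r1, r2),
      hap_start = c(s1, s2),
      strand = rep(c("+", "-"), each = n_pairs),
      insert = rep(ins, 2L))
    tb$n_errors <- stats::rbinom(nrow(tb), rl, config$error_rate)
    err <- which(tb$n_errors > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in err) {
      s <- tb$seq[[i]]
      at <- sample.int(rl, tb$n_errors[[i]])
      for (p in at) {
        substr(s, p, p) <- sample(setdiff(bases, substr(s, p, p)), 1L)
      }
      tb$seq[[i]] <- s
    }
    tb
  })
}
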