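#' Build the two haplotype transcriptomes of a cross
#'
#' Applies each parent's variants to the reference, lifts the exon
#' coordinates through the indel shifts, and splices the exon sequences per
#' haplotype (reverse-complemented for minus-strand transcripts).
#'
#' @param genome Reference sequence.
#' @param variants_a,variants_b Variant tibbles (`pos`, `ref`, `alt`, `nd`,
#'   `ni`) for the two haplotypes; each set must be internally non-conflicting.
#' @param transcripts Transcript tibble.
#' @return Tibble: `transcript_id`, `hap` (`"a"`/`"b"`), `seq`.
#' @export
build_haplotype_transcriptomes <- function(genome, variants_a, variants_b,
                                           transcripts) {
  one <- function(vars, hap) {
    hseq <- apply_variants(genome, vars)
    rows <- lapply(seq_len(nrow(transcripts)), function(i) {
      tx <- transcripts[i, ]
      ex <- tx$exons[[1]]
      hs <- lift_to_hap(vars, ex$start)
      he <- lift_to_hap(vars, ex$end)
      # exon boundaries deleted on this haplotype: clamp to the nearest
      # surviving base inside the exon
      for (j in seq_along(hs)) {
        if (is.na(hs[[j]])) hs[[j]] <- lift_first_alive(vars, ex$start[[j]], +1L)
        if (is.na(he[[j]])) he[[j]] <- lift_first_alive(vars, ex$end[[j]], -1L)
      }
      parts <- substring(hseq, hs, he)
      sq <- if (tx$strand == "+") paste(parts, collapse = "")
            else paste(revcomp(parts), collapse = "")
      tibble(transcript_id = tx$transcript_id, hap = hap, seq = sq)
    })
    bind_rows(rows)
  }
  bind_rows(one(variants_a, "a"), one(variants_b, "b"))
}

# First reference position at or beyond `gpos` (direction +1) or at or before
# it (direction -1) that survives on the haplotype, lifted.
lift_first_alive <- function(vars, gpos, dir) {
  for (step in 0:200) {
    p <- gpos + dir * step
    h <- lift_to_hap(vars, p)
    if (!is.na(h)) return(h)
  }
  abort("no surviving base near the exon boundary")
}

#' Assign reads to parental alleles via dual-transcriptome alignment
#'
#' Each read is aligned (gapless, minimum Hamming distance over all offsets of
#' all transcripts) to both haplotype transcriptomes. Reads placeable at more
#' than one genomic location are discarded; reads aligning to both haplotypes
#' with equal mismatch counts are uninformative; otherwise the read supports
#' the haplotype with fewer mismatches, and reads aligning to only one
#' haplotype support that one.
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param transcriptomes Output of [build_haplotype_transcriptomes()].
#' @param genome Optional reference sequence; when supplied, reads whose
#'   genomic placement is ambiguous ([place_reads()]) are discarded.
#' @param cap Mismatch cap (default 10% of read length).
#' @return Tibble: `read_id`, `assignment` (`allele_a` / `allele_b` /
#'   `uninformative` / `discarded`), `transcript_id` of the best alignment
#'   (NA when unaligned), `mm_a`, `mm_b`.
#' @export
assign_reads <- function(reads, transcriptomes, genome = NULL, cap = NULL) {
  cap <- cap %||% ceiling(0.1 * max(nchar(reads$seq)))
  discarded <- rep(FALSE, nrow(reads))
  if (!is.null(genome)) {
    pl <- place_reads(reads, genome, cap = cap)
    discarded <- pl$status == "ambiguous"
  }
  best_in <- function(seqs, hap) {
    tt <- transcriptomes[transcriptomes$hap == hap, ]
    subj <- lapply(tt$seq, Biostrings::DNAString)
    t(vapply(seqs, function(s) {
      for (ori in c(s, revcomp(s))) {
        r <- Biostrings::DNAString(ori)
        rl <- length(r)
        bmm <- Inf; btx <- NA_character_
        for (j in seq_along(subj)) {
          cl <- length(subj[[j]])
          if (cl < rl) next
          ed <- min(Biostrings::neditStartingAt(r, subj[[j]],
                                                starting.at = 1:(cl - rl + 1L)))
          if (ed < bmm) { bmm <- ed; btx <- tt$transcript_id[[j]] }
        }
        if (bmm <= cap) return(c(mm = bmm, tx = match(btx, tt$transcript_id)))
      }
      c(mm = Inf, tx = NA_real_)
    }, c(mm = 0, tx = 0)))
  }
  ba <- best_in(reads$seq, "a")
  bb <- best_in(reads$seq, "b")
  tx_a <- transcriptomes$transcript_id[transcriptomes$hap == "a"][ba[, "tx"]]
  tx_b <- transcriptomes$transcript_id[transcriptomes$hap == "b"][bb[, "tx"]]
  assignment <- dplyr::case_when(
    discarded ~ "discarded",
    is.infinite(ba[, "mm"]) & is.infinite(bb[, "mm"]) ~ "uninformative",
    is.infinite(bb[, "mm"]) ~ "allele_a",
    is.infinite(ba[, "mm"]) ~ "allele_b",
    ba[, "mm"] < bb[, "mm"] ~ "allele_a",
    bb[, "mm"] < ba[, "mm"] ~ "allele_b",
    TRUE ~ "uninformative")
  tibble(read_id = reads$read_id, assignment = assignment,
         transcript_id = ifelse(assignment == "allele_b", tx_b, tx_a),
         mm_a = as.numeric(ba[, "mm"]), mm_b = as.numeric(bb[, "mm"]))
}

#' Two-sided exact binomial test for allelic imbalance
#'
#' Tests the allele1 count against a symmetric binomial (p = 0.5). The
#' two-sided p-value is `min(1, 2 x smaller tail)`, which for p = 0.5
#' coincides with the conventional exact test. Transcripts with fewer than
#' `min_reads` informative reads are not tested (NA).
#'
#' @param allele1,allele2 Informative read counts (vectors).
#' @param min_reads Minimum total informative reads (default 20).
#' @return Vector of p-values (NA where untested).
#' @export
ase_test <- function(allele1, allele2, min_reads = 20L) {
  n <- allele1 + allele2
  k <- pmin(allele1, allele2)
  p <- pmin(1, 2 * stats::pbinom(k, n, 0.5))
  # when allele1 = allele2 the two tails overlap at the centre: p = 1
  p[allele1 == allele2 & n > 0] <- 1
  p[n < min_reads] <- NA_real_
  p
}

#' Test allelic imbalance in both reciprocal crosses and combine
#'
#' Runs [ase_test()] per cross on transcripts with at least `min_reads`
#' informative reads, adjusts with Benjamini-Hochberg within cross, and
#' reports a transcript as significantly imbalanced only when it passes the
#' FDR threshold in both the initial and the reciprocal cross (counts are
#' never pooled across crosses).
#'
#' @param counts Tibble from [sim_f1_counts()] or equivalent:
#'   `transcript_id`, `cross`, `allele1`, `allele2`.
#' @param fdr FDR level (default 0.10).
#' @param min_reads Minimum informative reads per cross.
#' @return Object of class `ase_result`: list with `records` (per transcript
#'   and cross: counts, `p`, `q`, `tested`), `significant` (transcript ids
#'   significant in both crosses), `concordance` (Spearman correlation of
#'   log2 allele ratios between crosses, a QC report, not a gate).
#' @export
combine_crosses <- function(counts, fdr = 0.10, min_reads = 20L) {
  rec <- counts |>
    mutate(p = ase_test(.data$allele1, .data$allele2, min_reads = min_reads),
           tested = !is.na(.data$p)) |>
    group_by(.data$cross) |>
    mutate(q = {
      q <- rep(NA_real_, dplyr::n())
      q[.data$tested] <- bh_adjust(.data$p[.data$tested])
      q
    }) |>
    ungroup()
  crosses <- unique(rec$cross)
  if (length(crosses) != 2L) abort("expected exactly two crosses")
  sig_by <- lapply(crosses, function(cr) {
    rec$transcript_id[rec$cross == cr & rec$tested & !is.na(rec$q) &
                        rec$q <= fdr]
  })
  ratios <- rec |>
    filter(.data$tested) |>
    mutate(ratio = log2((.data$allele1 + 0.5) / (.data$allele2 + 0.5))) |>
    select("transcript_id", "cross", "ratio") |>
    tidyr::pivot_wider(names_from = "cross", values_from = "ratio") |>
    tidyr::drop_na()
  conc <- if (nrow(ratios) >= 3L) {
    stats::cor(ratios[[2]], ratios[[3]], method = "spearman")
  } else NA_real_
  structure(list(records = rec,
                 significant = intersect(sig_by[[1]], sig_by[[2]]),
                 concordance = conc, fdr = fdr, min_reads = min_reads),
            class = "ase_result")
}

#' @export
print.ase_result <- function(x, ...) {
  n_tested <- length(unique(x$records$transcript_id[x$records$tested]))
  cat("<ase_result>", n_tested, "transcripts tested;",
      length(x$significant), "imbalanced in both crosses at",
      sprintf("%.0f%% FDR\n", 100 * x$fdr))
  cat(sprintf("  reciprocal-cross concordance (Spearman): %.3f\n", x$concordance))
  invisible(x)
}

#' Validate variant calls from parental RNA-seq allele support
#'
#' A variant is a true positive when all aligned reads support it over the
#' reference, or when read support for it is significant (two-tailed binomial
#' p < 0.05); a false positive when all reads support the reference or
#' reference support is significant; otherwise unresolved (low coverage).
#'
#' @param support Tibble with `variant_reads` and `reference_reads` per
#'   variant (extra columns pass through).
#' @param alpha Binomial significance level.
#' @return Input with `p` and `verdict` (`TP` / `FP` / `unresolved`) added.
#' @export
validate_variants <- function(support, alpha = 0.05) {
  v <- support$variant_reads; r <- support$reference_reads
  n <- v + r
  p <- pmin(1, 2 * stats::pbinom(pmin(v, r), n, 0.5))
  p[v == r & n > 0] <- 1
  verdict <- dplyr::case_when(
    n == 0 ~ "unresolved",
    r == 0 ~ "TP",
    v == 0 ~ "FP",
    p < alpha & v > r ~ "TP",
    p < alpha & r > v ~ "FP",
    TRUE ~ "unresolved")
  support$p <- ifelse(n > 0, p, NA_real_)
  support$verdict <- verdict
  support
}

#' F1 validation rate of cis-eQTLs by effect-size cutoff
#'
#' For each effect cutoff, the fraction of eligible eQTL transcripts (those
#' whose parental lines carry different alleles) with effect at or above the
#' cutoff that show significant allelic imbalance; the empirical p-value per
#' cutoff counts how many of `n_perm` random transcript sets of the same size,
#' drawn from all tested eQTL transcripts, validate at least as well.
#'
#' @param eqtl_transcripts Tibble with `transcript_id` and `effect_log2` for
#'   eligible eQTL transcripts.
#' @param tested_transcripts Character vector of all transcripts tested for
#'   ASE (the sampling pool).
#' @param ase_significant Character vector of ASE-significant transcripts.
#' @param effect_cutoffs Numeric cutoffs in log2 units (default 1, log2(3),
#'   2: two-, three-, four-fold).
#' @param n_perm Number of random sets (default 1000).
#' @param seed Seed for the sampling stream.
#' @return Tibble: `cutoff`, `n_transcripts`, `validated_fraction`,
#'   `empirical_p`.
#' @export
eqtl_validation_rate <- function(eqtl_transcripts, tested_transcripts,
                                 ase_significant,
                                 effect_cutoffs = c(1, log2(3), 2),
                                 n_perm = 1000L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    rows <- lapply(effect_cutoffs, function(co) {
      set <- unique(eqtl_transcripts$transcript_id[
        eqtl_transcripts$effect_log2 >= co])
      if (!length(set)) {
        return(tibble(cutoff = co, n_transcripts = 0L,
                      validated_fraction = NA_real_, empirical_p = NA_real_))
      }
      real <- mean(set %in% ase_significant)
      rand <- vapply(seq_len(n_perm), function(b) {
        mean(sample(tested_transcripts, length(set)) %in% ase_significant)
      }, numeric(1))
      tibble(cutoff = co, n_transcripts = length(set),
             validated_fraction = real,
             empirical_p = mean(rand >= real))
    })
    bind_rows(rows)
  })
}
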