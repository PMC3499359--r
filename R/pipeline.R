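#' Run the full synthetic pipeline
#'
#' Chains every stage on synthetic data: genome and transcript simulation,
#' variant planting, haplotype reconstruction, read simulation and vote-based
#' genotyping for a subset of lines, variant classification and
#' genomic-context summaries, expression simulation and cis-eQTL mapping,
#' F1 count simulation and allelic-imbalance analysis, and the eQTL-vs-ASE
#' validation-rate comparison. Returns a report object; optionally writes
#' every artifact in its standard format.
#'
#' @param config A [sim_config()].
#' @param eqtl An [eqtl_config()]; defaults to 200 permutations seeded from
#'   `config$seed`.
#' @param genotype_lines Number of lines to genotype from simulated reads
#'   (read simulation dominates run time; two lines demonstrate the stage).
#' @param outdir Optional directory for FASTA/FASTQ/VCF/GFF3/TSV/JSON output.
#' @return A `varcis_report` list: per-stage result objects plus a manifest
#'   of stage digests.
#' @export
run_pipeline <- function(config, eqtl = NULL, genotype_lines = 2L,
                         outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  eqtl <- eqtl %||% eqtl_config(seed = config$seed, n_perm = 200L)
  genome0 <- sim_genome(config)
  txr <- sim_transcripts(genome0, config)
  genome <- txr$genome
  transcripts <- txr$transcripts
  panel <- sim_variants(genome, config)
  panel <- normalize_variants(panel, genome)
  panel <- classify_variants(panel, genome)
  haps <- build_haplotypes(genome, panel)

  # genotyping on a subset of lines
  gl <- seq_len(min(genotype_lines, config$n_lines))
  cand <- candidate_sites(panel, genome)
  geno <- lapply(gl, function(l) {
    reads <- sim_reads(haps[[l]], config, line = paste0("line_", l))
    calls <- genotype_line(reads, genome, cand)
    calls$line <- l
    calls$true_allele <- cand$line_allele[match(calls$site_id, cand$site_id)] |>
      vapply(function(z) z[[l]], integer(1))
    calls
  })
  geno <- bind_rows(geno)
  alt_calls <- geno[geno$allele != "0", ]
  is_true <- alt_calls$allele == as.character(alt_calls$true_allele)
  recall <- mean(alt_calls$called[is_true])
  false_calls <- sum(alt_calls$called[!is_true])

  spectrum <- variant_spectrum(panel)
  sites <- group_alleles(panel, transcripts)
  expr <- sim_expression(panel, transcripts, config, sites = sites)
  keep <- expressed_filter(expr$expression)
  variable <- genetic_variance_filter(expr$expression)
  fit <- map_cis_eqtl(expr$expression, sites, eqtl,
                      transcript_ids = keep$transcript_id[keep$retained])

  f1 <- sim_f1_counts(panel, transcripts, config)
  ase <- combine_crosses(f1$counts)
  sig_rows <- fit$results |>
    filter(.data$method == "allele", !is.na(.data$significant),
           .data$significant, !is.na(.data$effect_log2))
  eligible <- if (nrow(sig_rows)) {
    sig_rows |>
      group_by(.data$transcript_id) |>
      summarise(effect_log2 = max(.data$effect_log2))
  } else sig_rows[, c("transcript_id", "effect_log2")]
  tested_pool <- unique(ase$records$transcript_id[ase$records$tested])
  validation <- if (nrow(eligible) > 0 && length(tested_pool) > 0) {
    eqtl_validation_rate(eligible, tested_pool, ase$significant,
                         seed = substream_seed(config$seed, "validation"))
  } else NULL

  manifest <- tibble(
    stage = c("genome", "transcripts", "panel", "haplotypes", "genotyping",
              "expression", "eqtl", "ase"),
    digest = vapply(list(genome, transcripts, panel, haps, geno,
                         expr$expression, fit$results, ase$records),
                    rlang::hash, character(1)))
  report <- structure(list(
    config = config, genome = genome, transcripts = transcripts,
    panel = panel, haplotypes = haps, genotyping = geno,
    genotyper_recall = recall, genotyper_false_calls = false_calls,
    spectrum = spectrum, sites = sites, expression = expr,
    expressed = keep, variable = variable, eqtl = fit,
    f1 = f1, ase = ase, validation = validation, manifest = manifest),
    class = "varcis_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.varcis_report <- function(x, ...) {
  cat("== varcis pipeline report (seed", x$config$seed, ") ==\n")
  cat("genome:", nchar(x$genome), "bp;", nrow(x$transcripts), "transcripts;",
      nrow(x$panel), "planted variants\n")
  cat("variant classes:\n")
  print(table(x$panel$top_level))
  cat(sprintf("genotyper: recall %.3f, false calls %d (on %d lines)\n",
              x$genotyper_recall, x$genotyper_false_calls,
              length(unique(x$genotyping$line))))
  cat(sprintf("expressed filter kept %d/%d transcripts\n",
              sum(x$expressed$retained), nrow(x$expressed)))
  print(x$eqtl)
  print(x$ase)
  if (!is.null(x$validation)) {
    cat("eQTL validation by effect cutoff:\n")
    print(x$validation)
  }
  invisible(x)
}

# Write every pipeline artifact in its standard on-disk format.
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_fasta(stats::setNames(as.character(report$genome),
                              attr(report$genome, "contig")), p("genome.fa"))
  write_fasta(report$haplotypes, p("haplotypes.fa"))
  write_vcf(report$panel, report$genome, p("panel.vcf"))
  if (requireNamespace("rtracklayer", quietly = TRUE) &&
      requireNamespace("GenomicRanges", quietly = TRUE)) {
    write_gff3(report$transcripts, p("transcripts.gff3"))
  }
  write_expression(report$expression$expression, p("expression.tsv"))
  readr::write_tsv(report$f1$counts, p("f1_counts.tsv"))
  readr::write_tsv(tidy(report$eqtl), p("eqtl_results.tsv"))
  readr::write_tsv(report$ase$records, p("ase_records.tsv"))
  write_truth_json(list(variants = report$panel[, c("variant_id", "pos", "ref",
                                                    "alt", "carriers")],
                        eqtls = report$expression$truth,
                        imbalance = report$f1$truth),
                   p("truth.json"))
  readr::write_tsv(report$manifest, p("manifest.tsv"))
  invisible(outdir)
}
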