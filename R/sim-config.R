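#' Simulation configuration
#'
#' Bundles every tunable parameter of the synthetic-data generator into one
#' validated object. The defaults describe the study design the package is
#' built around: a panel of 39 fully inbred (homozygous) lines, short
#' paired-end reads at 20-fold coverage, microarray-style log2 expression for
#' both sexes in two replicates, and F1 hybrid allele-specific counts with a
#' mean depth of 200 informative reads per transcript.
#'
#' @param seed Integer root seed. Mandatory: every stage derives a named
#'   substream from it, so there is no implicit entropy anywhere.
#' @param genome_length Reference contig length in bp.
#' @param gc_fraction GC content of the simulated reference, in `[0, 1]`.
#' @param n_lines Number of inbred lines in the panel (>= 4).
#' @param variant_rates Named per-bp densities of unique planted variants, with
#'   names among `snp`, `ins`, `del`, `mns`, `complex`. Defaults mirror the
#'   relative abundances of SNPs, indels and complex variants seen in dense
#'   natural fly panels, scaled to desk size.
#' @param afs_model Allele-frequency model for carrier counts:
#'   `"neutral_folded"` draws derived-allele counts from the standard neutral
#'   spectrum (P(i) proportional to 1/i, i = 1..n-1), whose folded form is the
#'   analytic expectation used by [variant_spectrum()]; `"fixed_counts"` gives
#'   every variant exactly `fixed_count` carrier lines.
#' @param fixed_count Carrier count used when `afs_model = "fixed_counts"`.
#' @param multiallelic_rate Fraction of multi-bp deletions that receive a
#'   second, overlapping allele (a SNP inside the deleted span carried by other
#'   lines), creating multi-allelic sites.
#' @param min_spacing Minimum gap in bp between planted variants (>= 1 keeps
#'   them non-overlapping, which keeps the planted truth unambiguous).
#' @param margin Variant-free zone at each contig end, bp.
#' @param read_length,insert_mean,insert_sd,coverage,error_rate Read simulator:
#'   read length (bp), insert size mean and sd (bp), fold coverage, and i.i.d.
#'   per-base error rate.
#' @param n_transcripts Number of transcripts to place.
#' @param eqtl_fraction Fraction of transcripts that receive a planted cis
#'   effect.
#' @param effect_size Planted allelic effect in log2 units; a vector is
#'   sampled from uniformly per planted eQTL (mixed effect strengths).
#' @param sex_specific_fraction Fraction of planted effects that act in one sex
#'   only (split evenly between males and females).
#' @param replicates Expression replicates per line and sex (>= 2).
#' @param residual_sd,line_sd Residual and line-effect standard deviations of
#'   the expression model, log2 units.
#' @param baseline_mean,baseline_sd Distribution of per-transcript baseline
#'   expression, log2 units.
#' @param f1_depth Mean number of informative reads per transcript and cross in
#'   the F1 count model (Poisson).
#' @param imbalance_fraction Fraction of informative transcripts with planted
#'   allelic imbalance.
#' @param imbalance_fold Planted allelic fold change (allele1/allele2 > 0).
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 20000, n_lines = 8)
#' cfg$n_lines
sim_config <- function(seed,
                       genome_length = 1e5,
                       gc_fraction = 0.42,
                       n_lines = 39,
                       variant_rates = c(snp = 2.3e-3, ins = 2.2e-4,
                                         del = 2.2e-4, mns = 1.3e-4,
                                         complex = 5e-5),
                       afs_model = c("neutral_folded", "fixed_counts"),
                       fixed_count = 1L,
                       multiallelic_rate = 0.05,
                       min_spacing = 2L,
                       margin = 200L,
                       read_length = 100L,
                       insert_mean = 300,
                       insert_sd = 30,
                       coverage = 20,
                       error_rate = 0.01,
                       n_transcripts = 20L,
                       eqtl_fraction = 0.3,
                       effect_size = 1.0,
                       sex_specific_fraction = 0.5,
                       replicates = 2L,
                       residual_sd = 0.25,
                       line_sd = 0.25,
                       baseline_mean = 8,
                       baseline_sd = 1,
                       f1_depth = 200,
                       imbalance_fraction = 0.2,
                       imbalance_fold = 1.5) {
  if (missing(seed)) abort("`seed` is mandatory: no implicit entropy")
  afs_model <- match.arg(afs_model)
  props <- c(gc_fraction = gc_fraction, multiallelic_rate = multiallelic_rate,
             eqtl_fraction = eqtl_fraction,
             sex_specific_fraction = sex_specific_fraction,
             imbalance_fraction = imbalance_fraction)
  bad <- props[props < 0 | props > 1]
  if (length(bad)) {
    abort(paste0("proportions must lie in [0,1]: ",
                 paste(names(bad), collapse = ", ")))
  }
  if (n_lines < 4) abort("`n_lines` must be >= 4")
  if (replicates < 2) abort("`replicates` must be >= 2")
  if (any(variant_rates < 0)) abort("variant rates must be non-negative")
  unknown <- setdiff(names(variant_rates),
                     c("snp", "ins", "del", "mns", "complex"))
  if (length(unknown)) {
    abort(paste0("unknown variant rate name(s): ",
                 paste(unknown, collapse = ", ")))
  }
  structure(list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    gc_fraction = gc_fraction,
    n_lines = as.integer(n_lines),
    variant_rates = variant_rates,
    afs_model = afs_model,
    fixed_count = as.integer(fixed_count),
    multiallelic_rate = multiallelic_rate,
    min_spacing = as.integer(min_spacing),
    margin = as.integer(margin),
    read_length = as.integer(read_length),
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    coverage = coverage,
    error_rate = error_rate,
    n_transcripts = as.integer(n_transcripts),
    eqtl_fraction = eqtl_fraction,
    effect_size = effect_size,
    sex_specific_fraction = sex_specific_fraction,
    replicates = as.integer(replicates),
    residual_sd = residual_sd,
    line_sd = line_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    f1_depth = f1_depth,
    imbalance_fraction = imbalance_fraction,
    imbalance_fold = imbalance_fold
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " genome:", x$genome_length, "bp  lines:", x$n_lines, "\n")
  cat("  variant rates/bp:",
      paste(names(x$variant_rates), signif(x$variant_rates, 3),
            sep = "=", collapse = " "), "\n")
  cat("  afs:", x$afs_model, " reads:", x$read_length, "bp @", x$coverage,
      "x, err", x$error_rate, "\n")
  cat("  expression:", x$n_transcripts, "transcripts,",
      x$replicates, "replicates, effect", x$effect_size, "log2\n")
  invisible(x)
}
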