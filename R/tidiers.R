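#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cis-eQTL fit
#'
#' One row per tested (transcript, site, sex, method) with the raw p-value,
#' the transcript's adjusted threshold at the operating alpha, the
#' significance flag and the allelic effect size.
#'
#' @param x A `cis_eqtl_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cis_eqtl_fit <- function(x, ...) {
  x$results |>
    select("transcript_id", "site_id", "sex", "method", "raw_p",
           "adjusted_threshold", "significant", "effect_log2")
}

#' Summarise a cis-eQTL fit
#'
#' One row per sex and method: transcripts tested, transcripts and sites
#' significant at the operating point, and the operating alpha / estimated
#' FDR.
#'
#' @inheritParams tidy.cis_eqtl_fit
#' @return A tibble.
#' @export
glance.cis_eqtl_fit <- function(x, ...) {
  x$results |>
    group_by(.data$sex, .data$method) |>
    summarise(n_transcripts = dplyr::n_distinct(.data$transcript_id),
              n_sites_tested = dplyr::n(),
              n_significant_sites = sum(.data$significant),
              n_significant_transcripts =
                dplyr::n_distinct(.data$transcript_id[.data$significant]),
              .groups = "drop") |>
    left_join(x$operating, by = c("sex", "method"))
}

#' Tidy an ASE result
#'
#' @param x An `ase_result`.
#' @param ... Unused.
#' @return Per transcript and cross: counts, p, q, and whether the transcript
#'   is significant in both crosses.
#' @export
tidy.ase_result <- function(x, ...) {
  x$records |>
    mutate(significant_both = .data$transcript_id %in% x$significant)
}

#' Summarise an ASE result
#'
#' @inheritParams tidy.ase_result
#' @return One-row tibble: transcripts tested, significant in both crosses,
#'   FDR level, reciprocal-cross concordance.
#' @export
glance.ase_result <- function(x, ...) {
  tibble(n_tested = length(unique(x$records$transcript_id[x$records$tested])),
         n_significant = length(x$significant),
         fdr = x$fdr, min_reads = x$min_reads,
         concordance = x$concordance)
}
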