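#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_hline labs facet_wrap position_dodge scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a SNP-density profile around variant breakpoints
#'
#' Solid line: SNP density in lines carrying the focal variant; dashed line:
#' the same loci in lines without it.
#'
#' @param object A `density_profile` from [snp_density_around()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object)[, c("offset", "density",
                                                 "density_control")],
                           -"offset", names_to = "series")
  d$series <- ifelse(d$series == "density", "carrier lines", "control lines")
  ggplot(d, aes(x = .data$offset, y = .data$value, linetype = .data$series)) +
    geom_line() +
    labs(x = "offset from breakpoint (bp)", y = "SNPs per kb per line",
         linetype = NULL)
}

#' Plot a TSS/TES feature profile
#'
#' @param object A `feature_profile` from [feature_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$value)) +
    geom_point(na.rm = TRUE) +
    geom_line(na.rm = TRUE) +
    labs(x = sprintf("offset from %s (bp, transcription rightward)",
                     attr(object, "anchor")),
         y = attr(object, "value_label"))
}

#' Plot an allele-frequency spectrum against the neutral expectation
#'
#' @param object A `variant_spectrum` from [variant_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variant_spectrum <- function(object, ...) {
  d <- as_tibble(object) |> filter(.data$minor_count > 0)
  ggplot(d, aes(x = .data$minor_count)) +
    geom_col(aes(y = .data$observed), fill = "grey40") +
    geom_line(aes(y = .data$expected), colour = "red") +
    facet_wrap(~type, scales = "free_y") +
    labs(x = "minor allele count (lines)", y = "variants",
         caption = "red: folded neutral expectation")
}

#' Volcano-style overview of a cis-eQTL fit
#'
#' @param object A `cis_eqtl_fit`.
#' @param method Association method to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cis_eqtl_fit <- function(object, method = "allele", ...) {
  d <- object$results[object$results$method == method, ]
  ggplot(d, aes(x = .data$effect_log2, y = -log10(.data$raw_p),
                colour = .data$significant)) +
    geom_point(alpha = 0.6) +
    facet_wrap(~sex) +
    labs(x = "allelic effect (log2)", y = "-log10 raw p",
         colour = "significant")
}

#' Allelic-imbalance overview plot
#'
#' Log2 allele ratio against informative depth per cross, transcripts
#' significant in both crosses highlighted.
#'
#' @param object An `ase_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ase_result <- function(object, ...) {
  d <- tidy(object) |> filter(.data$tested)
  d$depth <- d$allele1 + d$allele2
  d$ratio <- log2((d$allele1 + 0.5) / (d$allele2 + 0.5))
  ggplot(d, aes(x = .data$depth, y = .data$ratio,
                colour = .data$significant_both)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_wrap(~cross) +
    labs(x = "informative reads", y = "log2(allele1/allele2)",
         colour = "imbalanced\n(both crosses)")
}

#' Coding indel size spectrum plot
#'
#' @param object A `frame_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frame_spectrum <- function(object, ...) {
  d <- object$sizes
  d$frame <- ifelse(d$size %% 3 == 0, "multiple of 3", "frameshift")
  ggplot(d, aes(x = .data$size, y = .data$n, fill = .data$frame)) +
    geom_col(position = position_dodge(preserve = "single")) +
    facet_wrap(~class) +
    labs(x = "indel size (bp)", y = "coding indels", fill = NULL)
}
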