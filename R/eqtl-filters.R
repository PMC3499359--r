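#' Filter probe sets by variant overlap
#'
#' Probes overlapping any sequence variant are removed (their hybridisation
#' signal is confounded by the variant itself); probe sets left with fewer
#' than `min_probes` probes are dropped entirely.
#'
#' @param probes Tibble with `probe_set`, `probe_id`, `start`, `end`
#'   (1-based inclusive genomic probe coordinates).
#' @param panel A `variant_panel`.
#' @param min_probes Minimum surviving probes per retained set.
#' @return Tibble: `probe_set`, `n_probes`, `n_surviving`, `retained`.
#' @export
filter_probesets <- function(probes, panel, min_probes = 3L) {
  vs <- ifelse(panel$nd > 0L, panel$pos, panel$pos - 1L)
  ve <- ifelse(panel$nd > 0L, panel$pos + panel$nd - 1L, panel$pos)
  hit <- vapply(seq_len(nrow(probes)), function(i) {
    any(probes$start[[i]] <= ve & probes$end[[i]] >= vs)
  }, logical(1))
  probes |>
    mutate(overlaps = hit) |>
    group_by(.data$probe_set) |>
    summarise(n_probes = dplyr::n(),
              n_surviving = sum(!.data$overlaps)) |>
    mutate(retained = .data$n_surviving >= min_probes)
}

#' Expression presence filter
#'
#' A line expresses a transcript when, in at least one sex, the transcript is
#' detected in every replicate; transcripts expressed in fewer than
#' `min_lines` lines are dropped. Detection flags come from upstream
#' presence/absence calling and arrive with the expression table.
#'
#' @param expression Long expression tibble with a logical `detected` column.
#' @param min_lines Minimum number of expressing lines (default 4).
#' @return Tibble: `transcript_id`, `n_expressing`, `retained`.
#' @export
expressed_filter <- function(expression, min_lines = 4L) {
  if (is.null(expression$detected) || anyNA(expression$detected)) {
    abort("`detected` flags are required for every replicate")
  }
  expression |>
    group_by(.data$transcript_id, .data$line, .data$sex) |>
    summarise(sex_ok = all(.data$detected), .groups = "drop") |>
    group_by(.data$transcript_id, .data$line) |>
    summarise(expressing = any(.data$sex_ok), .groups = "drop") |>
    group_by(.data$transcript_id) |>
    summarise(n_expressing = sum(.data$expressing)) |>
    mutate(retained = .data$n_expressing >= min_lines)
}

#' Genetic-variance filter
#'
#' One-way fixed-effect ANOVA of the line term per transcript and sex,
#' Benjamini-Hochberg corrected across transcripts within sex; transcripts
#' with adjusted p at or below `fdr` are genetically variable. Transcripts
#' with zero residual variance are flagged and not tested.
#'
#' @param expression Long expression tibble (needs >= 2 replicates per line).
#' @param fdr FDR level (default the conservative 0.001).
#' @return Tibble: `transcript_id`, `sex`, `p`, `q`, `tested`, `variable`.
#' @export
genetic_variance_filter <- function(expression, fdr = 0.001) {
  reps <- expression |>
    count(.data$transcript_id, .data$sex, .data$line)
  if (any(reps$n < 2L)) abort("need at least 2 replicates per line and sex")
  combos <- distinct(expression, .data$transcript_id, .data$sex)
  res <- purrr::pmap(combos, function(transcript_id, sex) {
    d <- expression[expression$transcript_id == transcript_id &
                      expression$sex == sex, ]
    within_var <- d |>
      group_by(.data$line) |>
      summarise(v = stats::var(.data$value)) |>
      pull(.data$v)
    if (all(within_var == 0)) {
      return(tibble(transcript_id = transcript_id, sex = sex,
                    p = NA_real_, tested = FALSE))
    }
    fit <- stats::aov(value ~ factor(line), data = d)
    p <- summary(fit)[[1]][["Pr(>F)"]][[1]]
    tibble(transcript_id = transcript_id, sex = sex, p = p, tested = TRUE)
  }) |> bind_rows()
  res |>
    group_by(.data$sex) |>
    mutate(q = {
      q <- rep(NA_real_, dplyr::n())
      q[.data$tested] <- bh_adjust(.data$p[.data$tested])
      q
    }) |>
    ungroup() |>
    mutate(variable = .data$tested & .data$q <= fdr)
}
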