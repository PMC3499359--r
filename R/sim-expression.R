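#' Simulate a log2 expression matrix with planted cis effects
#'
#' Expression for each transcript, line, sex and replicate is
#' `baseline + line effect + planted allelic effect + residual noise`, all in
#' log2 units. Planted effects shift the lines carrying a non-reference allele
#' at one testable site within 10 kb of the transcript, in the effect's sex
#' scope only. Two replicates per line and sex are generated by default.
#'
#' @param panel A `variant_panel`.
#' @param transcripts Transcript tibble from [sim_transcripts()].
#' @param config A [sim_config()].
#' @param sites Optional precomputed [group_alleles()] result (recomputed when
#'   omitted).
#' @return List with `expression` (tibble: `transcript_id`, `line`, `sex`
#'   ("M"/"F"), `replicate`, `value`, `detected`) and `truth` (tibble of
#'   planted effects: `transcript_id`, `site_id`, `scope`, `effect`,
#'   `carrier_lines` list-column).
#' @export
sim_expression <- function(panel, transcripts, config, sites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_lines <- attr(panel, "n_lines")
  sites <- sites %||% group_alleles(panel, transcripts)
  with_substream(config$seed, "expression", code = {
    n_eqtl <- round(config$eqtl_fraction * nrow(transcripts))
    pairs <- sites$pairs
    testable_ids <- sites$sites$site_id[sites$sites$testable]
    pairs <- pairs[pairs$site_id %in% testable_ids, ]
    eligible_tx <- intersect(transcripts$transcript_id, unique(pairs$transcript_id))
    if (n_eqtl > length(eligible_tx)) {
      warn(sprintf("only %d transcripts have a testable site within 10 kb; planting %d effects",
                   length(eligible_tx), length(eligible_tx)))
      n_eqtl <- length(eligible_tx)
    }
    chosen <- if (n_eqtl > 0L) sample(eligible_tx, n_eqtl) else character(0)
    truth <- lapply(chosen, function(tx) {
      cand <- pairs$site_id[pairs$transcript_id == tx]
      sid <- if (length(cand) == 1L) cand else sample(cand, 1L)
      srow <- sites$sites[sites$sites$site_id == sid, ]
      carrier <- which(srow$line_allele[[1]] != 0L)
      scope <- if (stats::runif(1) < config$sex_specific_fraction) {
        sample(c("M", "F"), 1L)
      } else "both"
      eff <- if (length(config$effect_size) > 1L) {
        sample(config$effect_size, 1L)
      } else config$effect_size
      tibble(transcript_id = tx, site_id = sid, scope = scope,
             effect = eff, carrier_lines = list(carrier))
    })
    truth <- if (length(truth)) bind_rows(truth) else
      tibble(transcript_id = character(), site_id = character(),
             scope = character(), effect = numeric(), carrier_lines = list())
    sexes <- c("M", "F")
    reps <- seq_len(config$replicates)
    grid <- tidyr::expand_grid(transcript_id = transcripts$transcript_id,
                               line = seq_len(n_lines), sex = sexes,
                               replicate = reps)
    base <- stats::setNames(stats::rnorm(nrow(transcripts), config$baseline_mean,
                                         config$baseline_sd),
                            transcripts$transcript_id)
    line_eff <- matrix(stats::rnorm(nrow(transcripts) * n_lines, 0, config$line_sd),
                       nrow = nrow(transcripts),
                       dimnames = list(transcripts$transcript_id, NULL))
    grid$value <- unname(base[grid$transcript_id]) +
      line_eff[cbind(match(grid$transcript_id, transcripts$transcript_id),
                     grid$line)] +
      stats::rnorm(nrow(grid), 0, config$residual_sd)
    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        hit <- grid$transcript_id == truth$transcript_id[[i]] &
          grid$line %in% truth$carrier_lines[[i]] &
          (truth$scope[[i]] == "both" | grid$sex == truth$scope[[i]])
        grid$value[hit] <- grid$value[hit] + truth$effect[[i]]
      }
    }
    grid$detected <- TRUE
    list(expression = grid, truth = truth)
  })
}

#' Simulate F1 allele-specific read counts
#'
#' For an initial and a reciprocal cross between two panel lines, draws
#' per-transcript informative read counts. A transcript is informative when
#' the two parents differ at at least one exonic variant; uninformative
#' transcripts emit zero reads. Depth is Poisson with mean `config$f1_depth`;
#' the count supporting parent A's allele is binomial with success probability
#' `fold / (1 + fold)`.
#'
#' @param panel A `variant_panel`.
#' @param transcripts Transcript tibble.
#' @param config A [sim_config()].
#' @param parents Integer vector of two line indices (parent A, parent B).
#' @param folds Optional named numeric vector of planted allele1/allele2 fold
#'   changes per transcript; defaults to `config$imbalance_fold` for a random
#'   `config$imbalance_fraction` of informative transcripts (direction chosen
#'   at random) and 1 elsewhere.
#' @return List with `counts` (tibble: `transcript_id`, `cross`, `allele1`,
#'   `allele2`) and `truth` (tibble: `transcript_id`, `informative`, `fold`).
#' @export
sim_f1_counts <- function(panel, transcripts, config,
                          parents = c(1L, 2L), folds = NULL) {
  stopifnot(inherits(config, "sim_config"), length(parents) == 2L)
  if (!is.null(folds) && any(folds <= 0)) abort("fold changes must be positive")
  info <- vapply(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    ex <- tx$exons[[1]]
    ov <- panel$pos <= max(ex$end) & (panel$pos + pmax(panel$nd, 1L) - 1L) >= min(ex$start)
    ov <- ov & vapply(seq_len(nrow(panel)), function(v) {
      any(panel$pos[[v]] <= ex$end &
            panel$pos[[v]] + max(panel$nd[[v]], 1L) - 1L >= ex$start)
    }, logical(1))
    any(ov & vapply(panel$carriers, function(cs) {
      xor(parents[[1]] %in% cs, parents[[2]] %in% cs)
    }, logical(1)))
  }, logical(1))
  with_substream(config$seed, "f1", paste(parents, collapse = "x"), code = {
    if (is.null(folds)) {
      folds <- stats::setNames(rep(1, nrow(transcripts)),
                               transcripts$transcript_id)
      inf_ids <- transcripts$transcript_id[info]
      n_imb <- round(config$imbalance_fraction * length(inf_ids))
      if (n_imb > 0L) {
        pick <- sample(inf_ids, n_imb)
        dir <- sample(c(1, -1), n_imb, replace = TRUE)
        folds[pick] <- ifelse(dir > 0, config$imbalance_fold,
                              1 / config$imbalance_fold)
      }
    } else {
      full <- stats::setNames(rep(1, nrow(transcripts)),
                              transcripts$transcript_id)
      full[names(folds)] <- folds
      folds <- full
    }
    counts <- lapply(c("initial", "reciprocal"), function(cross) {
      depth <- ifelse(info, stats::rpois(nrow(transcripts), config$f1_depth), 0L)
      f <- folds[transcripts$transcript_id]
      a1 <- stats::rbinom(nrow(transcripts), depth, f / (1 + f))
      tibble(transcript_id = transcripts$transcript_id, cross = cross,
             allele1 = a1, allele2 = depth - a1)
    })
    list(counts = bind_rows(counts),
         truth = tibble(transcript_id = transcripts$transcript_id,
                        informative = info,
                        fold = unname(folds[transcripts$transcript_id])))
  })
}
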