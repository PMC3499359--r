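#' Group overlapping variants into multi-allelic sites
#'
#' Overlapping variants across the panel are merged into sites whose alleles
#' are the distinct local haplotypes (combinations of member variants carried
#' by a line); the reference allele is the empty combination. Each allele
#' carries an alignment score, the maximum of its total inserted and total
#' deleted bases (0 for the reference). Alleles carried by fewer than
#' `min_lines` lines are excluded from testing (their lines are dropped); a
#' site is testable when at least two alleles remain. Sites are paired with
#' every transcript whose either end lies within `window` bp.
#'
#' @param panel A `variant_panel`.
#' @param transcripts Transcript tibble (may be empty; then no pairs).
#' @param window cis window in bp (default 10 kb).
#' @param min_lines Minimum carrier lines per tested allele.
#' @return List with `sites` (tibble: `site_id`, `contig`, `start`, `end`,
#'   `n_alleles`, `alleles` list-column (`allele_id`, `n_lines`, `score`,
#'   `included`), `line_allele` list-column (allele id per line, 0 =
#'   reference), `testable`) and `pairs` (tibble: `site_id`, `transcript_id`,
#'   `distance`).
#' @export
group_alleles <- function(panel, transcripts = NULL, window = 10000L,
                          min_lines = 3L) {
  n_lines <- attr(panel, "n_lines")
  if (nrow(panel) == 0L) {
    return(list(sites = tibble(), pairs = tibble()))
  }
  v <- panel[order(panel$pos), ]
  s <- v$pos
  e <- v$pos + pmax(v$nd, 1L) - 1L
  cluster <- integer(nrow(v))
  cur <- 1L; max_end <- e[[1]]; cluster[[1]] <- 1L
  for (i in seq_len(nrow(v))[-1]) {
    if (s[[i]] > max_end) {
      cur <- cur + 1L
      max_end <- e[[i]]
    } else {
      max_end <- max(max_end, e[[i]])
    }
    cluster[[i]] <- cur
  }
  carr <- carrier_matrix(v, n_lines)
  rows <- lapply(seq_len(cur), function(ci) {
    idx <- which(cluster == ci)
    sub <- carr[idx, , drop = FALSE]
    keys <- apply(sub, 2, function(z) paste(which(z), collapse = ","))
    ukeys <- setdiff(unique(keys), "")
    ukeys <- ukeys[order(nchar(ukeys), ukeys)]
    allele_of <- match(keys, ukeys, nomatch = 0L)  # 0 = reference
    members <- lapply(ukeys, function(kk) {
      v$variant_id[idx[as.integer(strsplit(kk, ",")[[1]])]]
    })
    score <- vapply(ukeys, function(kk) {
      mem <- idx[as.integer(strsplit(kk, ",")[[1]])]
      max(sum(v$ni[mem]), sum(v$nd[mem]))
    }, numeric(1))
    counts <- tabulate(allele_of + 1L, nbins = length(ukeys) + 1L)
    al <- tibble(allele_id = 0:length(ukeys),
                 n_lines = counts,
                 score = c(0, unname(score)),
                 members = c(list(character(0)), members))
    al$included <- al$n_lines >= min_lines
    tibble(contig = v$contig[[idx[[1]]]],
           start = min(v$pos[idx]),
           end = max(v$pos[idx] + pmax(v$nd[idx], 1L) - 1L),
           n_alleles = length(ukeys) + 1L,
           alleles = list(al),
           line_allele = list(allele_of),
           member_ids = list(v$variant_id[idx]),
           testable = sum(al$included) >= 2L)
  })
  sites <- bind_rows(rows)
  sites$site_id <- sprintf("site%05d", seq_len(nrow(sites)))
  sites <- select(sites, "site_id", everything())
  pairs <- tibble(site_id = character(), transcript_id = character(),
                  distance = numeric())
  if (!is.null(transcripts) && nrow(transcripts) > 0L) {
    pl <- lapply(seq_len(nrow(transcripts)), function(i) {
      tx <- transcripts[i, ]
      dpt <- function(p) pmax(0, pmax(sites$start - p, p - sites$end))
      d <- pmin(dpt(tx$start), dpt(tx$end))
      hit <- which(d <= window)
      if (!length(hit)) return(NULL)
      tibble(site_id = sites$site_id[hit], transcript_id = tx$transcript_id,
             distance = d[hit])
    })
    pairs <- bind_rows(pl)
  }
  list(sites = sites, pairs = pairs)
}

# Kruskal-Wallis chi-square p-values for many rankings at once.
# R: n x B matrix whose columns are midrank vectors of the same value multiset;
# g: integer group labels (length n). Tie correction follows the classical
# formula, computed once from the first column.
kw_pvals <- function(R, g) {
  n <- nrow(R)
  S <- rowsum(R, g)
  nk <- tabulate(match(g, sort(unique(g))))
  H <- 12 / (n * (n + 1)) * colSums(S^2 / nk) - 3 * (n + 1)
  t_ <- table(R[, 1])
  C <- 1 - sum(t_^3 - t_) / (n^3 - n)
  if (C <= 0) return(rep(1, ncol(R)))
  stats::pchisq(H / C, df = length(nk) - 1L, lower.tail = FALSE)
}

# Rank-regression p-values: Pearson correlation between a fixed rank vector x
# and each column of rank matrix R, tested with the slope t-test.
score_pvals <- function(x, R) {
  n <- length(x)
  if (stats::sd(x) == 0) abort("constant score vector: association undefined")
  r <- as.numeric(stats::cor(x, R))
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Allele association test
#'
#' Kruskal-Wallis test of line expression ranks grouped by site allele
#' (midranks for ties, classical tie correction, chi-square approximation
#' with groups - 1 degrees of freedom). Alleles excluded at [group_alleles()]
#' time are dropped together with their lines.
#'
#' @param site_row One-row tibble from `group_alleles()$sites`.
#' @param expr_by_line Numeric vector of (replicate-averaged) expression, one
#'   value per line, single sex.
#' @return Raw p-value.
#' @export
allele_association <- function(site_row, expr_by_line) {
  g <- site_row$line_allele[[1]]
  al <- site_row$alleles[[1]]
  keep <- g %in% al$allele_id[al$included]
  g <- g[keep]
  if (length(unique(g)) < 2L) abort("fewer than two allele groups after filtering")
  y <- expr_by_line[keep]
  kw_pvals(matrix(rank(y), ncol = 1), g)[[1]]
}

#' Alignment-score association test
#'
#' Linear regression between the rank of allele alignment scores (the maximum
#' of bases inserted and bases deleted, 0 for the reference allele) and the
#' rank of expression, tested by the slope t-test. This associates the size
#' of the variant with expression, which matters when more than two alleles
#' carry variants of different lengths.
#'
#' @inheritParams allele_association
#' @return Raw p-value.
#' @export
score_association <- function(site_row, expr_by_line) {
  g <- site_row$line_allele[[1]]
  al <- site_row$alleles[[1]]
  keep <- g %in% al$allele_id[al$included]
  g <- g[keep]
  sc <- al$score[match(g, al$allele_id)]
  if (length(unique(sc)) < 2L) abort("fewer than two distinct alignment scores")
  y <- expr_by_line[keep]
  score_pvals(rank(sc), matrix(rank(y), ncol = 1))[[1]]
}

#' Per-transcript adjusted significance threshold from permutation minima
#'
#' Given the vector of per-permutation minimum p-values over all tests of one
#' transcript, the adjusted threshold for a nominal level `alpha` is the
#' element at 1-based index `round(alpha * n_perm)` of the ascending-sorted
#' vector (with 10,000 permutations and nominal 0.05, the 500th element).
#'
#' @param minima Numeric vector of per-permutation minimum p-values.
#' @param alpha Nominal significance level.
#' @return Adjusted p-value threshold.
#' @export
adjusted_threshold <- function(minima, alpha) {
  idx <- round(alpha * length(minima))
  if (idx < 1L) abort("alpha * n_perm < 1: no threshold index exists")
  sort(minima)[idx]
}

#' Expected-over-observed FDR estimate over a nominal-alpha grid
#'
#' The FDR at nominal level alpha is the number of transcripts expected to
#' pass their adjusted threshold by chance (`alpha * n_tested`) divided by the
#' number actually passing. The operating point is the largest grid alpha
#' whose FDR does not exceed `target`.
#'
#' @param pass_table Tibble with columns `alpha` and `n_passing`, plus the
#'   total `n_tested`.
#' @param n_tested Number of transcripts tested.
#' @param target FDR target (default 0.10).
#' @return Tibble `alpha`, `n_passing`, `fdr`, `operating` (logical marking
#'   the chosen alpha; all FALSE when no grid point qualifies).
#' @export
estimate_fdr <- function(pass_table, n_tested, target = 0.10) {
  out <- pass_table
  out$fdr <- ifelse(out$n_passing > 0, out$alpha * n_tested / out$n_passing,
                    NA_real_)
  ok <- which(!is.na(out$fdr) & out$fdr <= target)
  out$operating <- FALSE
  if (length(ok)) out$operating[ok[which.max(out$alpha[ok])]] <- TRUE
  out
}

#' Allelic effect size of a site on expression
#'
#' Maximum absolute difference in mean (replicate-averaged) log2 expression
#' between any two tested allele groups; 1.0 means a two-fold effect.
#'
#' @inheritParams allele_association
#' @return Effect in log2 units (>= 0).
#' @export
effect_size <- function(site_row, expr_by_line) {
  g <- site_row$line_allele[[1]]
  al <- site_row$alleles[[1]]
  keep <- g %in% al$allele_id[al$included]
  mns <- tapply(expr_by_line[keep], g[keep], mean)
  if (length(mns) < 2L) abort("fewer than two allele groups")
  max(stats::dist(matrix(mns, ncol = 1)))
}

#' Configuration of the cis-eQTL scan
#'
#' @param seed Seed for the permutation streams (one substream per transcript
#'   and sex, applied jointly to all sites of the transcript so linkage
#'   between sites is preserved).
#' @param n_perm Number of permutations of line labels (>= 100).
#' @param alpha_grid Nominal significance grid; every value must satisfy
#'   `round(alpha * n_perm) >= 1`.
#' @param fdr_target Target false discovery rate for the operating point.
#' @param methods Association methods to run: `"allele"` (Kruskal-Wallis) and
#'   or `"score"` (rank regression on alignment scores). Methods are
#'   permutation-corrected independently.
#' @return List of class `eqtl_config`.
#' @export
eqtl_config <- function(seed, n_perm = 1000L,
                        alpha_grid = c(0.001, 0.0025, 0.005, 0.01, 0.025,
                                       0.05, 0.1),
                        fdr_target = 0.10,
                        methods = c("allele", "score")) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (n_perm < 100L) abort("n_perm must be at least 100")
  if (any(alpha_grid <= 0 | alpha_grid >= 1)) abort("alpha grid must lie in (0,1)")
  feasible <- round(alpha_grid * n_perm) >= 1
  if (!any(feasible)) abort("no alpha in the grid satisfies round(alpha * n_perm) >= 1")
  if (!all(feasible)) {
    warn(sprintf("dropping %d grid alpha(s) with round(alpha * n_perm) < 1",
                 sum(!feasible)))
    alpha_grid <- alpha_grid[feasible]
  }
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 alpha_grid = sort(alpha_grid), fdr_target = fdr_target,
                 methods = methods),
            class = "eqtl_config")
}

#' Map cis-eQTLs with permutation-based per-transcript thresholds
#'
#' For each transcript, sex and association method: every testable site within
#' the cis window is tested; the same `n_perm` random permutations of line
#' labels are applied jointly to all sites of the transcript, the minimum
#' p-value per permutation forms the minima vector, and the adjusted
#' threshold at each nominal alpha is read from its sorted order statistics
#' ([adjusted_threshold()]). The operating alpha is chosen per sex and method
#' by the expected-over-observed FDR estimator ([estimate_fdr()]); a site is a
#' significant cis-eQTL when its raw p-value is at or below the transcript's
#' adjusted threshold at the operating alpha.
#'
#' @param expression Long expression tibble (`transcript_id`, `line`, `sex`,
#'   `replicate`, `value`); replicates are averaged per line and sex before
#'   ranking.
#' @param sites Result of [group_alleles()].
#' @param config An [eqtl_config()].
#' @param transcript_ids Optional subset of transcripts to scan.
#' @param sexes Sexes to analyse (default both present in the data).
#' @return Object of class `cis_eqtl_fit`; see [tidy.cis_eqtl_fit()] and
#'   [glance.cis_eqtl_fit()].
#' @export
map_cis_eqtl <- function(expression, sites, config,
                         transcript_ids = NULL, sexes = NULL) {
  stopifnot(inherits(config, "eqtl_config"))
  st <- sites$sites
  pairs <- sites$pairs
  testable <- st$site_id[st$testable]
  pairs <- pairs[pairs$site_id %in% testable, ]
  sexes <- sexes %||% sort(unique(expression$sex))
  tx_ids <- transcript_ids %||% sort(unique(pairs$transcript_id))
  tx_ids <- intersect(tx_ids, unique(expression$transcript_id))
  avg <- expression |>
    group_by(.data$transcript_id, .data$sex, .data$line) |>
    summarise(value = mean(.data$value), .groups = "drop")
  results <- list(); tx_rows <- list()
  for (sx in sexes) {
    av <- avg[avg$sex == sx, ]
    for (tx in tx_ids) {
      y_tb <- av[av$transcript_id == tx, ]
      y <- y_tb$value[order(y_tb$line)]
      n <- length(y)
      sids <- pairs$site_id[pairs$transcript_id == tx]
      if (!length(sids)) next
      srows <- st[match(sids, st$site_id), ]
      perm <- with_substream(config$seed, "perm", tx, sx, code = {
        vapply(seq_len(config$n_perm), function(b) sample.int(n), integer(n))
      })
      for (method in config$methods) {
        obs <- numeric(nrow(srows)); pm <- matrix(NA_real_, nrow(srows), config$n_perm)
        keep_site <- rep(TRUE, nrow(srows))
        for (si in seq_len(nrow(srows))) {
          srow <- srows[si, ]
          g <- srow$line_allele[[1]]
          al <- srow$alleles[[1]]
          keep <- g %in% al$allele_id[al$included]
          gk <- g[keep]
          if (method == "score") {
            sc <- al$score[match(gk, al$allele_id)]
            if (length(unique(sc)) < 2L) { keep_site[[si]] <- FALSE; next }
            xr <- rank(sc)
          } else if (length(unique(gk)) < 2L) {
            keep_site[[si]] <- FALSE; next
          }
          if (all(keep)) {
            Rp <- matrix(rank(y)[perm], n)
          } else {
            Yp <- matrix(y[perm], n)[keep, , drop = FALSE]
            Rp <- apply(Yp, 2, rank)
          }
          robs <- matrix(rank(y[keep]), ncol = 1)
          if (method == "allele") {
            obs[[si]] <- kw_pvals(robs, gk)[[1]]
            pm[si, ] <- kw_pvals(Rp, gk)
          } else {
            obs[[si]] <- score_pvals(xr, robs)[[1]]
            pm[si, ] <- score_pvals(xr, Rp)
          }
        }
        if (!any(keep_site)) next
        minima <- apply(pm[keep_site, , drop = FALSE], 2, min)
        thr <- vapply(config$alpha_grid, adjusted_threshold,
                      numeric(1), minima = minima)
        eff <- vapply(which(keep_site), function(si) {
          effect_size(srows[si, ], y)
        }, numeric(1))
        tx_rows[[length(tx_rows) + 1L]] <- tibble(
          transcript_id = tx, sex = sx, method = method,
          min_p = min(obs[keep_site]),
          thresholds = list(stats::setNames(thr, config$alpha_grid)))
        results[[length(results) + 1L]] <- tibble(
          transcript_id = tx, sex = sx, method = method,
          site_id = srows$site_id[keep_site],
          raw_p = obs[keep_site], effect_log2 = eff)
      }
    }
  }
  tx_tb <- bind_rows(tx_rows)
  res_tb <- bind_rows(results)
  # FDR per sex x method over the alpha grid, then the operating threshold
  fdr_rows <- list(); op_rows <- list()
  for (sx in unique(tx_tb$sex)) for (me in unique(tx_tb$method)) {
    sub <- tx_tb[tx_tb$sex == sx & tx_tb$method == me, ]
    pass <- vapply(seq_along(config$alpha_grid), function(ai) {
      sum(vapply(seq_len(nrow(sub)), function(i) {
        sub$min_p[[i]] <= sub$thresholds[[i]][[ai]]
      }, logical(1)))
    }, integer(1))
    ft <- estimate_fdr(tibble(alpha = config$alpha_grid, n_passing = pass),
                       n_tested = nrow(sub), target = config$fdr_target)
    ft$sex <- sx; ft$method <- me
    fdr_rows[[length(fdr_rows) + 1L]] <- ft
    op <- if (any(ft$operating)) ft$alpha[ft$operating] else NA_real_
    op_rows[[length(op_rows) + 1L]] <-
      tibble(sex = sx, method = me, operating_alpha = op,
             operating_fdr = if (any(ft$operating)) ft$fdr[ft$operating] else NA_real_)
  }
  fdr_tb <- bind_rows(fdr_rows)
  op_tb <- bind_rows(op_rows)
  # per-site significance at the operating alpha
  res_tb$adjusted_threshold <- NA_real_
  res_tb$significant <- FALSE
  for (i in seq_len(nrow(op_tb))) {
    if (is.na(op_tb$operating_alpha[[i]])) next
    ai <- match(op_tb$operating_alpha[[i]], config$alpha_grid)
    sel <- res_tb$sex == op_tb$sex[[i]] & res_tb$method == op_tb$method[[i]]
    key <- paste(tx_tb$transcript_id, tx_tb$sex, tx_tb$method)
    thr_of <- stats::setNames(vapply(tx_tb$thresholds, `[[`, numeric(1), ai), key)
    res_tb$adjusted_threshold[sel] <-
      thr_of[paste(res_tb$transcript_id[sel], res_tb$sex[sel], res_tb$method[sel])]
    res_tb$significant[sel] <- res_tb$raw_p[sel] <= res_tb$adjusted_threshold[sel]
  }
  structure(list(results = res_tb, transcripts = tx_tb, fdr = fdr_tb,
                 operating = op_tb, config = config),
            class = "cis_eqtl_fit")
}

#' @export
print.cis_eqtl_fit <- function(x, ...) {
  cat("<cis_eqtl_fit>", length(unique(x$transcripts$transcript_id)),
      "transcripts,", x$config$n_perm, "permutations\n")
  print(x$operating)
  invisible(x)
}

#' Sex specificity of cis-eQTL-associated transcripts
#'
#' Labels each transcript with a significant eQTL as male-specific,
#' female-specific, or shared, using the operating threshold of each sex
#' (no secondary lenient threshold).
#'
#' @param fit A `cis_eqtl_fit` covering both sexes.
#' @param method Association method to classify on.
#' @return Tibble: `transcript_id`, `class` (`"male"`, `"female"`, `"both"`).
#' @export
sex_specificity <- function(fit, method = "allele") {
  r <- fit$results[fit$results$method == method & fit$results$significant, ]
  m <- unique(r$transcript_id[r$sex == "M"])
  f <- unique(r$transcript_id[r$sex == "F"])
  tibble(transcript_id = union(m, f)) |>
    mutate(class = case_when(
      .data$transcript_id %in% m & .data$transcript_id %in% f ~ "both",
      .data$transcript_id %in% m ~ "male",
      TRUE ~ "female"))
}
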