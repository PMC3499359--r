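test_that("probe-set filter drops variant-hit probes and thin sets", {
  g <- strrep("ACGT", 1000)
  panel <- make_panel(g, c(100, 200, 300), c("A", "A", "A"), c("G", "G", "G"),
                      list(1L, 1L, 1L), 8)
  probes <- tibble::tibble(
    probe_set = rep(c("ps1", "ps2", "ps3"), c(5, 3, 3)),
    probe_id = paste0("p", 1:11),
    start = c(90, 190, 290, 400, 425,      # ps1: 3 of 5 probes hit
              500, 525, 550,               # ps2: untouched
              95, 600, 625),               # ps3: 1 of 3 hit
    end = c(115, 215, 315, 420, 445, 520, 545, 570, 120, 620, 645))
  out <- filter_probesets(probes, panel)
  expect_equal(out$retained[out$probe_set == "ps1"], FALSE)  # 2 < 3 survive
  expect_equal(out$retained[out$probe_set == "ps2"], TRUE)   # boundary: 3 left
  expect_equal(out$retained[out$probe_set == "ps3"], FALSE)
  # no variants: everything retained
  out0 <- filter_probesets(probes, panel[0, ])
  expect_true(all(out0$retained))
})

test_that("expression presence filter counts lines by the both-replicates rule", {
  base <- tidyr::expand_grid(transcript_id = c("t1", "t2", "t3"),
                             line = 1:6, sex = c("M", "F"), replicate = 1:2)
  base$value <- 8
  base$detected <- TRUE
  # t2: detected in one replicate only, everywhere -> 0 expressing lines
  base$detected[base$transcript_id == "t2" & base$replicate == 2] <- FALSE
  # t3: both replicates detected in males for lines 1-4 only
  base$detected[base$transcript_id == "t3" &
                  !(base$sex == "M" & base$line <= 4)] <- FALSE
  out <- expressed_filter(base)
  expect_true(out$retained[out$transcript_id == "t1"])
  expect_false(out$retained[out$transcript_id == "t2"])
  expect_equal(out$n_expressing[out$transcript_id == "t2"], 0)
  expect_true(out$retained[out$transcript_id == "t3"])   # 4-line boundary
  base$detected[5] <- NA
  expect_error(expressed_filter(base), "detected")
})

test_that("genetic-variance filter separates heritable from noise-only transcripts", {
  withr::with_seed(14, {
    n_lines <- 20
    mk <- function(id, line_sd) {
      le <- rnorm(n_lines, 0, line_sd)
      tidyr::expand_grid(line = 1:n_lines, sex = c("M", "F"), replicate = 1:2) |>
        dplyr::mutate(transcript_id = id,
                      value = 8 + le[.data$line] + rnorm(dplyr::n(), 0, 0.25))
    }
    heritable <- dplyr::bind_rows(lapply(1:10, function(i) mk(paste0("h", i), 3)))
    flat <- dplyr::bind_rows(lapply(1:10, function(i) mk(paste0("f", i), 0)))
    out <- genetic_variance_filter(dplyr::bind_rows(heritable, flat), fdr = 0.001)
    expect_true(all(out$variable[grepl("^h", out$transcript_id)]))
    # at the 0.001 level a lone chance pass among the 20 noise-only tests is
    # possible; more than one would indicate miscalibration
    expect_lte(sum(out$variable[grepl("^f", out$transcript_id)]), 1)
    # degenerate: identical replicates everywhere -> flagged, not tested
    dg <- tidyr::expand_grid(line = 1:n_lines, sex = "M", replicate = 1:2) |>
      dplyr::mutate(transcript_id = "dg", value = 5, detected = TRUE)
    out2 <- genetic_variance_filter(dg)
    expect_false(out2$tested)
    # the F test itself matches stats::aov on one transcript/sex
    d1 <- heritable[heritable$transcript_id == "h1" & heritable$sex == "M", ]
    p_pkg <- out$p[out$transcript_id == "h1" & out$sex == "M"]
    p_aov <- summary(stats::aov(value ~ factor(line), data = d1))[[1]][["Pr(>F)"]][[1]]
    expect_equal(p_pkg, p_aov)
  })
})

test_that("allele grouping merges overlaps, collapses rare alleles and respects the window", {
  g <- strrep("ACGT", 10000)
  # two distant SNPs -> two sites; SNP inside a deletion -> one 3-allele site
  p <- make_panel(g, c(1000, 5000, 7000, 7002),
                  c("A", "A", substr(g, 7000, 7009), substr(g, 7002, 7002)),
                  c("G", "G", "", "A"),
                  list(c(1:4), c(5:8), c(1:3), c(4:6)), n_lines = 12)
  ga <- group_alleles(p, window = 10000)
  expect_equal(nrow(ga$sites), 3)
  multi <- ga$sites[ga$sites$start == 7000, ]
  expect_equal(multi$n_alleles, 3)
  la <- multi$line_allele[[1]]
  expect_equal(sum(la == 0), 6)            # reference lines
  expect_equal(length(unique(la)), 3)
  # alignment scores: deletion allele max(0, 10) = 10; SNP allele 1; ref 0
  expect_setequal(multi$alleles[[1]]$score, c(0, 10, 1))
  # rare allele exclusion: an allele with 2 carriers is not testable
  p2 <- make_panel(g, 2000, "A", "G", list(c(1L, 2L)), n_lines = 12)
  ga2 <- group_alleles(p2)
  expect_false(ga2$sites$testable)
  # cis-window boundary: transcript ends 10,001 bp away is not paired
  tx <- tibble::tibble(transcript_id = c("near", "far"), contig = "sim1",
                       start = c(11000L, 12001L), end = c(11400L, 12400L),
                       strand = "+", tss = c(11000L, 12001L),
                       tes = c(11400L, 12400L),
                       exons = list(tibble::tibble(start = 11000L, end = 11400L),
                                    tibble::tibble(start = 12001L, end = 12400L)),
                       utr5_len = 0L, cds_len = 0L, tx_len = 401L)
  ga3 <- group_alleles(make_panel(g, 1000, "A", "G", list(1:6), 12), tx)
  expect_equal(ga3$pairs$transcript_id, "near")  # far end is 10,001 bp away
})

test_that("vectorised association p-values agree exactly with the base tests", {
  withr::with_seed(17, {
    for (rep in 1:25) {
      n <- sample(8:39, 1)
      k <- sample(2:4, 1)
      g <- sample(rep(seq_len(k), length.out = n))
      y <- rnorm(n)
      if (rep %% 3 == 0) y <- round(y, 1)  # force ties
      p_ref <- stats::kruskal.test(y, factor(g))$p.value
      p_pkg <- varcis:::kw_pvals(matrix(rank(y), ncol = 1), g)[[1]]
      expect_equal(p_pkg, p_ref, tolerance = 1e-12)
      x <- sample(c(0, 1, 7), n, replace = TRUE)
      if (length(unique(x)) < 2) next
      ct <- stats::cor.test(rank(x), rank(y), method = "pearson")
      p_pkg2 <- varcis:::score_pvals(rank(x), matrix(rank(y), ncol = 1))[[1]]
      expect_equal(p_pkg2, ct$p.value, tolerance = 1e-9)
    }
  })
})

test_that("allele association handles degenerate and score-specific cases", {
  site <- make_site(c(rep(0, 5), rep(1, 5)))
  expect_equal(allele_association(site, rep(1, 10)), 1)  # constant expression
  # an all-reference site has a single group
  site0 <- make_site(rep(0, 10))
  expect_error(allele_association(site0, rnorm(10)), "two allele groups")
  # score association needs two distinct scores
  site_same <- make_site(c(rep(1, 5), rep(2, 5)), scores = c(3, 3))
  expect_error(score_association(site_same, rnorm(10)), "distinct")
  withr::with_seed(19, {
    # monotone score-expression relation across 3 alleles beats any pairwise subset
    g3 <- c(rep(0, 4), rep(1, 4), rep(2, 4))
    y3 <- c(rnorm(4, 0, .1), rnorm(4, 1, .1), rnorm(4, 2, .1))
    site3 <- make_site(g3, scores = c(0, 2, 5))
    p_all <- score_association(site3, y3)
    for (drop in 0:2) {
      keep <- g3 != drop
      sub <- make_site(g3[keep], scores = setdiff(c(0, 2, 5), c(0, 2, 5)[drop + 1]))
      expect_gt(score_association(sub, y3[keep]), p_all)
    }
  })
})

test_that("chi-square KW p-values track the exhaustive permutation distribution", {
  withr::with_seed(23, {
    configs <- list(c(3, 3), c(3, 4), c(4, 4), c(5, 5), c(3, 3, 3), c(4, 3, 3))
    for (sizes in configs) {
      for (rep in 1:3) {
        y <- rnorm(sum(sizes))
        g <- rep(seq_along(sizes), sizes)
        ex <- exact_kw_p(y, g)
        p_chi <- allele_association(make_site(g - 1), y)
        # the exact distribution at n <= 10 is coarse (atoms of 1/10 and up);
        # the chi-square approximation tracks it within that discreteness
        expect_lt(abs(p_chi - ex$p), 0.2)
      }
    }
  })
})

test_that("adjusted thresholds index the sorted minima vector", {
  minima <- sample(seq_len(10000) / 10000)
  expect_equal(adjusted_threshold(minima, 0.05), 0.05)  # the 500th element
  expect_equal(adjusted_threshold(rep(0.42, 1000), 0.01), 0.42)
  expect_error(adjusted_threshold(minima[1:5], 0.05), "index")
})

test_that("the FDR estimator is the expected-over-observed ratio", {
  ft <- estimate_fdr(tibble::tibble(alpha = c(0.01, 0.05),
                                    n_passing = c(30L, 100L)),
                     n_tested = 1000)
  expect_equal(ft$fdr, c(0.01 * 1000 / 30, 0.05 * 1000 / 100))
  expect_equal(ft$operating, c(FALSE, FALSE))  # 0.33 and 0.5 both exceed 10%
  ft2 <- estimate_fdr(tibble::tibble(alpha = c(0.01, 0.05),
                                     n_passing = c(200L, 300L)),
                      n_tested = 1000, target = 0.10)
  expect_equal(ft2$operating, c(TRUE, FALSE))  # only alpha = 0.01 has FDR <= 0.1
  ft3 <- estimate_fdr(tibble::tibble(alpha = 0.05, n_passing = 0L), 100)
  expect_true(is.na(ft3$fdr))
})

test_that("effect sizes are max pairwise group-mean differences", {
  site <- make_site(c(rep(0, 4), rep(1, 4)))
  expect_equal(effect_size(site, c(rep(5, 4), rep(6, 4))), 1)
  expect_equal(effect_size(site, rep(5, 8)), 0)
  site3 <- make_site(c(rep(0, 3), rep(1, 3), rep(2, 3)))
  expect_equal(effect_size(site3, c(rep(5, 3), rep(6, 3), rep(7, 3))), 2)
})

test_that("cis scan recovers a strong planted effect and classifies sex specificity", {
  cfg <- sim_config(seed = 61, genome_length = 80000, n_lines = 39,
                    n_transcripts = 8, eqtl_fraction = 0.5,
                    sex_specific_fraction = 1, effect_size = 1.5)
  g0 <- sim_genome(cfg)
  tr <- sim_transcripts(g0, cfg)
  panel <- normalize_variants(sim_variants(tr$genome, cfg), tr$genome)
  sites <- group_alleles(panel, tr$transcripts)
  ex <- sim_expression(panel, tr$transcripts, cfg, sites = sites)
  fit <- map_cis_eqtl(ex$expression, sites,
                      eqtl_config(seed = 3, n_perm = 300, methods = "allele",
                                  alpha_grid = c(0.01, 0.025, 0.05, 0.1)))
  sx <- sex_specificity(fit)
  found <- dplyr::inner_join(sx, ex$truth, by = "transcript_id")
  expect_gt(nrow(found), 0)
  # male-planted effects come out male-specific and vice versa
  expect_true(all(found$class ==
                    ifelse(found$scope == "M", "male", "female")))
  td <- tidy(fit)
  expect_true(all(td$significant == (td$raw_p <= td$adjusted_threshold) |
                    is.na(td$adjusted_threshold)))
  gl <- glance(fit)
  expect_setequal(gl$sex, c("M", "F"))
})

test_that("allele and score methods agree on bi-allelic sites", {
  # bi-allelic sites only; the two methods should declare the same transcripts
  # significant almost always
  withr::with_seed(29, {
    n_lines <- 39
    n_tx <- 40
    rows <- list(); exprs <- list()
    for (t in seq_len(n_tx)) {
      carriers <- sort(sample.int(n_lines, sample(5:20, 1)))
      la <- integer(n_lines); la[carriers] <- 1L
      site <- make_site(la, scores = c(0, 1))
      site$site_id <- sprintf("s%02d", t)
      rows[[t]] <- site
      eff <- sample(c(0, 0.8), 1)
      y <- 8 + eff * (la == 1) + rnorm(n_lines, 0, 0.35)
      exprs[[t]] <- tidyr::expand_grid(line = 1:n_lines, sex = "M",
                                       replicate = 1:2) |>
        dplyr::mutate(transcript_id = sprintf("t%02d", t),
                      value = y[.data$line] + rnorm(dplyr::n(), 0, 0.1))
    }
    sites <- list(sites = dplyr::bind_rows(rows) |>
                    dplyr::mutate(testable = TRUE),
                  pairs = tibble::tibble(site_id = sprintf("s%02d", 1:n_tx),
                                         transcript_id = sprintf("t%02d", 1:n_tx),
                                         distance = 0))
    fit <- map_cis_eqtl(dplyr::bind_rows(exprs), sites,
                        eqtl_config(seed = 5, n_perm = 400,
                                    alpha_grid = c(0.01, 0.025, 0.05, 0.1)))
    sig <- tidy(fit) |>
      dplyr::distinct(.data$transcript_id, .data$method, .data$significant)
    wide <- tidyr::pivot_wider(sig, names_from = "method",
                               values_from = "significant")
    expect_gte(mean(wide$allele == wide$score), 0.95)
  })
})
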