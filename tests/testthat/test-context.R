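test_that("SNP density profile localises planted clustering and satisfies the count identity", {
  withr::with_seed(4, {
    g <- random_dna_str(60000)
    n_lines <- 10
    # focal deletions every ~2 kb; SNPs planted only within 40 bp of them,
    # carried by the same lines
    del_pos <- seq(2000, 58000, by = 2000)
    snp_pos <- del_pos + sample(c(-40:-10, 10:40), length(del_pos), replace = TRUE)
    carr <- replicate(length(del_pos), sort(sample.int(n_lines, 4)),
                      simplify = FALSE)
    p <- make_panel(g, c(del_pos, snp_pos),
                    c(substring(g, del_pos, del_pos + 2),
                      substring(g, snp_pos, snp_pos)),
                    c(rep("", length(del_pos)),
                      vapply(snp_pos, function(q) {
                        sample(setdiff(c("A", "C", "G", "T"),
                                       substr(g, q, q)), 1)
                      }, character(1))),
                    c(carr, carr), n_lines = n_lines,
                    type = rep(c("del", "snp"), each = length(del_pos)))
    prof <- snp_density_around(p, "del", window = 1000, bin = 50)
    peak <- prof$count[abs(prof$offset) <= 50]
    expect_equal(sum(peak), sum(prof$count))  # all mass within +/- 50 bp
    expect_gt(sum(peak), 0)
    # control lines never carry these SNPs (same carrier sets)
    expect_equal(sum(prof$count_control), 0)
    # count identity against a direct triple-count oracle
    direct <- 0
    for (i in seq_along(del_pos)) {
      for (j in seq_along(snp_pos)) {
        if (abs(snp_pos[[j]] - del_pos[[i]]) <= 1000) {
          direct <- direct + length(intersect(carr[[i]], carr[[j]]))
        }
      }
    }
    expect_equal(sum(prof$count), direct)
    expect_error(snp_density_around(p, "del", allele_count_range = c(9, 9)),
                 "no focal")
  })
})

test_that("independently planted SNPs give a flat profile and matching control", {
  withr::with_seed(9, {
    g <- random_dna_str(200000)
    n_lines <- 20
    pos <- sort(sample(1000:199000, 900))
    carr <- replicate(length(pos), sort(sample.int(n_lines, sample(2:10, 1))),
                      simplify = FALSE)
    is_del <- seq_along(pos) %% 9 == 0
    p <- make_panel(g, pos,
                    ifelse(is_del, substring(g, pos, pos + 3),
                           substring(g, pos, pos)),
                    ifelse(is_del, "", "N"),  # alt content irrelevant here
                    carr, n_lines = n_lines,
                    type = ifelse(is_del, "del", "snp"))
    prof <- snp_density_around(p, "del", window = 2000, bin = 500)
    # independence null: per-bin densities fluctuate around a common mean
    expect_lt(max(prof$density) / max(mean(prof$density), 1e-9), 2.5)
    # and the control (non-carrier lines) sees the same loci: similar density
    expect_lt(abs(mean(prof$density) - mean(prof$density_control)),
              0.5 * mean(prof$density))
  })
})

test_that("adjacency excess is ~1 under independence and validates its inputs", {
  withr::with_seed(13, {
    n_lines <- 10
    g_len <- 200000
    pos <- sort(sample(seq(5, g_len - 5, by = 1), 2000))  # uniform: chance adjacency only
    carr <- replicate(length(pos), sort(sample.int(n_lines, sample(1:6, 1))),
                      simplify = FALSE)
    p <- make_panel(strrep("A", 10), pos, "A", "C", carr, n_lines = n_lines,
                    type = "snp")
    attr(p, "genome_length") <- g_len
    ae <- adjacency_excess(p, g_len, window = 1000, n_sim = 400, seed = 2)
    di <- ae[ae$order == "di", ]
    expect_true(di$ci_lo <= 1 && 1 <= di$ci_hi)
    expect_error(adjacency_excess(p, g_len, window = 2), "window")
    expect_error(adjacency_excess(p, g_len, n_sim = 50), "n_sim")
  })
})

test_that("windows with fewer than two substitutions contribute nothing", {
  p <- make_panel(strrep("A", 10), c(100, 5100), "A", "C",
                  list(1L, 1L), n_lines = 4, type = "snp")
  attr(p, "genome_length") <- 10000L
  ae <- adjacency_excess(p, 10000, window = 1000, n_sim = 100, seed = 1)
  expect_equal(ae$observed, c(0, 0))
  expect_equal(ae$expected, c(0, 0))
})

test_that("density correlations recover identical, independent and opposed layouts", {
  g_len <- 100000L
  bins <- 20
  # identical per-bin densities: deletions placed right next to each SNP
  snp_pos <- as.integer(seq(2500, 97500, length.out = 60))
  p_same <- make_panel(strrep("A", 10), c(snp_pos, snp_pos + 1L),
                       c(rep("A", 60), rep("AA", 60)),
                       c(rep("C", 60), rep("", 60)),
                       replicate(120, 1L, simplify = FALSE), 4,
                       type = rep(c("snp", "del"), each = 60))
  attr(p_same, "genome_length") <- g_len
  dc <- density_correlation(p_same, bin_size = 5000)
  expect_equal(dc$rho[dc$type == "del"], 1)
  # anti-sorted: SNP counts increase along the genome, deletions decrease
  snp_anti <- unlist(lapply(seq_len(bins), function(b) {
    rep(as.integer((b - 1) * 5000 + 2500), b)
  }))
  del_anti <- unlist(lapply(seq_len(bins), function(b) {
    rep(as.integer((b - 1) * 5000 + 2600), bins + 1 - b)
  }))
  p_anti <- make_panel(strrep("A", 10), c(snp_anti, del_anti),
                       c(rep("A", length(snp_anti)), rep("AA", length(del_anti))),
                       c(rep("C", length(snp_anti)), rep("", length(del_anti))),
                       replicate(length(snp_anti) + length(del_anti), 1L,
                                 simplify = FALSE), 4,
                       type = rep(c("snp", "del"),
                                  c(length(snp_anti), length(del_anti))))
  attr(p_anti, "genome_length") <- g_len
  dc2 <- density_correlation(p_anti, bin_size = 5000)
  expect_equal(dc2$rho[dc2$type == "del"], -1)
  # independent Poisson counts: |rho| small (null simulation, fixed seed)
  withr::with_seed(31, {
    ns <- 400
    p_ind <- make_panel(strrep("A", 10),
                        c(sample(g_len, ns), sample(g_len, ns)),
                        c(rep("A", ns), rep("AA", ns)),
                        c(rep("C", ns), rep("", ns)),
                        replicate(2 * ns, 1L, simplify = FALSE), 4,
                        type = rep(c("snp", "del"), each = ns))
    attr(p_ind, "genome_length") <- g_len
    dc3 <- density_correlation(p_ind, bin_size = 2500)
    expect_lt(abs(dc3$rho[dc3$type == "del"]), 2.5 / sqrt(dc3$n_bins[[1]]))
  })
  # constant density vector (one deletion per bin) is flagged
  bin_mid <- as.integer(seq(2500, 97500, by = 5000))
  p_const <- make_panel(strrep("A", 10),
                        c(snp_anti, bin_mid),
                        c(rep("A", length(snp_anti)), rep("AA", bins)),
                        c(rep("C", length(snp_anti)), rep("", bins)),
                        replicate(length(snp_anti) + bins, 1L,
                                  simplify = FALSE), 4,
                        type = rep(c("snp", "del"), c(length(snp_anti), bins)))
  attr(p_const, "genome_length") <- g_len
  expect_warning(density_correlation(p_const, bin_size = 5000), "constant")
})

test_that("r^2 follows the indicator-correlation definition", {
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)  # sign-invariant
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_warning(r2 <- ld_r2(c(1, 1, 1, 1), c(0, 1, 0, 1)), "monomorphic")
  expect_true(is.na(r2))
  g <- strrep("ACGT", 100)
  p <- make_panel(g, c(10, 50), c("A", "A"), c("G", "G"),
                  list(c(1L, 2L), c(3L, 4L)), n_lines = 4)
  expect_equal(ld_r2("v001", "v002", panel = p), 1)  # complementary carriers
})

test_that("feature profiles are strand-oriented and localise planted peaks", {
  tx <- tibble::tibble(
    transcript_id = c("p", "m"), contig = "sim1",
    start = c(5000L, 20000L), end = c(6000L, 21000L),
    strand = c("+", "-"),
    tss = c(5000L, 21000L), tes = c(6000L, 20000L),
    exons = list(tibble::tibble(start = 5000L, end = 6000L),
                 tibble::tibble(start = 20000L, end = 21000L)),
    utr5_len = 0L, cds_len = 0L, tx_len = 1001L)
  # a variant 300 bp upstream of the minus-strand TSS (genomic 21300)
  x <- tibble::tibble(pos = 21300L)
  prof <- feature_profile(x, tx[2, ], anchor = "TSS", window = 2000, bin = 100)
  hit <- prof$offset[prof$n > 0]
  expect_length(hit, 1)
  expect_lt(hit, 0)  # upstream = negative offset after strand flipping
  # planted peak within [-500, 500] of the TSS across both strands
  withr::with_seed(8, {
    x2 <- tibble::tibble(pos = c(5000L + sample(-500:500, 50, TRUE),
                                 21000L + sample(-500:500, 50, TRUE)))
    prof2 <- feature_profile(x2, tx, anchor = "TSS", window = 5000, bin = 500)
    expect_equal(sum(prof2$n[abs(prof2$offset) <= 500]), 100)
  })
  expect_error(feature_profile(x, tx[0, ], anchor = "TSS"), "empty")
})

test_that("coding consequences follow the class rules", {
  w <- tiny_world()
  tx <- w$transcripts
  g <- w$genome
  # work on a plus-strand transcript with a known CDS
  i <- which(tx$strand == "+")[1]
  t1 <- tx[i, ]
  cds_iv <- varcis:::cds_genomic_intervals(t1)
  cds_iv <- cds_iv[order(cds_iv$start), ]
  # pick an in-frame position: codon-aligned offset inside the first CDS chunk
  cstart <- cds_iv$start[[1]]
  pos3 <- cstart + 9L
  del3 <- tibble::tibble(pos = pos3, ref = substr(as.character(g), pos3, pos3 + 2),
                         alt = "", nd = 3L, ni = 0L)
  expect_true(variant_consequence(del3, t1, g) %in% c("in_frame", "stop_gain"))
  del1 <- tibble::tibble(pos = pos3, ref = substr(as.character(g), pos3, pos3),
                         alt = "", nd = 1L, ni = 0L)
  expect_equal(variant_consequence(del1, t1, g), "frameshift")
  # insertion of TAA at a codon boundary -> stop gain (codon-aligned)
  ins_taa <- tibble::tibble(pos = pos3, ref = "", alt = "TAA", nd = 0L, ni = 3L)
  expect_equal(variant_consequence(ins_taa, t1, g), "stop_gain")
  # deletion covering the whole CDS -> gene disruption
  big <- tibble::tibble(pos = min(cds_iv$start) - 2L,
                        ref = substr(as.character(g), min(cds_iv$start) - 2L,
                                     max(cds_iv$end) + 2L),
                        alt = "", nd = max(cds_iv$end) - min(cds_iv$start) + 5L,
                        ni = 0L)
  expect_equal(variant_consequence(big, t1, g), "gene_disruption")
  # splice dinucleotide overlap
  intr <- varcis:::intron_intervals(t1)
  spl <- tibble::tibble(pos = intr$start[[1]],
                        ref = substr(as.character(g), intr$start[[1]],
                                     intr$start[[1]]),
                        alt = "", nd = 1L, ni = 0L)
  expect_equal(variant_consequence(spl, t1, g), "splice_site_disruption")
  # UTR-only overlap
  utr_pos <- t1$start + 2L
  utr <- tibble::tibble(pos = utr_pos,
                        ref = substr(as.character(g), utr_pos, utr_pos),
                        alt = "G", nd = 1L, ni = 1L)
  if (utr$ref == "G") utr$alt <- "C"
  expect_equal(variant_consequence(utr, t1, g), "UTR")
  expect_error(variant_consequence(del3, dplyr::mutate(t1, cds_len = 0L), g),
               "CDS")
})

test_that("consequence agrees with a rebuild-and-translate oracle", {
  w <- tiny_world()
  g <- as.character(w$genome)
  oracle <- function(v, tx) {
    # rebuild the mutant transcript by applying the variant to the genome and
    # lifting the exon coordinates, then translate and compare proteins
    mut_g <- apply_variants(g, v)
    ex <- tx$exons[[1]]
    shift <- v$ni - v$nd
    lift <- function(q) ifelse(q >= v$pos + max(v$nd, 1L), q + shift, q)
    ex2 <- tibble::tibble(start = lift(ex$start), end = lift(ex$end))
    tx2 <- tx
    tx2$exons <- list(ex2)
    mut_tx <- varcis:::spliced_seq(tx2, mut_g)
    cds_len2 <- tx$cds_len + (if ((v$ni - v$nd) %% 3 == 0) v$ni - v$nd else 0)
    mut_cds <- substr(mut_tx, tx$utr5_len + 1, tx$utr5_len + cds_len2)
    if ((v$ni - v$nd) %% 3 != 0) return("frameshift")
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(mut_cds), if.fuzzy.codon = "X")))
    body <- substr(aa, 1, nchar(aa) - 1)
    if (grepl("\\*", body)) "stop_gain"
    else if (substr(aa, nchar(aa), nchar(aa)) != "*") "stop_loss"
    else "in_frame"
  }
  withr::with_seed(55, {
    checked <- 0
    for (rep in 1:120) {
      i <- sample(nrow(w$transcripts), 1)
      tx <- w$transcripts[i, ]
      cds_iv <- varcis:::cds_genomic_intervals(tx)
      cds_iv <- cds_iv[order(cds_iv$start), ]
      k <- sample(nrow(cds_iv), 1)
      # random small variant fully inside one CDS chunk
      nd <- sample(0:4, 1)
      ni <- sample(0:4, 1)
      if (nd + ni == 0) next
      lo <- cds_iv$start[[k]] + 3L
      hi <- cds_iv$end[[k]] - 3L - nd
      if (hi <= lo) next
      pos <- sample(lo:hi, 1)
      ref <- substr(g, pos, pos + nd - 1)
      alt <- if (ni > 0) random_dna_str(ni) else ""
      if (identical(ref, alt)) next
      if (nd > 0 && ni > 0 && (substr(ref, 1, 1) == substr(alt, 1, 1) ||
                               substr(ref, nd, nd) == substr(alt, ni, ni))) next
      v <- tibble::tibble(pos = pos, ref = ref, alt = alt,
                          nd = nchar(ref), ni = nchar(alt))
      got <- variant_consequence(v, tx, w$genome)
      expect_equal(got, oracle(v, tx),
                   label = sprintf("tx %s pos %d %s>%s: %s", tx$transcript_id,
                                   pos, ref, alt, got))
      checked <- checked + 1
    }
    expect_gt(checked, 60)
  })
})

test_that("frame spectrum summarises coding indels and singleton enrichment", {
  w <- tiny_world()
  tx <- w$transcripts
  g <- as.character(w$genome)
  cds_iv <- dplyr::bind_rows(lapply(seq_len(nrow(tx)), function(i) {
    varcis:::cds_genomic_intervals(tx[i, ])
  }))
  cds_iv <- cds_iv[order(cds_iv$start), ]
  mid <- function(k) as.integer(round((cds_iv$start[[k]] + cds_iv$end[[k]]) / 2))
  # all coding deletions of size 3 -> mod-3 fraction 1
  pos_a <- vapply(1:4, mid, integer(1))
  p3 <- make_panel(g, pos_a, substring(g, pos_a, pos_a + 2), "",
                   replicate(4, 1L, simplify = FALSE), 12)
  fs <- frame_spectrum(p3, tx)
  expect_equal(fs$mod3_fraction, 1)
  # sizes 1..6 uniform -> mod-3 fraction 1/3; frameshifts all singletons,
  # in-frame indels all shared
  ks <- seq_len(min(6, nrow(cds_iv)))
  pos_b <- vapply(ks, mid, integer(1))
  sizes <- seq_along(ks)
  carr <- ifelse(sizes %% 3 == 0, list(c(1L, 2L, 3L)), list(1L))
  p6 <- make_panel(g, pos_b,
                   substring(g, pos_b, pos_b + sizes - 1), "",
                   carr, 12)
  fs6 <- frame_spectrum(p6, tx)
  expect_equal(fs6$mod3_fraction, 1 / 3)
  expect_equal(fs6$singleton_frameshift, 1)
  expect_equal(fs6$singleton_inframe, 0)
  expect_error(frame_spectrum(p6[0, ], tx), "indel")
})
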