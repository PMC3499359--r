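#' SNP density around focal variants
#'
#' For every focal variant of the requested type (optionally restricted to a
#' minor-allele-count range), counts SNP observations per carrier line in
#' offset bins around the variant breakpoint (the normalized variant start;
#' the insertion point for insertions). The control profile counts the same
#' SNP loci in the lines that do not carry the focal variant, which is the
#' comparison that separates locus-level mutation-proneness from
#' population-level haplotype structure.
#'
#' @param panel A `variant_panel` (classified or with planted `type` labels).
#' @param focal_type Character vector of types to use as focal variants
#'   (matched against `top_level` when present, else `type`).
#' @param window Half-width of the profile in bp.
#' @param bin Bin width in bp (`window` must be a multiple of `bin`).
#' @param allele_count_range Optional length-2 vector restricting focal
#'   variants by carrier count, e.g. `c(2, 4)`.
#' @return A `density_profile` tibble: `offset` (bin midpoint), `count` and
#'   `count_control` (SNP-line observations), `density` and `density_control`
#'   (SNPs per kb per line).
#' @export
snp_density_around <- function(panel, focal_type, window = 1000L, bin = 50L,
                               allele_count_range = NULL) {
  if (bin <= 0L || window < bin) abort("need window >= bin > 0")
  n_lines <- attr(panel, "n_lines")
  type <- panel[["top_level"]] %||% panel[["type"]]
  is_snp <- panel$nd == 1L & panel$ni == 1L
  focal <- which(type %in% focal_type)
  if (!is.null(allele_count_range)) {
    focal <- focal[panel$n_carriers[focal] >= allele_count_range[[1]] &
                     panel$n_carriers[focal] <= allele_count_range[[2]]]
  }
  if (!length(focal)) abort("no focal variants in the requested type/count range")
  snp_idx <- which(is_snp)
  snp_pos <- panel$pos[snp_idx]
  ord <- order(snp_pos)
  snp_idx <- snp_idx[ord]; snp_pos <- snp_pos[ord]
  breaks <- seq(-window, window, by = bin)
  nb <- length(breaks) - 1L
  count <- numeric(nb); count_ctl <- numeric(nb)
  lines_focal <- 0; lines_ctl <- 0
  carr <- carrier_matrix(panel, n_lines)
  for (f in focal) {
    p <- panel$pos[[f]]
    lo <- findInterval(p - window, snp_pos) + 1L
    hi <- findInterval(p + window, snp_pos)
    cf <- carr[f, ]
    lines_focal <- lines_focal + sum(cf)
    lines_ctl <- lines_ctl + (n_lines - sum(cf))
    if (hi < lo) next
    for (j in lo:hi) {
      s <- snp_idx[[j]]
      if (s == f) next
      off <- snp_pos[[j]] - p
      b <- min(nb, findInterval(off, breaks, rightmost.closed = TRUE))
      cs <- carr[s, ]
      count[[b]] <- count[[b]] + sum(cs & cf)
      count_ctl[[b]] <- count_ctl[[b]] + sum(cs & !cf)
    }
  }
  out <- tibble(
    offset = (utils::head(breaks, -1L) + utils::tail(breaks, -1L)) / 2,
    count = count, count_control = count_ctl,
    density = count / (lines_focal / length(focal)) / length(focal) / (bin / 1000),
    density_control = count_ctl / (lines_ctl / length(focal)) / length(focal) /
      (bin / 1000))
  structure(out, class = c("density_profile", class(out)),
            n_focal = length(focal), bin = bin)
}

# Variant-by-line logical carrier matrix.
carrier_matrix <- function(panel, n_lines = attr(panel, "n_lines")) {
  m <- matrix(FALSE, nrow(panel), n_lines)
  for (i in seq_len(nrow(panel))) m[i, panel$carriers[[i]]] <- TRUE
  m
}

#' Adjacency excess of multi-nucleotide substitutions
#'
#' Tests whether adjacent substituted bases occur more often than expected if
#' single-nucleotide substitutions fell independently. All substituted base
#' positions per line (SNPs plus the component bases of balanced
#' multi-nucleotide substitutions) are collected in non-overlapping genomic
#' windows; observed di- (tri-) nucleotide substitutions are maximal runs of
#' exactly 2 (3) adjacent substituted bases. The expectation re-places each
#' window's substitutions uniformly `n_sim` times and counts chance
#' adjacencies; the ratio observed / mean simulated measures the excess, with
#' a Monte-Carlo confidence interval from the simulated totals.
#'
#' @param panel A `variant_panel`.
#' @param genome Reference sequence (or its length).
#' @param window Window length in bp (> 2).
#' @param n_sim Number of uniform re-placements (>= 100).
#' @param seed Seed for the re-placement stream.
#' @param conf Confidence level of the Monte-Carlo interval.
#' @return Tibble with rows `di` and `tri`: `observed`, `expected`, `ratio`,
#'   `ci_lo`, `ci_hi`.
#' @export
adjacency_excess <- function(panel, genome, window = 1000L, n_sim = 1000L,
                             seed = 1L, conf = 0.95) {
  if (window <= 2L) abort("window must exceed 2 bp")
  if (n_sim < 100L) abort("n_sim must be at least 100")
  L <- if (is.character(genome)) nchar(genome) else as.integer(genome)
  n_lines <- attr(panel, "n_lines")
  is_sub <- panel$nd == panel$ni & panel$nd >= 1L
  sub <- panel[is_sub, ]
  n_win <- L %/% window
  # substituted positions per (line, window)
  groups <- vector("list", 0)
  obs_di <- 0L; obs_tri <- 0L
  carr <- carrier_matrix(sub, n_lines)
  pos_list <- lapply(seq_len(nrow(sub)), function(i) {
    sub$pos[[i]] + seq_len(sub$nd[[i]]) - 1L
  })
  m_counts <- integer(0)
  for (l in seq_len(n_lines)) {
    p <- sort(unlist(pos_list[carr[, l]]))
    p <- p[p <= n_win * window]
    if (!length(p)) next
    w <- (p - 1L) %/% window
    for (pw in split(p, w)) {
      r <- rle(cumsum(c(1L, diff(pw) != 1L)))$lengths
      obs_di <- obs_di + sum(r == 2L)
      obs_tri <- obs_tri + sum(r == 3L)
      if (length(pw) >= 2L) m_counts <- c(m_counts, length(pw))
    }
  }
  sim_di <- numeric(n_sim)
  sim_tri <- numeric(n_sim)
  withr::with_seed(as.integer(seed), {
    for (m in m_counts) {
      for (s in seq_len(n_sim)) {
        q <- sort.int(sample.int(window, m))
        r <- rle(cumsum(c(1L, diff(q) != 1L)))$lengths
        sim_di[[s]] <- sim_di[[s]] + sum(r == 2L)
        sim_tri[[s]] <- sim_tri[[s]] + sum(r == 3L)
      }
    }
  })
  a <- (1 - conf) / 2
  mk <- function(obs, sims) {
    e <- mean(sims)
    tibble(observed = obs, expected = e,
           ratio = if (e > 0) obs / e else NA_real_,
           ci_lo = obs / stats::quantile(sims, 1 - a, names = FALSE),
           ci_hi = obs / stats::quantile(sims, a, names = FALSE))
  }
  bind_rows(di = mk(obs_di, sim_di), tri = mk(obs_tri, sim_tri),
            .id = "order")
}

#' Rank correlation of variant-type densities along the genome
#'
#' Bins the contig, counts variants per bin and type, and reports the Spearman
#' rank correlation (midranks for ties) of each non-SNP type's density with
#' the SNP density.
#'
#' @param panel A `variant_panel` with `top_level` or `type` labels.
#' @param bin_size Bin width in bp; at least 10 complete bins are required.
#' @return Tibble: `type`, `rho`, `n_bins`. Types with constant density give
#'   `NA` with a warning.
#' @export
density_correlation <- function(panel, bin_size = 5000L) {
  L <- attr(panel, "genome_length")
  n_bins <- L %/% bin_size
  if (n_bins < 10L) abort("need at least 10 complete bins")
  type <- panel[["top_level"]] %||% panel[["type"]]
  top <- ifelse(panel$nd == 1L & panel$ni == 1L, "snp", type)
  keep <- panel$pos <= n_bins * bin_size
  b <- (panel$pos[keep] - 1L) %/% bin_size + 1L
  tab <- table(factor(b, levels = seq_len(n_bins)), top[keep])
  if (!"snp" %in% colnames(tab)) abort("panel contains no SNPs")
  snp <- as.numeric(tab[, "snp"])
  others <- setdiff(colnames(tab), "snp")
  rho <- vapply(others, function(ty) {
    y <- as.numeric(tab[, ty])
    if (stats::sd(y) == 0 || stats::sd(snp) == 0) {
      warn(sprintf("constant density vector for type '%s': correlation undefined", ty))
      return(NA_real_)
    }
    stats::cor(snp, y, method = "spearman")
  }, numeric(1))
  tibble(type = others, rho = unname(rho), n_bins = n_bins)
}

#' Linkage disequilibrium between two bi-allelic sites
#'
#' Squared Pearson correlation of 0/1 allele indicators across lines. Sites
#' can be given as indicator vectors, or as variant ids together with the
#' panel.
#'
#' @param x,y 0/1 indicator vectors across lines, or variant ids when `panel`
#'   is supplied.
#' @param panel Optional `variant_panel` used to resolve ids to carrier sets.
#' @return `r^2` (scalar). Monomorphic sites give `NA` with a warning.
#' @export
#' @examples
#' ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1))
ld_r2 <- function(x, y, panel = NULL) {
  if (!is.null(panel)) {
    n <- attr(panel, "n_lines")
    ind <- function(id) {
      i <- match(id, panel$variant_id)
      if (is.na(i)) abort(sprintf("unknown variant id '%s'", id))
      as.integer(seq_len(n) %in% panel$carriers[[i]])
    }
    x <- ind(x); y <- ind(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("monomorphic site: r^2 undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Strand-oriented profile around transcription start or end sites
#'
#' Aggregates per-position values (variant density by default, or any numeric
#' column such as `-log10(p)`) in bins of offset from the TSS or TES of every
#' transcript, flipping minus-strand transcripts so that transcription always
#' proceeds in the positive x direction.
#'
#' @param x Tibble with a `pos` column (e.g. a `variant_panel` or an eQTL
#'   result joined to site positions).
#' @param transcripts Transcript tibble from [sim_transcripts()].
#' @param anchor `"TSS"` or `"TES"`.
#' @param window Half-width in bp.
#' @param bin Bin width in bp.
#' @param value Optional name of a numeric column in `x` to average per bin;
#'   when `NULL` the profile is a density (rows per kb per transcript).
#' @return A `feature_profile` tibble: `offset`, `n`, `value`.
#' @export
feature_profile <- function(x, transcripts, anchor = c("TSS", "TES"),
                            window = 10000L, bin = 500L, value = NULL) {
  anchor <- match.arg(anchor)
  if (nrow(transcripts) == 0L) abort("empty transcript annotation")
  breaks <- seq(-window, window, by = bin)
  nb <- length(breaks) - 1L
  n <- numeric(nb); vsum <- numeric(nb)
  vals <- if (is.null(value)) rep(1, nrow(x)) else x[[value]]
  for (i in seq_len(nrow(transcripts))) {
    a <- if (anchor == "TSS") transcripts$tss[[i]] else transcripts$tes[[i]]
    sgn <- if (transcripts$strand[[i]] == "+") 1L else -1L
    off <- (x$pos - a) * sgn
    keep <- which(off >= -window & off < window)
    if (!length(keep)) next
    b <- findInterval(off[keep], breaks, rightmost.closed = TRUE)
    for (j in seq_along(keep)) {
      n[[b[[j]]]] <- n[[b[[j]]]] + 1
      vsum[[b[[j]]]] <- vsum[[b[[j]]]] + vals[[keep[[j]]]]
    }
  }
  out <- tibble(
    offset = (utils::head(breaks, -1L) + utils::tail(breaks, -1L)) / 2,
    n = n,
    value = if (is.null(value)) {
      n / nrow(transcripts) / (bin / 1000)
    } else {
      ifelse(n > 0, vsum / n, NA_real_)
    })
  structure(out, class = c("feature_profile", class(out)),
            anchor = anchor,
            value_label = value %||% "variants per kb per transcript")
}

# CDS intervals of one transcript in genomic coordinates (1-based inclusive).
cds_genomic_intervals <- function(tx_row) {
  ex <- exon_map(tx_row)
  c1 <- tx_row$utr5_len + 1L
  c2 <- tx_row$utr5_len + tx_row$cds_len
  rows <- list()
  for (i in seq_len(nrow(ex))) {
    lo <- max(c1, ex$tx_start[[i]]); hi <- min(c2, ex$tx_end[[i]])
    if (lo > hi) next
    if (tx_row$strand == "+") {
      rows[[length(rows) + 1L]] <-
        tibble(start = ex$start[[i]] + (lo - ex$tx_start[[i]]),
               end = ex$start[[i]] + (hi - ex$tx_start[[i]]))
    } else {
      rows[[length(rows) + 1L]] <-
        tibble(start = ex$end[[i]] - (hi - ex$tx_start[[i]]),
               end = ex$end[[i]] - (lo - ex$tx_start[[i]]))
    }
  }
  bind_rows(rows)
}

overlaps_any <- function(s, e, iv) {
  nrow(iv) > 0L && any(s <= iv$end & e >= iv$start)
}

#' Coding consequence of a variant on a transcript
#'
#' Classifies a normalized variant overlapping a transcript into one of the
#' functional classes `gene_disruption` (deletion removing the entire coding
#' region), `splice_site_disruption` (overlap of an intron's first or last two
#' bases), `stop_gain`, `stop_loss`, `in_frame`, `frameshift`, `UTR`
#' (UTR-only overlap), or `intron` (intronic overlap away from splice sites,
#' outside the functional classes). In-frame coding variants are screened for
#' created stop codons by editing the coding sequence in transcript space and
#' scanning codons; stop loss is only evaluated when the variant overlaps the
#' annotated stop codon.
#'
#' @param variant One-row tibble (`pos`, `ref`, `alt`, `nd`, `ni`).
#' @param tx_row One-row transcript tibble.
#' @param genome Reference sequence.
#' @return Character scalar consequence class.
#' @export
variant_consequence <- function(variant, tx_row, genome) {
  if (tx_row$cds_len <= 0L) abort("transcript lacks a CDS")
  nd <- variant$nd; ni <- variant$ni
  vs <- if (nd > 0L) variant$pos else variant$pos - 1L
  ve <- if (nd > 0L) variant$pos + nd - 1L else variant$pos
  if (ve < tx_row$start || vs > tx_row$end) abort("variant does not overlap the transcript")
  cds_iv <- cds_genomic_intervals(tx_row)
  if (nd > 0L && vs <= min(cds_iv$start) && ve >= max(cds_iv$end)) {
    return("gene_disruption")
  }
  introns <- intron_intervals(tx_row)
  if (nrow(introns)) {
    splice <- bind_rows(tibble(start = introns$start, end = introns$start + 1L),
                        tibble(start = introns$end - 1L, end = introns$end))
    if (overlaps_any(vs, ve, splice)) return("splice_site_disruption")
  }
  coding <- if (nd > 0L) overlaps_any(variant$pos, ve, cds_iv)
            else insertion_in_interval(variant$pos, cds_iv)
  if (coding) {
    if ((ni - nd) %% 3L != 0L) return("frameshift")
    return(inframe_consequence(variant, tx_row, genome))
  }
  exonic <- if (nd > 0L) overlaps_any(variant$pos, ve, tx_row$exons[[1]])
            else insertion_in_interval(variant$pos, tx_row$exons[[1]])
  if (exonic) return("UTR")
  "intron"
}

# An insertion between reference bases pos-1 and pos falls inside an interval
# when both neighbours do: an insertion exactly at a feature boundary belongs
# to neither side's interior.
insertion_in_interval <- function(pos, iv) {
  nrow(iv) > 0L && any(pos - 1L >= iv$start & pos <= iv$end)
}

# Stop-codon screen for an in-frame coding variant: edit the CDS in transcript
# space, then scan codons of the edited stretch.
inframe_consequence <- function(variant, tx_row, genome) {
  ref_tx <- spliced_seq(tx_row, genome)
  cds <- substr(ref_tx, tx_row$utr5_len + 1L, tx_row$utr5_len + tx_row$cds_len)
  ed <- tx_edit(variant, tx_row)
  ca <- ed$a - tx_row$utr5_len
  cb <- ed$b - tx_row$utr5_len
  ca_cl <- max(ca, 1L); cb_cl <- min(cb, tx_row$cds_len)
  mutant <- paste0(substr(cds, 1L, ca_cl - 1L), ed$repl,
                   substr(cds, cb_cl + 1L, tx_row$cds_len))
  ml <- nchar(mutant)
  stops <- c("TAA", "TAG", "TGA")
  at <- if (ml >= 6L) seq(1L, ml - 3L, by = 3L) else integer(0)
  internal <- substring(mutant, at, at + 2L)
  touches_stop <- cb >= tx_row$cds_len - 2L
  if (any(internal %in% stops)) return("stop_gain")
  if (touches_stop && !substr(mutant, ml - 2L, ml) %in% stops) return("stop_loss")
  "in_frame"
}

# Transcript-space edit of a genomic variant: returns the affected transcript
# coordinates [a, b] (b = a - 1 for insertions) and the replacement sequence
# on the transcript strand.
tx_edit <- function(variant, tx_row) {
  plus <- tx_row$strand == "+"
  if (variant$nd > 0L) {
    gpos <- variant$pos:(variant$pos + variant$nd - 1L)
    tpos <- genome_to_tx(tx_row, gpos)
    if (any(is.na(tpos))) abort("variant crosses an exon boundary")
    a <- min(tpos); b <- max(tpos)
    repl <- if (plus) variant$alt else revcomp(variant$alt)
  } else {
    t_at <- genome_to_tx(tx_row, variant$pos)
    t_prev <- genome_to_tx(tx_row, variant$pos - 1L)
    if (is.na(t_at) || is.na(t_prev)) abort("insertion at an exon boundary")
    a <- min(t_at, t_prev) + 1L
    b <- a - 1L
    repl <- if (plus) variant$alt else revcomp(variant$alt)
  }
  list(a = a, b = b, repl = repl)
}

#' Size spectrum of coding indels
#'
#' Histogram of pure insertions and deletions overlapping coding sequence by
#' size, the fraction of sizes that are multiples of three (frame-preserving),
#' and the fraction of singletons (carrier count 1) among frameshifting
#' versus non-frameshifting coding indels.
#'
#' @param panel A `variant_panel`.
#' @param transcripts Transcript tibble.
#' @return A `frame_spectrum` list: `sizes` tibble (`size`, `class`, `n`),
#'   `mod3_fraction`, `singleton_frameshift`, `singleton_inframe`,
#'   `n_coding_indels`.
#' @export
frame_spectrum <- function(panel, transcripts) {
  is_indel <- xor(panel$nd == 0L, panel$ni == 0L)
  idx <- which(is_indel)
  if (!length(idx)) abort("panel has no pure indels")
  cds_all <- bind_rows(lapply(seq_len(nrow(transcripts)), function(i) {
    cds_genomic_intervals(transcripts[i, ])
  }))
  coding <- vapply(idx, function(i) {
    if (panel$nd[[i]] > 0L) {
      overlaps_any(panel$pos[[i]], panel$pos[[i]] + panel$nd[[i]] - 1L, cds_all)
    } else {
      insertion_in_interval(panel$pos[[i]], cds_all)
    }
  }, logical(1))
  idx <- idx[coding]
  if (!length(idx)) abort("no coding indels found")
  size <- panel$nd[idx] + panel$ni[idx]
  cls <- ifelse(panel$nd[idx] > 0L, "deletion", "insertion")
  singleton <- panel$n_carriers[idx] == 1L
  fs <- size %% 3L != 0L
  res <- list(
    sizes = tibble(size = size, class = cls) |>
      count(.data$size, .data$class, name = "n"),
    mod3_fraction = mean(!fs),
    singleton_frameshift = if (any(fs)) mean(singleton[fs]) else NA_real_,
    singleton_inframe = if (any(!fs)) mean(singleton[!fs]) else NA_real_,
    n_coding_indels = length(idx))
  structure(res, class = "frame_spectrum")
}

#' @export
print.frame_spectrum <- function(x, ...) {
  cat("<frame_spectrum>", x$n_coding_indels, "coding indels;",
      sprintf("%.1f%% frame-preserving (size %% 3 == 0)\n", 100 * x$mod3_fraction))
  cat(sprintf("  singleton fraction: frameshift %.2f, in-frame %.2f\n",
              x$singleton_frameshift, x$singleton_inframe))
  invisible(x)
}
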