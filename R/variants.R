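#' Normalize variants
#'
#' Brings every variant into canonical form: shared leading and trailing bases
#' between the reference and alternative allele are trimmed (suffix first,
#' then prefix, adjusting `pos`), and pure indels are left-shifted to the
#' smallest equivalent position (the standard left-alignment used for VCF
#' representation). The operation is idempotent and errors when a reference
#' allele disagrees with the genome.
#'
#' @param panel A `variant_panel` or any tibble with `pos`, `ref`, `alt`.
#' @param genome Reference sequence the variants are expressed against.
#' @return The input tibble with `pos`, `ref`, `alt`, `nd`, `ni` updated.
#' @export
normalize_variants <- function(panel, genome) {
  g <- as.character(genome)
  out <- panel
  for (i in seq_len(nrow(panel))) {
    v <- normalize_one(panel$pos[[i]], panel$ref[[i]], panel$alt[[i]], g)
    out$pos[[i]] <- v$pos; out$ref[[i]] <- v$ref; out$alt[[i]] <- v$alt
  }
  out$nd <- nchar(out$ref)
  out$ni <- nchar(out$alt)
  if (any(out$nd + out$ni < 1L)) abort("degenerate variant: empty ref and alt")
  out
}

normalize_one <- function(pos, ref, alt, g) {
  nd <- nchar(ref); ni <- nchar(alt)
  if (nd > 0L && substr(g, pos, pos + nd - 1L) != ref) {
    abort(sprintf("reference allele disagrees with genome at pos %d", pos))
  }
  # trim shared suffix
  while (nd > 0L && ni > 0L &&
         substr(ref, nd, nd) == substr(alt, ni, ni) &&
         !(nd == 1L && ni == 1L)) {
    ref <- substr(ref, 1L, nd - 1L); alt <- substr(alt, 1L, ni - 1L)
    nd <- nd - 1L; ni <- ni - 1L
  }
  # trim shared prefix
  while (nd > 0L && ni > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         !(nd == 1L && ni == 1L)) {
    ref <- substr(ref, 2L, nd); alt <- substr(alt, 2L, ni)
    pos <- pos + 1L
    nd <- nd - 1L; ni <- ni - 1L
  }
  # left-shift pure indels through repeated sequence
  if (xor(nd == 0L, ni == 0L)) {
    allele <- if (nd > 0L) ref else alt
    k <- nchar(allele)
    while (pos > 1L && substr(g, pos - 1L, pos - 1L) == substr(allele, k, k)) {
      allele <- paste0(substr(g, pos - 1L, pos - 1L), substr(allele, 1L, k - 1L))
      pos <- pos - 1L
    }
    if (nd > 0L) ref <- allele else alt <- allele
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify variants by type
#'
#' Assigns each normalized variant exactly one top-level class from the
#' deleted/inserted base counts (`nd`, `ni`): `snp` when `nd = ni = 1`,
#' `insertion` when `nd = 0`, `deletion` when `ni = 0`, and `complex` when
#' both are positive. Subtypes are derived from the allele sequence plus its
#' flanking genome context:
#' \itemize{
#'   \item homopolymer: repeat unit of size 1, resulting run >= 3 bases;
#'   \item microsatellite: unit size 2-4, resulting number of full repeat
#'     units >= 4;
#'   \item tandem repeat: unit size > 4, resulting repeats >= 2;
#'   \item segmental duplication: allele >= 100 bp with a homologous genomic
#'     interval (>= 90% identity over >= 90% of its length, see
#'     [find_duplicon()]);
#'   \item MNS: balanced substitution, `nd = ni > 1`;
#'   \item inversion: `nd = ni >= 4` and the alternative allele is the exact
#'     reverse complement of the reference allele.
#' }
#' Insertion repeat counts are evaluated on the post-insertion sequence;
#' deletion repeat counts on the reference sequence. Only full repeat units in
#' the allele's own phase are counted.
#'
#' @param panel Normalized `variant_panel` (or tibble with `pos`, `ref`,
#'   `alt`, `nd`, `ni`).
#' @param genome Reference sequence.
#' @param check_duplicons Whether to run the homology search for alleles
#'   >= `dup_min_len` bp (it is the only expensive part).
#' @param dup_min_len Minimum allele length for the duplication subtype.
#' @return The input with `top_level`, `subtype`, `repeat_size` columns added.
#' @export
classify_variants <- function(panel, genome, check_duplicons = TRUE,
                              dup_min_len = 100L) {
  nd <- panel$nd; ni <- panel$ni
  if (any(nd + ni < 1L)) abort("variants must satisfy nd + ni >= 1")
  top <- ifelse(nd == 1L & ni == 1L, "snp",
         ifelse(nd == 0L, "insertion",
         ifelse(ni == 0L, "deletion", "complex")))
  subtype <- rep("none", nrow(panel))
  repeat_size <- rep(NA_integer_, nrow(panel))
  g <- as.character(genome)
  for (i in seq_len(nrow(panel))) {
    if (top[[i]] == "snp") next
    if (top[[i]] == "complex") {
      if (nd[[i]] == ni[[i]] && nd[[i]] > 1L) {
        subtype[[i]] <- if (nd[[i]] >= 4L &&
                            panel$alt[[i]] == revcomp(panel$ref[[i]]))
          "inversion" else "MNS"
      }
      next
    }
    allele <- if (top[[i]] == "insertion") panel$alt[[i]] else panel$ref[[i]]
    rep_cls <- repeat_subtype(allele, g, panel$pos[[i]], panel$nd[[i]])
    if (!is.na(rep_cls$subtype)) {
      subtype[[i]] <- rep_cls$subtype
      repeat_size[[i]] <- rep_cls$repeat_size
    } else if (check_duplicons && nchar(allele) >= dup_min_len) {
      hit <- find_duplicon(panel[i, ], g)
      if (nrow(hit)) subtype[[i]] <- "segmental_duplication"
    }
  }
  panel$top_level <- top
  panel$subtype <- subtype
  panel$repeat_size <- repeat_size
  panel
}

# Repeat-context subtype of a pure indel. The repeat unit is the smallest
# period of the indel allele (which must be a whole number of units); the
# resulting copy number is counted on the post-insertion sequence for
# insertions and on the reference for deletions, walking whole units outward
# from the allele in its own phase.
repeat_subtype <- function(allele, g, pos, nd, flank = 200L) {
  m <- nchar(allele)
  if (m == 0L) return(list(subtype = NA_character_, repeat_size = NA_integer_))
  p <- smallest_period(allele)
  unit <- substr(allele, 1L, p)
  copies <- m %/% p
  # context: for an insertion the allele sits between pos-1 and pos of the
  # reference; for a deletion it occupies pos..pos+nd-1 of the reference.
  left_end <- pos - 1L
  right_start <- if (nd > 0L) pos + nd else pos
  lf <- substr(g, max(1L, left_end - flank + 1L), left_end)
  rf <- substr(g, right_start, min(nchar(g), right_start + flank - 1L))
  # walk left
  q <- nchar(lf)
  while (q >= p && substr(lf, q - p + 1L, q) == unit) {
    copies <- copies + 1L
    q <- q - p
  }
  q <- 0L
  while (q + p <= nchar(rf) && substr(rf, q + 1L, q + p) == unit) {
    copies <- copies + 1L
    q <- q + p
  }
  if (p == 1L && copies >= 3L) {
    list(subtype = "homopolymer", repeat_size = 1L)
  } else if (p >= 2L && p <= 4L && copies >= 4L) {
    list(subtype = "microsatellite", repeat_size = p)
  } else if (p > 4L && copies >= 2L) {
    list(subtype = "tandem_repeat", repeat_size = p)
  } else {
    list(subtype = NA_character_, repeat_size = NA_integer_)
  }
}

#' Site-frequency spectrum of a variant panel
#'
#' Histogram of variants by minor allele count and top-level type, with the
#' folded neutral expectation scaled to the observed polymorphic total per
#' type. Variants carried by all lines are reported in a `minor_count = 0`
#' bin labelled alternate-fixed: for those, the rare allele is the one in the
#' reference genome.
#'
#' @param panel A classified `variant_panel` (a `type`/`top_level` column is
#'   used if present, otherwise everything is pooled).
#' @return A `variant_spectrum` tibble: `type`, `minor_count`, `observed`,
#'   `expected`.
#' @export
variant_spectrum <- function(panel) {
  if (nrow(panel) == 0L) abort("empty panel")
  n_lines <- attr(panel, "n_lines")
  if (is.null(n_lines)) abort("panel lacks an n_lines attribute")
  type <- panel[["top_level"]] %||% panel[["type"]] %||% rep("all", nrow(panel))
  minor <- pmin(panel$n_carriers, n_lines - panel$n_carriers)
  exp_sfs <- neutral_folded_sfs(n_lines)
  out <- tidyr::expand_grid(type = sort(unique(type)),
                            minor_count = c(0L, exp_sfs$minor_count))
  obs <- tibble(type = type, minor_count = minor) |>
    count(.data$type, .data$minor_count, name = "observed")
  out <- left_join(out, obs, by = c("type", "minor_count")) |>
    mutate(observed = tidyr::replace_na(.data$observed, 0L))
  totals <- out |>
    filter(.data$minor_count > 0L) |>
    group_by(.data$type) |>
    summarise(total = sum(.data$observed))
  out <- out |>
    left_join(totals, by = "type") |>
    left_join(exp_sfs, by = "minor_count") |>
    mutate(expected = .data$total * .data$expected_prop) |>
    select("type", "minor_count", "observed", "expected")
  class(out) <- c("variant_spectrum", class(out))
  attr(out, "n_lines") <- n_lines
  out
}

#' Find a homologous genomic interval for a large variant allele
#'
#' Seeded local homology search replacing an external aligner: exact k-mer
#' seeds of the variant allele are matched against the genome (both strands),
#' seed hits are grouped by diagonal, and candidate placements are verified by
#' gapless comparison over the full allele length. A hit is reported when
#' identity is at least `min_identity` over at least `min_cover` of the allele
#' length. For deletions, the allele's own locus is excluded.
#'
#' @param variant One-row tibble with `pos`, `ref`, `alt`, `nd`, `ni`.
#' @param genome Reference sequence.
#' @param k Seed length.
#' @param min_identity Minimum identity of the verified alignment.
#' @param min_cover Minimum aligned fraction of the allele.
#' @return Tibble with zero rows (no hit) or columns `start`, `end`, `strand`,
#'   `identity`, `location` (`"intra"` for same-contig hits; the simulator is
#'   single-contig, so inter-contig hits only arise with user genomes).
#' @export
find_duplicon <- function(variant, genome, k = 16L,
                          min_identity = 0.9, min_cover = 0.9) {
  allele <- if (variant$ni >= variant$nd) variant$alt else variant$ref
  m <- nchar(allele)
  if (m < k) abort("allele shorter than the seed length")
  g <- as.character(genome)
  gl <- nchar(g)
  self_start <- if (variant$nd >= variant$ni) variant$pos else NA_integer_
  best <- NULL
  for (strand in c("+", "-")) {
    a <- if (strand == "+") allele else revcomp(allele)
    offs <- seq(1L, m - k + 1L)
    seeds <- substring(a, offs, offs + k - 1L)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(g))
    starts <- Biostrings::startIndex(hits)
    diag <- unlist(lapply(seq_along(starts), function(j) {
      if (is.null(starts[[j]])) integer(0) else starts[[j]] - offs[[j]] + 1L
    }))
    if (!length(diag)) next
    if (!is.na(self_start) && strand == "+") {
      diag <- diag[abs(diag - self_start) > m]  # exclude the allele's own locus
    }
    if (!length(diag)) next
    tab <- sort(table(diag), decreasing = TRUE)
    cand <- as.integer(names(tab))[seq_len(min(5L, length(tab)))]
    for (d in cand) {
      s <- max(1L, d)
      e <- min(gl, d + m - 1L)
      aligned <- e - s + 1L
      if (aligned < min_cover * m) next
      asub <- substr(a, s - d + 1L, e - d + 1L)
      edits <- hamming(asub, substr(g, s, e))
      identity <- 1 - edits / aligned
      if (identity >= min_identity &&
          (is.null(best) || identity > best$identity)) {
        best <- tibble(start = s, end = e, strand = strand,
                       identity = identity, location = "intra")
      }
    }
  }
  best %||% tibble(start = integer(), end = integer(), strand = character(),
                   identity = numeric(), location = character())
}
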