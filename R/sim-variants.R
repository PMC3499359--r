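#' Plant variants on a reference genome
#'
#' Draws a panel of SNPs, insertions, deletions, balanced multi-nucleotide
#' substitutions (MNS) and unbalanced complex variants at the configured
#' per-bp rates, assigns each to a carrier-line subset drawn from the
#' configured allele-frequency model, and (optionally) overlays additional
#' alleles on a fraction of deletions to create multi-allelic sites. Variants
#' are otherwise non-overlapping, so the planted truth is unambiguous and
#' haplotypes reconstruct exactly.
#'
#' @param genome A [sim_genome()] sequence (transcript ORFs may already be
#'   embedded by [sim_transcripts()]).
#' @param config A [sim_config()].
#' @return A `variant_panel`: a tibble with one row per planted variant and
#'   columns `variant_id`, `contig`, `pos` (1-based first affected reference
#'   base; for insertions the base before which the new sequence goes), `ref`,
#'   `alt`, `nd`, `ni`, `type` (planted label), `carriers` (list-column of
#'   carrier line indices) and `n_carriers`. Attributes: `n_lines`,
#'   `genome_length`, `contig`.
#' @export
sim_variants <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- nchar(genome)
  contig <- attr(genome, "contig") %||% "sim1"
  n_lines <- config$n_lines
  counts <- round(config$variant_rates * L)
  counts <- counts[counts > 0]
  if (!length(counts)) {
    return(new_variant_panel(empty_variants(), n_lines, L, contig))
  }
  with_substream(config$seed, "variants", code = {
    type <- rep(names(counts), counts)
    n <- length(type)
    nd <- integer(n); ni <- integer(n)
    is <- type == "ins"; dl <- type == "del"; mn <- type == "mns"
    cx <- type == "complex"; sn <- type == "snp"
    nd[sn] <- 1L; ni[sn] <- 1L
    ni[is] <- pmin(stats::rgeom(sum(is), 0.35) + 1L, 50L)
    nd[dl] <- pmin(stats::rgeom(sum(dl), 0.35) + 1L, 50L)
    k <- sample(2:6, sum(mn), replace = TRUE,
                prob = c(0.61, 0.22, 0.09, 0.05, 0.03))
    nd[mn] <- k; ni[mn] <- k
    nd[cx] <- sample(1:6, sum(cx), replace = TRUE)
    ni[cx] <- sample(1:6, sum(cx), replace = TRUE)
    bump <- cx & nd == ni
    ni[bump] <- ni[bump] + 1L  # keep 'complex' distinct from balanced MNS
    # shuffle so types are interleaved along the contig
    ord <- sample.int(n)
    type <- type[ord]; nd <- nd[ord]; ni <- ni[ord]
    span <- pmax(nd, 1L)
    pos <- place_spans(n, span, lo = config$margin + 1L,
                       hi = L - config$margin - max(span),
                       gap = config$min_spacing)
    ref <- ifelse(nd > 0L, substring(as.character(genome), pos, pos + nd - 1L), "")
    alt <- draw_alt(ref, ni)
    # carrier counts from the AFS model
    ncar <- switch(config$afs_model,
      neutral_folded = sample.int(n_lines - 1L, n, replace = TRUE,
                                  prob = 1 / seq_len(n_lines - 1L)),
      fixed_counts = rep(config$fixed_count, n))
    carriers <- lapply(ncar, function(k) sort(sample.int(n_lines, k)))
    tb <- tibble(contig = contig, pos = pos, ref = ref, alt = alt,
                 nd = nd, ni = ni, type = type, carriers = carriers)
    tb <- bind_rows(tb, overlay_alleles(tb, genome, config))
    tb <- arrange(tb, .data$pos, .data$nd)
    tb$variant_id <- sprintf("var%05d", seq_len(nrow(tb)))
    tb$n_carriers <- lengths(tb$carriers)
    tb <- select(tb, "variant_id", "contig", "pos", "ref", "alt",
                 "nd", "ni", "type", "carriers", "n_carriers")
    new_variant_panel(tb, n_lines, L, contig)
  })
}

new_variant_panel <- function(tb, n_lines, genome_length, contig) {
  structure(tb, n_lines = as.integer(n_lines),
            genome_length = as.integer(genome_length), contig = contig,
            class = c("variant_panel", class(tibble())))
}

empty_variants <- function() {
  tibble(variant_id = character(), contig = character(), pos = integer(),
         ref = character(), alt = character(), nd = integer(), ni = integer(),
         type = character(), carriers = list(), n_carriers = integer())
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("<variant_panel>", nrow(x), "variants across",
      attr(x, "n_lines"), "lines on", attr(x, "contig"),
      paste0("(", attr(x, "genome_length"), " bp)\n"))
  NextMethod()
}

# Greedy non-overlapping placement of n spans with a minimum gap; bounded
# retries, then an informative error when the requested density is infeasible.
place_spans <- function(n, span, lo, hi, gap, max_tries = 8L) {
  if (hi < lo) abort("genome too short for requested variants and margins")
  max_span <- max(span)
  for (try in seq_len(max_tries)) {
    cand <- sort(sample(lo:hi, min(hi - lo + 1L, n * 3L * try)))
    # greedy gap filter with the conservative (largest) span, so any subset
    # of the accepted positions is collision-free regardless of assignment
    acc <- integer(length(cand))
    k <- 0L
    last_end <- -Inf
    for (p in cand) {
      if (p > last_end + gap) {
        k <- k + 1L
        acc[[k]] <- p
        last_end <- p + max_span - 1L
      }
    }
    if (k >= n) return(sort(sample(acc[seq_len(k)], n)))
  }
  abort("variant placement failed: rates too high for genome length")
}

# Alternative alleles: random sequence forced to differ from the reference
# allele at its first and last base, so substitutions carry no shared flanks.
draw_alt <- function(ref, ni) {
  bases <- c("A", "C", "G", "T")
  n <- length(ref)
  out <- character(n)
  for (i in seq_len(n)) {
    if (ni[[i]] == 0L) { out[[i]] <- ""; next }
    a <- sample(bases, ni[[i]], replace = TRUE)
    r <- strsplit(ref[[i]], "")[[1]]
    if (length(r)) {
      a[[1]] <- sample(setdiff(bases, r[[1]]), 1L)
      if (ni[[i]] > 1L) {
        a[[ni[[i]]]] <- sample(setdiff(bases, r[[length(r)]]), 1L)
      }
    }
    out[[i]] <- paste(a, collapse = "")
  }
  out
}

# Second alleles overlapping a fraction of multi-bp deletions: a SNP inside
# the deleted span, carried by lines that lack the deletion. This is the only
# sanctioned overlap; it creates multi-allelic sites for the eQTL machinery.
overlay_alleles <- function(tb, genome, config) {
  idx <- which(tb$type == "del" & tb$nd >= 2L)
  n_extra <- round(config$multiallelic_rate * length(idx))
  if (n_extra == 0L) return(empty_variants()[0, c("contig", "pos", "ref", "alt",
                                                  "nd", "ni", "type", "carriers")])
  idx <- sample(idx, n_extra)
  rows <- lapply(idx, function(i) {
    p <- tb$pos[[i]] + sample.int(tb$nd[[i]], 1L) - 1L
    r <- substr(as.character(genome), p, p)
    a <- sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    free <- setdiff(seq_len(config$n_lines), tb$carriers[[i]])
    k <- min(length(free), sample.int(max(1L, length(free) %/% 2L), 1L))
    tibble(contig = tb$contig[[i]], pos = p, ref = r, alt = a,
           nd = 1L, ni = 1L, type = "snp",
           carriers = list(sort(sample(free, k))))
  })
  bind_rows(rows)
}

#' Apply variants to a sequence
#'
#' Rebuilds one haplotype by substituting each variant's alternative allele
#' into the reference. Variants must be non-overlapping within the set.
#'
#' @param genome Reference sequence (character scalar).
#' @param variants Tibble with `pos`, `ref`, `alt`, `nd` columns, any order.
#' @return Character scalar haplotype sequence.
#' @export
apply_variants <- function(genome, variants) {
  g <- as.character(genome)
  if (nrow(variants) == 0L) return(g)
  v <- variants[order(variants$pos, variants$nd), ]
  ends <- v$pos + pmax(v$nd, 1L) - 1L
  if (any(utils::head(ends, -1L) >= utils::tail(v$pos, -1L) &
          utils::head(v$nd, -1L) > 0L)) {
    abort("variants overlap within one haplotype")
  }
  pieces <- character(2L * nrow(v) + 1L)
  cur <- 1L
  for (i in seq_len(nrow(v))) {
    pieces[[2L * i - 1L]] <- substr(g, cur, v$pos[[i]] - 1L)
    pieces[[2L * i]] <- v$alt[[i]]
    if (v$nd[[i]] > 0L && substr(g, v$pos[[i]], ends[[i]]) != v$ref[[i]]) {
      abort(sprintf("reference allele mismatch at pos %d", v$pos[[i]]))
    }
    cur <- v$pos[[i]] + v$nd[[i]]
  }
  pieces[[2L * nrow(v) + 1L]] <- substr(g, cur, nchar(g))
  paste(pieces, collapse = "")
}

#' Reconstruct per-line haplotypes from a variant panel
#'
#' @param genome Reference sequence.
#' @param panel A `variant_panel` from [sim_variants()].
#' @return Named character vector `line_1` .. `line_n` of haplotype sequences
#'   (inbred lines are fully homozygous, one haplotype each).
#' @export
build_haplotypes <- function(genome, panel) {
  n_lines <- attr(panel, "n_lines")
  haps <- vapply(seq_len(n_lines), function(l) {
    mine <- panel[vapply(panel$carriers, function(cs) l %in% cs, logical(1)), ]
    apply_variants(genome, mine)
  }, character(1))
  stats::setNames(haps, paste0("line_", seq_len(n_lines)))
}

# Lift reference coordinates onto a haplotype defined by `variants`
# (non-overlapping, sorted or not). Positions deleted on the haplotype map to
# NA. Insertions at position p shift all coordinates >= p.
lift_to_hap <- function(variants, gpos) {
  if (nrow(variants) == 0L) return(as.integer(gpos))
  v <- variants[order(variants$pos), ]
  out <- integer(length(gpos))
  for (j in seq_along(gpos)) {
    p <- gpos[[j]]
    before <- v$pos + v$nd - 1L < p & v$nd > 0L | (v$nd == 0L & v$pos <= p)
    inside <- v$nd > 0L & v$pos <= p & p <= v$pos + v$nd - 1L
    if (any(inside)) { out[[j]] <- NA_integer_; next }
    out[[j]] <- p + sum(v$ni[before] - v$nd[before])
  }
  out
}

#' Folded neutral site-frequency spectrum
#'
#' Analytic expectation under the standard neutral model for a sample of `n`
#' haploid lines: the expected proportion of variants with minor allele count
#' `i` is proportional to `(1/i + 1/(n-i)) / (1 + [i == n-i])`.
#'
#' @param n_lines Number of lines.
#' @return Tibble with `minor_count` and `expected_prop` (summing to 1).
#' @export
neutral_folded_sfs <- function(n_lines) {
  i <- seq_len(floor(n_lines / 2))
  w <- (1 / i + 1 / (n_lines - i)) / (1 + (i == n_lines - i))
  tibble(minor_count = i, expected_prop = w / sum(w))
}
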