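#' Place reads on a reference genome
#'
#' Exact k-mer seeding (three seed offsets per read, both orientations)
#' followed by bounded-mismatch gapless extension at each candidate locus.
#' Reads with more than one equally good best locus are marked `ambiguous`
#' and excluded from downstream voting; reads whose best placement exceeds
#' the mismatch cap are `unplaced`.
#'
#' @param reads Tibble with `read_id` and `seq` (e.g. from [sim_reads()]).
#' @param genome Reference sequence.
#' @param k Seed length.
#' @param cap Mismatch cap; defaults to 10% of the read length, rounded up.
#' @return Tibble: `read_id`, `status` (`placed` / `ambiguous` / `unplaced`),
#'   `pos` (1-based placement of the read's first base in genome forward
#'   orientation), `strand`, `mismatches`.
#' @export
place_reads <- function(reads, genome, k = 24L, cap = NULL) {
  g <- as.character(genome)
  gl <- nchar(g)
  rl <- nchar(reads$seq)
  if (any(rl > gl)) abort("read longer than the genome")
  cap <- cap %||% ceiling(0.1 * max(rl))
  n <- nrow(reads)
  fwd <- reads$seq
  rev <- revcomp(fwd)
  seed_offs <- function(len) unique(pmax(1L, c(1L, (len - k) %/% 2L + 1L, len - k + 1L)))
  # collect (read, strand, offset) seed triples; reads are typically uniform
  # length so offsets are shared
  seeds <- character(0); m_read <- integer(0); m_strand <- character(0)
  m_off <- integer(0)
  for (strand in c("+", "-")) {
    sq <- if (strand == "+") fwd else rev
    for (o in seed_offs(min(rl))) {
      seeds <- c(seeds, substring(sq, o, o + k - 1L))
      m_read <- c(m_read, seq_len(n))
      m_strand <- c(m_strand, rep(strand, n))
      m_off <- c(m_off, rep(o, n))
    }
  }
  ok <- nchar(seeds) == k
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[ok]))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(g))
  starts <- Biostrings::startIndex(hits)
  nh <- vapply(starts, length, integer(1))
  midx <- which(ok)
  cand <- tibble(read = rep(m_read[midx], nh),
                 strand = rep(m_strand[midx], nh),
                 pos = unlist(starts) - rep(m_off[midx], nh) + 1L)
  out <- tibble(read_id = reads$read_id, status = "unplaced",
                pos = NA_integer_, strand = NA_character_,
                mismatches = NA_integer_)
  if (nrow(cand) == 0L) return(out)
  cand <- distinct(cand, .data$read, .data$strand, .data$pos)
  cand <- cand[cand$pos >= 1L & cand$pos + rl[cand$read] - 1L <= gl, ]
  if (nrow(cand) == 0L) return(out)
  rseq <- ifelse(cand$strand == "+", fwd[cand$read], rev[cand$read])
  gsub_ <- substring(g, cand$pos, cand$pos + rl[cand$read] - 1L)
  cand$mm <- hamming(rseq, gsub_)
  cand <- cand[cand$mm <= cap, ]
  if (nrow(cand) == 0L) return(out)
  best <- cand |>
    group_by(.data$read) |>
    filter(.data$mm == min(.data$mm)) |>
    ungroup()
  tallies <- count(best, .data$read, name = "n_best")
  uni <- tallies$read[tallies$n_best == 1L]
  amb <- tallies$read[tallies$n_best > 1L]
  b1 <- best[best$read %in% uni, ]
  out$status[amb] <- "ambiguous"
  out$status[b1$read] <- "placed"
  out$pos[b1$read] <- b1$pos
  out$strand[b1$read] <- b1$strand
  out$mismatches[b1$read] <- b1$mm
  out
}

#' Allele context for a candidate site
#'
#' Builds the candidate allele sequences for vote-based genotyping: the
#' reference allele and every population-discovered alternative allele at the
#' site, each embedded in identical reference flanks.
#'
#' @param genome Reference sequence.
#' @param pos,ref 1-based start and reference allele of the site (`ref = ""`
#'   for pure insertion sites).
#' @param alts Character vector of alternative allele sequences.
#' @param flank Flank length; one read length guarantees any read overlapping
#'   the site can be scored in full.
#' @return An `allele_context` list: `pos`, `ref`, `alleles` (named character,
#'   `"0"` = reference), `flank`, `span` (genomic interval of the site).
#' @export
allele_context <- function(genome, pos, ref, alts, flank = 100L) {
  g <- as.character(genome)
  nd <- nchar(ref)
  lf <- substr(g, max(1L, pos - flank), pos - 1L)
  rs <- pos + nd
  rf <- substr(g, rs, min(nchar(g), rs + flank - 1L))
  if (nd > 0L && substr(g, pos, pos + nd - 1L) != ref) {
    abort("reference allele disagrees with the genome")
  }
  alleles <- c("0" = paste0(lf, ref, rf),
               stats::setNames(paste0(lf, alts, rf), seq_along(alts)))
  if (anyDuplicated(alleles)) abort("candidate allele sequences must be distinct")
  structure(list(pos = pos, ref = ref, alleles = alleles, flank = flank,
                 span = c(pos, pos + max(nd, 1L) - 1L)),
            class = "allele_context")
}

#' Score reads against the candidate alleles of a site
#'
#' Gapless alignment of each read at every offset of every candidate allele
#' sequence; the score is the minimum mismatch count over offsets. Scores
#' above the cap become `NA` (no alignment).
#'
#' @param seqs Character vector of read sequences, oriented to the genome
#'   forward strand.
#' @param context An [allele_context()].
#' @param cap Mismatch cap; defaults to 10% of read length, rounded up.
#' @return Integer matrix, reads x alleles.
#' @export
score_reads <- function(seqs, context, cap = NULL) {
  if (!length(context$alleles)) abort("empty candidate allele list")
  cap <- cap %||% ceiling(0.1 * max(nchar(seqs)))
  m <- matrix(NA_integer_, length(seqs), length(context$alleles),
              dimnames = list(NULL, names(context$alleles)))
  ctx <- lapply(context$alleles, Biostrings::DNAString)
  for (i in seq_along(seqs)) {
    r <- Biostrings::DNAString(seqs[[i]])
    rl <- length(r)
    for (a in seq_along(ctx)) {
      cl <- length(ctx[[a]])
      if (cl < rl) next
      ed <- Biostrings::neditStartingAt(r, ctx[[a]], starting.at = 1:(cl - rl + 1L),
                                        with.indels = FALSE)
      mn <- min(ed)
      if (mn <= cap) m[i, a] <- mn
    }
  }
  m
}

#' Tally allele votes from scored reads
#'
#' Each read with a unique minimum-mismatch allele casts one positive vote for
#' that allele and one negative vote for every other candidate; reads tied
#' between two or more alleles abstain entirely.
#'
#' @param scores Matrix from [score_reads()].
#' @return A `vote_tally` tibble: `allele`, `pos_votes`, `neg_votes`, with
#'   attribute `n_informative` (number of voting reads).
#' @export
tally_votes <- function(scores) {
  k <- ncol(scores)
  pos <- integer(k); neg <- integer(k)
  informative <- 0L
  for (i in seq_len(nrow(scores))) {
    s <- scores[i, ]
    if (all(is.na(s))) next
    mn <- min(s, na.rm = TRUE)
    best <- which(!is.na(s) & s == mn)
    if (length(best) != 1L) next  # tie: abstain
    informative <- informative + 1L
    pos[best] <- pos[best] + 1L
    neg[-best] <- neg[-best] + 1L
  }
  structure(tibble(allele = colnames(scores), pos_votes = pos, neg_votes = neg),
            class = c("vote_tally", class(tibble())),
            n_informative = informative)
}

#' Update variant calls from a vote tally
#'
#' A new call for a non-reference allele is made when its positive votes
#' exceed its negative votes by at least one; an existing call is removed when
#' its positive votes are not greater than half its negative votes (real
#' halving); otherwise the status is unchanged. Vote counts are carried along
#' as tags on the call record.
#'
#' @param tally A `vote_tally`.
#' @param existing Character vector of allele ids already called for this
#'   line (from earlier discovery stages).
#' @return Tibble: `allele`, `existing`, `pos_votes`, `neg_votes`, `called`.
#' @export
update_calls <- function(tally, existing = character(0)) {
  tb <- as_tibble(tally)
  tb$existing <- tb$allele %in% as.character(existing)
  # removal needs actual negative evidence: with zero votes of either sign
  # nothing changes
  tb$called <- ifelse(
    tb$existing,
    !(tb$neg_votes > 0L & tb$pos_votes <= tb$neg_votes / 2),
    tb$pos_votes >= tb$neg_votes + 1L)
  tb$called[tb$allele == "0"] <- NA  # the reference allele is not "called"
  tb[, c("allele", "existing", "pos_votes", "neg_votes", "called")]
}

#' Candidate sites for genotyping from a population call set
#'
#' Merges overlapping variants into sites ([group_alleles()] with no carrier
#' minimum) and spells out every population-discovered allele of each site as
#' an explicit sequence over the site span, so vote-based genotyping always
#' competes all alleles of a locus jointly (a read carrying a deletion must
#' not be credited to a SNP inside the deleted span).
#'
#' @param panel A `variant_panel` (the combined call set of all lines).
#' @param genome Reference sequence.
#' @return Tibble: `site_id`, `pos` (site start), `ref` (reference allele over
#'   the site span), `alts` (list-column of alternative allele sequences,
#'   named by allele id), `members` (list-column: variant ids per alternative
#'   allele), `line_allele` (list-column: true allele id per line).
#' @export
candidate_sites <- function(panel, genome) {
  g <- as.character(genome)
  ga <- group_alleles(panel, transcripts = NULL, min_lines = 1L)
  st <- ga$sites
  rows <- lapply(seq_len(nrow(st)), function(i) {
    s <- st$start[[i]]; e <- st$end[[i]]
    span_ref <- substr(g, s, e)
    al <- st$alleles[[i]]
    alt_ids <- al$allele_id[al$allele_id > 0L]
    alts <- vapply(alt_ids, function(a) {
      mem <- panel[panel$variant_id %in% al$members[[a + 1L]], ]
      mem$pos <- mem$pos - s + 1L
      apply_variants(span_ref, mem)
    }, character(1))
    tibble(site_id = st$site_id[[i]], pos = s, ref = span_ref,
           alts = list(stats::setNames(alts, alt_ids)),
           members = list(stats::setNames(al$members[al$allele_id > 0L],
                                          alt_ids)),
           line_allele = st$line_allele[i])
  })
  bind_rows(rows)
}

#' Genotype one line at candidate sites by differential read alignment
#'
#' Runs the full vote-based genotyping stage for one line: reads are placed on
#' the reference, reads overlapping each candidate site are scored against
#' the site's population-wide candidate alleles, votes are tallied, and calls
#' are made or removed by the vote rules.
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param genome Reference sequence.
#' @param sites Tibble of candidate sites: `site_id`, `pos`, `ref`, and
#'   `alts` (list-column of alternative allele character vectors).
#' @param existing Optional tibble of existing calls: `site_id`, `allele`.
#' @param placements Optional precomputed [place_reads()] result.
#' @param flank Flank length for allele contexts (default one read length).
#' @param cap Mismatch cap for allele scoring (default 10% of read length).
#' @param place_cap Mismatch cap for the initial reference placement. A read
#'   spanning an indel mismatches the reference at up to half its length
#'   downstream of the breakpoint under gapless alignment, so placement is
#'   deliberately tolerant (default 45% of read length) while allele scoring
#'   keeps the strict cap; loosely placed reads that fit no candidate allele
#'   simply cannot vote.
#' @return Tibble with one row per site and allele: `site_id`, `allele`,
#'   `existing`, `pos_votes`, `neg_votes`, `called`, `n_informative`.
#' @export
genotype_line <- function(reads, genome, sites, existing = NULL,
                          placements = NULL, flank = NULL, cap = NULL,
                          place_cap = NULL) {
  rl <- max(nchar(reads$seq))
  flank <- flank %||% rl
  place_cap <- place_cap %||% ceiling(0.45 * rl)
  placements <- placements %||% place_reads(reads, genome, cap = place_cap)
  placed <- placements[placements$status == "placed", ]
  placed$seq <- ifelse(placed$strand == "+",
                       reads$seq[match(placed$read_id, reads$read_id)],
                       revcomp(reads$seq[match(placed$read_id, reads$read_id)]))
  res <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ctx <- allele_context(genome, sites$pos[[i]], sites$ref[[i]],
                          sites$alts[[i]], flank = flank)
    lo <- ctx$span[[1]] - rl + 1L
    hi <- ctx$span[[2]] + rl - 1L
    near <- placed[placed$pos >= lo & placed$pos <= hi, ]
    sc <- score_reads(near$seq, ctx, cap = cap)
    tl <- tally_votes(sc)
    ex <- if (is.null(existing)) character(0) else
      existing$allele[existing$site_id == sites$site_id[[i]]]
    calls <- update_calls(tl, ex)
    calls$site_id <- sites$site_id[[i]]
    calls$n_informative <- attr(tl, "n_informative")
    res[[i]] <- calls
  }
  bind_rows(res) |>
    select("site_id", "allele", "existing", "pos_votes", "neg_votes",
           "called", "n_informative")
}
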