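#' Simulate a reference genome
#'
#' Draws a single autosome-like contig of i.i.d. bases at the configured GC
#' fraction. Deterministic for a given `config$seed` (substream `"genome"`).
#'
#' @param config A [sim_config()].
#' @return A character scalar with attributes `contig` (the contig name,
#'   `"sim1"`) and `class` `"sim_genome"`.
#' @export
#' @examples
#' g <- sim_genome(sim_config(seed = 1, genome_length = 1000))
#' nchar(g)
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length <= 0) abort("genome length must be positive")
  seq <- with_substream(config$seed, "genome", code = {
    random_dna(config$genome_length, config$gc_fraction)
  })
  structure(seq, contig = "sim1", class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> contig", attr(x, "contig"), "-", nchar(x), "bp\n")
  invisible(x)
}

# Codons that never terminate translation, used to write clean ORFs.
.sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- apply(expand.grid(b, b, b), 1, paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Simulate a transcript annotation
#'
#' Places non-overlapping transcripts on both strands, each with a 5' UTR, a
#' clean open reading frame (ATG start, no internal stop, terminal stop codon),
#' a 3' UTR, and one intron with canonical GT..AG splice dinucleotides. The
#' generated gene sequences are written into the returned copy of the genome,
#' so that coding-consequence predictions can be checked against honest
#' translation.
#'
#' @param genome A [sim_genome()] sequence.
#' @param config A [sim_config()].
#' @return A list with elements `transcripts` (a tibble with one row per
#'   transcript: id, contig, 1-based `start`/`end`, `strand`, `tss`, `tes`,
#'   `exons` list-column of genomic exon intervals in transcript order,
#'   `utr5_len`, `cds_len`, `tx_len`) and `genome` (the genome with gene
#'   sequences embedded).
#' @export
sim_transcripts <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transcripts
  contig <- attr(genome, "contig") %||% "sim1"
  if (n == 0L) {
    return(list(transcripts = empty_transcripts(), genome = genome))
  }
  L <- nchar(genome)
  res <- with_substream(config$seed, "transcripts", code = {
    utr5 <- sample(40:120, n, replace = TRUE)
    ncod <- sample(60:180, n, replace = TRUE)
    utr3 <- sample(40:120, n, replace = TRUE)
    ilen <- sample(60:200, n, replace = TRUE)
    glen <- utr5 + 3L * (ncod + 2L) + utr3 + ilen
    gap <- 400L
    need <- sum(glen) + gap * (n + 1L) + 2L * config$margin
    if (need > L) {
      abort(sprintf("%d transcripts need %d bp but genome has %d",
                    n, need, L))
    }
    # random left-to-right placement: distribute the slack among n+1 gaps
    slack <- L - 2L * config$margin - sum(glen) - gap * (n + 1L)
    cuts <- sort(sample.int(slack + 1L, n + 1L, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))
    starts <- integer(n)
    cur <- config$margin + gap + extra[[1]]
    rows <- vector("list", n)
    g <- as.character(genome)
    for (i in seq_len(n)) {
      starts[[i]] <- cur + 1L
      strand <- sample(c("+", "-"), 1L)
      cds <- paste0("ATG",
                    paste(sample(.sense_codons, ncod[[i]], replace = TRUE),
                          collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      tx <- paste0(random_dna(utr5[[i]], config$gc_fraction), cds,
                   random_dna(utr3[[i]], config$gc_fraction))
      tx_len <- nchar(tx)
      sp <- sample(seq_len(tx_len - 1L), 1L)  # exon1 = tx[1..sp]
      intron <- paste0("GT", random_dna(ilen[[i]] - 4L, config$gc_fraction), "AG")
      gseq <- paste0(substr(tx, 1L, sp), intron, substr(tx, sp + 1L, tx_len))
      gl <- nchar(gseq)
      stopifnot(gl == glen[[i]])
      s <- starts[[i]]
      e <- s + gl - 1L
      if (strand == "+") {
        exons <- tibble(start = c(s, s + sp + ilen[[i]]),
                        end = c(s + sp - 1L, e))
      } else {
        gseq <- revcomp(gseq)
        # transcript order: first exon is at the genomic 3' end
        exons <- tibble(start = c(e - sp + 1L, s),
                        end = c(e, s + (tx_len - sp) - 1L))
      }
      substr(g, s, e) <- gseq
      rows[[i]] <- tibble(
        transcript_id = sprintf("tx%03d", i),
        contig = contig, start = s, end = e, strand = strand,
        tss = if (strand == "+") s else e,
        tes = if (strand == "+") e else s,
        exons = list(exons),
        utr5_len = utr5[[i]], cds_len = 3L * (ncod[[i]] + 2L),
        tx_len = tx_len)
      cur <- e + gap + extra[[i + 1L]]
    }
    list(tb = bind_rows(rows), g = g)
  })
  genome_out <- structure(res$g, contig = contig, class = "sim_genome")
  list(transcripts = res$tb, genome = genome_out)
}

empty_transcripts <- function() {
  tibble(transcript_id = character(), contig = character(),
         start = integer(), end = integer(), strand = character(),
         tss = integer(), tes = integer(), exons = list(),
         utr5_len = integer(), cds_len = integer(), tx_len = integer())
}

# Exon table of one transcript with cumulative transcript-coordinate offsets.
# Exons are stored in transcript order; `tx_start` is the transcript coordinate
# of the exon's first base (5' end on the transcript strand).
exon_map <- function(tx_row) {
  ex <- tx_row$exons[[1]]
  w <- ex$end - ex$start + 1L
  ex$tx_start <- cumsum(c(1L, utils::head(w, -1L)))
  ex$tx_end <- ex$tx_start + w - 1L
  ex
}

# Map a genomic position to a transcript coordinate (NA when intronic or
# outside the transcript).
genome_to_tx <- function(tx_row, gpos) {
  ex <- exon_map(tx_row)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- gpos >= ex$start[[i]] & gpos <= ex$end[[i]]
    if (tx_row$strand == "+") {
      out[hit] <- ex$tx_start[[i]] + (gpos[hit] - ex$start[[i]])
    } else {
      out[hit] <- ex$tx_start[[i]] + (ex$end[[i]] - gpos[hit])
    }
  }
  out
}

# Spliced transcript sequence from an arbitrary genome string.
spliced_seq <- function(tx_row, genome) {
  ex <- tx_row$exons[[1]]
  parts <- substring(as.character(genome), ex$start, ex$end)
  if (tx_row$strand == "+") paste(parts, collapse = "")
  else paste(revcomp(parts), collapse = "")
}

# Intron intervals (genomic, 1-based inclusive) of one transcript.
intron_intervals <- function(tx_row) {
  ex <- tx_row$exons[[1]][order(tx_row$exons[[1]]$start), , drop = FALSE]
  if (nrow(ex) < 2L) return(tibble(start = integer(), end = integer()))
  tibble(start = utils::head(ex$end, -1L) + 1L,
         end = utils::tail(ex$start, -1L) - 1L)
}
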