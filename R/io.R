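# Format boundaries: FASTA/FASTQ through Biostrings, VCF written natively
# (anchor-base convention) and read back through vcfR, GFF3 through
# rtracklayer, SAM as minimal single-end records. Internal coordinates are
# 1-based inclusive; conversion to the standards happens only here.

#' Write / read FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read FASTQ
#'
#' Read names carry the truth tags of [sim_reads()] (`read_id` plus origin
#' fields), so reads written and re-read keep their provenance.
#'
#' @param reads Read tibble from [sim_reads()].
#' @param path Output file.
#' @return `read_fastq()` returns a tibble with `read_id` and `seq` (plus
#'   origin fields parsed back from the names when present).
#' @export
write_fastq <- function(reads, path) {
  ids <- sprintf("%s|hs:%d|st:%s", reads$read_id, reads$hap_start, reads$strand)
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, ids))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- names(x)
  parts <- stringr::str_match(nm, "^([^|]+)(?:\\|hs:(-?\\d+)\\|st:([+-]))?")
  tibble(read_id = parts[, 2], seq = unname(as.character(x)),
         hap_start = as.integer(parts[, 3]), strand = parts[, 4])
}

#' Write a variant panel as multi-sample VCF
#'
#' One record per variant with haploid GT columns per line. SNPs and balanced
#' or unbalanced substitutions are written at their own position; pure indels
#' use the standard anchor-base convention (the preceding reference base is
#' prepended to both alleles and POS moves one left). Vote tags, when present
#' (`pos_votes`/`neg_votes` columns), are emitted in INFO.
#'
#' @param panel A `variant_panel` (normalized).
#' @param genome Reference sequence (for anchor bases and the contig header).
#' @param path Output file.
#' @export
write_vcf <- function(panel, genome, path) {
  g <- as.character(genome)
  n_lines <- attr(panel, "n_lines")
  contig <- attr(panel, "contig") %||% "sim1"
  pure <- xor(panel$nd == 0L, panel$ni == 0L)
  if (any(pure & panel$pos < 2L)) {
    abort("indel at contig start cannot be anchored in VCF")
  }
  anchor <- ifelse(pure, substring(g, panel$pos - 1L, panel$pos - 1L), "")
  pos <- ifelse(pure, panel$pos - 1L, panel$pos)
  ref <- paste0(anchor, panel$ref)
  alt <- paste0(anchor, panel$alt)
  gt <- vapply(seq_len(nrow(panel)), function(i) {
    paste(ifelse(seq_len(n_lines) %in% panel$carriers[[i]], "1", "0"),
          collapse = "\t")
  }, character(1))
  info <- if (all(c("pos_votes", "neg_votes") %in% names(panel))) {
    sprintf("PV=%d;NV=%d", panel$pos_votes, panel$neg_votes)
  } else rep(".", nrow(panel))
  header <- c(
    "##fileformat=VCFv4.3",
    sprintf("##contig=<ID=%s,length=%d>", contig, nchar(g)),
    "##INFO=<ID=PV,Number=1,Type=Integer,Description=\"Positive genotyping votes\">",
    "##INFO=<ID=NV,Number=1,Type=Integer,Description=\"Negative genotyping votes\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("line_", seq_len(n_lines))), collapse = "\t"))
  body <- paste(panel$contig, pos, panel$variant_id, ref, alt, ".", "PASS",
                info, "GT", gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF back into a variant panel
#'
#' Anchor bases shared between REF and ALT are stripped (inverting the
#' convention of [write_vcf()]); symbolic alleles are refused. Requires the
#' vcfR package.
#'
#' @param path VCF file.
#' @param genome_length Optional contig length (read from the header when
#'   absent).
#' @return A `variant_panel`.
#' @export
read_vcf <- function(path, genome_length = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) abort("vcfR is required")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl("^<", fix$ALT))) abort("symbolic alleles are not supported")
  gt <- vcfR::extract.gt(v)
  pos <- as.integer(fix$POS)
  ref <- fix$REF; alt <- fix$ALT
  anchored <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &
    (nchar(ref) > 1L | nchar(alt) > 1L)
  ref[anchored] <- substring(ref[anchored], 2L)
  alt[anchored] <- substring(alt[anchored], 2L)
  pos[anchored] <- pos[anchored] + 1L
  carriers <- lapply(seq_len(nrow(fix)), function(i) {
    unname(which(gt[i, ] == "1"))
  })
  tb <- tibble(variant_id = fix$ID, contig = fix$CHROM, pos = pos,
               ref = ref, alt = alt, nd = nchar(ref), ni = nchar(alt),
               type = NA_character_, carriers = unname(carriers),
               n_carriers = lengths(carriers))
  gl <- genome_length
  if (is.null(gl)) {
    m <- stringr::str_match(v@meta, "##contig=<ID=[^,]+,length=(\\d+)>")
    gl <- suppressWarnings(as.integer(stats::na.omit(m[, 2])[1]))
  }
  new_variant_panel(tb, n_lines = ncol(gt), genome_length = gl,
                    contig = fix$CHROM[[1]])
}

#' Write / read a transcript annotation as GFF3
#'
#' mRNA and exon features with strand; requires rtracklayer.
#'
#' @param transcripts Transcript tibble.
#' @param path GFF3 file.
#' @export
write_gff3 <- function(transcripts, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    abort("rtracklayer and GenomicRanges are required")
  }
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    rows[[length(rows) + 1L]] <-
      data.frame(contig = tx$contig, start = tx$start, end = tx$end,
                 strand = tx$strand, type = "mRNA", ID = tx$transcript_id,
                 Parent = NA_character_)
    ex <- tx$exons[[1]][order(tx$exons[[1]]$start), ]
    rows[[length(rows) + 1L]] <-
      data.frame(contig = tx$contig, start = ex$start, end = ex$end,
                 strand = tx$strand, type = "exon",
                 ID = paste0(tx$transcript_id, ":exon", seq_len(nrow(ex))),
                 Parent = tx$transcript_id)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, type = df$type, ID = df$ID, Parent = df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @return `read_gff3()` returns a transcript tibble (`tss`, `tes` and exon
#'   order recomputed from strand; CDS columns are absent).
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  mr <- df[df$type == "mRNA", ]
  rows <- lapply(seq_len(nrow(mr)), function(i) {
    id <- mr$ID[[i]]
    ex <- df[df$type == "exon" &
               vapply(df$Parent, function(p) id %in% unlist(p), logical(1)), ]
    ex <- ex[order(ex$start, decreasing = mr$strand[[i]] == "-"), ]
    tibble(transcript_id = id, contig = as.character(mr$seqnames[[i]]),
           start = mr$start[[i]], end = mr$end[[i]],
           strand = as.character(mr$strand[[i]]),
           tss = if (mr$strand[[i]] == "+") mr$start[[i]] else mr$end[[i]],
           tes = if (mr$strand[[i]] == "+") mr$end[[i]] else mr$start[[i]],
           exons = list(tibble(start = ex$start, end = ex$end)),
           utr5_len = NA_integer_, cds_len = NA_integer_,
           tx_len = sum(ex$end - ex$start + 1L))
  })
  bind_rows(rows)
}

#' Write read placements as minimal SAM
#'
#' Single-end records with reverse-strand and unmapped flags; enough for
#' external inspection of placements, not a full alignment format.
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param placements [place_reads()] result aligned to `reads`.
#' @param genome Reference sequence.
#' @param path Output file.
#' @export
write_sam <- function(reads, placements, genome, path) {
  contig <- attr(genome, "contig") %||% "sim1"
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", contig, nchar(genome)))
  rl <- nchar(reads$seq)
  mapped <- placements$status == "placed"
  flag <- ifelse(!mapped, 4L, ifelse(placements$strand == "-", 16L, 0L))
  seqout <- ifelse(!is.na(placements$strand) & placements$strand == "-",
                   revcomp(reads$seq), reads$seq)
  body <- paste(sub("/", "_", placements$read_id), flag, contig,
                ifelse(mapped, placements$pos, 0L), ifelse(mapped, 60L, 0L),
                ifelse(mapped, paste0(rl, "M"), "*"),
                "*", 0L, 0L, seqout, "*", sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read the long expression table as TSV
#'
#' @param expression Long expression tibble.
#' @param path TSV file.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    transcript_id = readr::col_character(),
                    line = readr::col_integer(),
                    sex = readr::col_character(),
                    replicate = readr::col_integer(),
                    value = readr::col_double(),
                    detected = readr::col_logical()))
}

#' Write planted truth as JSON
#'
#' @param truth List of truth tibbles (variants / eqtls / imbalance).
#' @param path JSON file.
#' @export
write_truth_json <- function(truth, path) {
  ser <- lapply(truth, function(tb) {
    if (is.data.frame(tb)) {
      tb <- as.data.frame(tb)
      for (cn in names(tb)) if (is.list(tb[[cn]])) {
        tb[[cn]] <- vapply(tb[[cn]], function(z) paste(z, collapse = ","),
                           character(1))
      }
    }
    tb
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
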