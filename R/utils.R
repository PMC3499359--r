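# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Deterministic sub-seed for a named stage. All randomness in the package flows
# from one root seed through these named substreams, so stages can be re-run
# independently and still reproduce the full-pipeline output byte for byte.
# Arithmetic stays below 2^53 so the modulus is exact in double precision.
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  label <- paste(c(...), collapse = "/")
  h <- seed %% 2147483647
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Run `code` under a stage-specific seed without disturbing the caller's RNG.
with_substream <- function(seed, ..., code) {
  withr::with_seed(substream_seed(seed, ...), code)
}

# Random DNA of length n at a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Vectorised reverse complement for plain character DNA.
revcomp <- function(x) {
  comp <- chartr("ACGTacgtN", "TGCAtgcaN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Hamming distance between pairs of equal-length strings (vectorised over pairs).
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- integer(length(a))
  for (i in seq_along(a)) {
    ra <- charToRaw(a[[i]])
    rb <- charToRaw(b[[i]])
    if (length(ra) != length(rb)) {
      abort("hamming() requires equal-length strings")
    }
    out[[i]] <- sum(ra != rb)
  }
  out
}

# Smallest period p of a string such that the string is unit^k with k = n/p.
smallest_period <- function(x) {
  n <- nchar(x)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    unit <- substr(x, 1L, p)
    if (x == strrep(unit, n %/% p)) return(p)
  }
  n
}

# Benjamini-Hochberg step-up adjustment (delegates to stats::p.adjust).
#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "BH"`, kept as a
#' named step so that every multiple-testing correction in the package goes
#' through one audited door. Errors on out-of-range input rather than
#' propagating nonsense quantiles.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
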