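# Internal helpers: seeded evaluation, CIGAR walking, DNA string utilities.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library code never leaks RNG state into the
#' caller's session. All stochastic operations in the package funnel through
#' this helper; there is no implicit global seed.
#'
#' @param seed a single finite integer-like number.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# reverse complement of plain character strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# sample a base different from `ref`; vectorized, one draw per element
other_base <- function(ref, n = length(ref)) {
  vapply(seq_len(n), function(i) sample(setdiff(DNA_BASES, ref[i]), 1L), "")
}

phred_error_prob <- function(q) 10^(-q / 10)

qual_to_string <- function(q) intToUtf8(as.integer(q) + 33L)

string_to_qual <- function(s) utf8ToInt(s) - 33L

## ---- CIGAR helpers -------------------------------------------------------
## GenomicAlignments supplies the decomposition; the site-offset walks below
## are the package's own because they need 1-based closed genomic semantics.

cigar_ops <- function(cigar) {
  list(op  = GenomicAlignments::explodeCigarOps(cigar)[[1L]],
       len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]])
}

cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# query offset (1-based, counting soft-clipped bases) of reference position
# `pos` for a read starting its aligned span at `start`; NA if `pos` falls in
# a deletion or outside the aligned span.
query_offset_at <- function(cigar, start, pos) {
  ops <- cigar_ops(cigar)
  r <- start
  q <- 1L
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (pos >= r && pos < r + len) return(q + (pos - r))
      r <- r + len
      q <- q + len
    } else if (op == "I" || op == "S") {
      q <- q + len
    } else if (op == "D" || op == "N") {
      if (pos >= r && pos < r + len) return(NA_integer_)
      r <- r + len
    }
  }
  NA_integer_
}

# first and last query offsets that are reference-aligned (M/=/X)
aligned_query_bounds <- function(cigar) {
  ops <- cigar_ops(cigar)
  q <- 1L
  first <- NA_integer_
  last <- NA_integer_
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (is.na(first)) first <- q
      last <- q + len - 1L
      q <- q + len
    } else if (op == "I" || op == "S") {
      q <- q + len
    }
  }
  c(first, last)
}

# (qpos, rpos) pairs for every reference-aligned base of a read
aligned_pairs <- function(cigar, start) {
  ops <- cigar_ops(cigar)
  r <- start
  q <- 1L
  qpos <- integer(0)
  rpos <- integer(0)
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      qpos <- c(qpos, q:(q + len - 1L))
      rpos <- c(rpos, r:(r + len - 1L))
      r <- r + len
      q <- q + len
    } else if (op == "I" || op == "S") {
      q <- q + len
    } else if (op == "D" || op == "N") {
      r <- r + len
    }
  }
  list(qpos = qpos, rpos = rpos)
}

# indel operations of a read: query-side boundary offset and reference span
read_indels <- function(cigar, start) {
  ops <- cigar_ops(cigar)
  r <- start
  q <- 1L
  out <- list()
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      r <- r + len
      q <- q + len
    } else if (op == "S") {
      q <- q + len
    } else if (op == "I") {
      out[[length(out) + 1L]] <- list(op = "I", qpos = q, ref_start = r, ref_end = r)
      q <- q + len
    } else if (op == "D" || op == "N") {
      out[[length(out) + 1L]] <- list(op = "D", qpos = q, ref_start = r, ref_end = r + len - 1L)
      r <- r + len
    }
  }
  out
}

has_softclip <- function(cigar) grepl("S", cigar, fixed = TRUE)

has_indel_op <- function(cigar) grepl("[ID]", cigar)
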