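## Read-level classification of alt-supporting base-calls (RBSM) and
## high-confidence candidate selection.

#' Extract the pileup at a site from alignment records
#'
#' One row per read with an aligned (non-deleted) base over `pos`:
#' the base, its Phred quality, the read's mapping quality, the query
#' offset of the site, the aligned query bounds, and artifact marks.
#'
#' @param reads alignment record `data.frame`.
#' @param chrom,pos site (1-based).
#' @return a pileup `data.frame`.
#' @export
pileup_at <- function(reads, chrom, pos) {
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  idx <- which(reads$chrom == chrom & reads$pos <= pos &
                 reads$pos + span - 1L >= pos)
  rows <- lapply(idx, function(i) {
    off <- query_offset_at(reads$cigar[i], reads$pos[i], pos)
    if (is.na(off)) return(NULL)
    ab <- aligned_query_bounds(reads$cigar[i])
    data.frame(
      read = i, qname = reads$qname[i],
      base = substring(reads$seq[i], off, off),
      bq = utf8ToInt(substring(reads$qual[i], off, off)) - 33L,
      mapq = reads$mapq[i], offset = off,
      aligned_first = ab[1L], aligned_last = ab[2L],
      cigar = reads$cigar[i],
      has_xa = !is.na(reads$xa[i]),
      has_softclip = has_softclip(reads$cigar[i]),
      realigned = isTRUE_vec(reads$realigned[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read = integer(0), qname = character(0),
                      base = character(0), bq = integer(0), mapq = integer(0),
                      offset = integer(0), aligned_first = integer(0),
                      aligned_last = integer(0), cigar = character(0),
                      has_xa = logical(0), has_softclip = logical(0),
                      realigned = logical(0))
  }
  out
}

# does any read of the pileup carry an indel operation whose reference
# footprint touches [pos - window, pos + window]?
pileup_indel_nearby <- function(reads, chrom, pos, window = 15L) {
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  idx <- which(reads$chrom == chrom & has_indel_op(reads$cigar) &
                 reads$pos <= pos + window &
                 reads$pos + span - 1L >= pos - window)
  for (i in idx) {
    for (ind in read_indels(reads$cigar[i], reads$pos[i])) {
      if (ind$ref_start <= pos + window && ind$ref_end >= pos - window) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Classify alt-supporting base-calls against the seven RBSM criteria
#'
#' A Reliable Base-call supporting Somatic Mutation (RBSM) is an
#' alt-supporting base-call passing all of:
#' \enumerate{
#'   \item base quality >= 25;
#'   \item read mapping quality >= 30;
#'   \item not within the 10-base edge zones of the read (the site must sit
#'     at least 11 aligned query bases from either aligned end);
#'   \item no other mismatch to the reference and no indel operation within
#'     ±15 query bases on the same read;
#'   \item no XA alternative-alignment tag on the read;
#'   \item no soft-clip operation anywhere in the read's CIGAR;
#'   \item not attributable to indel realignment: the read is not marked as
#'     indel-realigned and no read of the local pileup carries an indel
#'     operation within ±15 bp of the site (a testable proxy for
#'     realignment-induced support; swap via `pileup_indel_window`).
#' }
#'
#' @param reads alignment record `data.frame` (the case sample's pileup
#'   source).
#' @param genome genome (`twin_reference` or named character vector), used
#'   for the criterion-(iv) mismatch scan.
#' @param chrom,pos,alt candidate site and alternate base.
#' @param bq_min,mapq_min,edge,mm_window,pileup_indel_window criterion
#'   thresholds (defaults 25, 30, 10, 15, 15).
#' @return `data.frame`, one row per alt-supporting base-call, with logical
#'   columns `crit_i` … `crit_vii` (TRUE = criterion satisfied), `is_rbsm`,
#'   and `failed` (comma-separated failed criteria, empty iff RBSM).
#' @export
classify_base_call <- function(reads, genome, chrom, pos, alt,
                               bq_min = 25, mapq_min = 30, edge = 10L,
                               mm_window = 15L, pileup_indel_window = 15L) {
  pile <- pileup_at(reads, chrom, pos)
  if (nrow(pile) == 0L) {
    stop(sprintf("no read covers %s:%d", chrom, pos), call. = FALSE)
  }
  genome <- as_genome(genome)
  vii_pileup_fail <- pileup_indel_nearby(reads, chrom, pos,
                                         pileup_indel_window)
  alt_rows <- which(pile$base == alt)
  res <- lapply(alt_rows, function(r) {
    i <- pile$read[r]
    c_i <- pile$bq[r] >= bq_min
    c_ii <- pile$mapq[r] >= mapq_min
    d_left <- pile$offset[r] - pile$aligned_first[r] + 1L
    d_right <- pile$aligned_last[r] - pile$offset[r] + 1L
    c_iii <- d_left >= edge + 1L && d_right >= edge + 1L
    # (iv): scan the aligned bases of this read for non-candidate
    # mismatches, and its CIGAR for indel operations, within the query window
    ap <- aligned_pairs(reads$cigar[i], reads$pos[i])
    inwin <- abs(ap$qpos - pile$offset[r]) <= mm_window
    qb <- substring(reads$seq[i], ap$qpos[inwin], ap$qpos[inwin])
    gb <- substring(genome[[chrom]], ap$rpos[inwin], ap$rpos[inwin])
    mm <- qb != gb & ap$rpos[inwin] != pos
    ind_near <- FALSE
    if (has_indel_op(reads$cigar[i])) {
      for (ind in read_indels(reads$cigar[i], reads$pos[i])) {
        if (abs(ind$qpos - pile$offset[r]) <= mm_window) ind_near <- TRUE
      }
    }
    c_iv <- !any(mm) && !ind_near
    c_v <- !pile$has_xa[r]
    c_vi <- !pile$has_softclip[r]
    c_vii <- !pile$realigned[r] && !vii_pileup_fail
    ok <- c(i = c_i, ii = c_ii, iii = c_iii, iv = c_iv, v = c_v,
            vi = c_vi, vii = c_vii)
    data.frame(
      qname = pile$qname[r], base = pile$base[r], bq = pile$bq[r],
      mapq = pile$mapq[r], offset = pile$offset[r],
      crit_i = c_i, crit_ii = c_ii, crit_iii = c_iii, crit_iv = c_iv,
      crit_v = c_v, crit_vi = c_vi, crit_vii = c_vii,
      is_rbsm = all(ok),
      failed = paste(names(ok)[!ok], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(qname = character(0), base = character(0),
                      bq = integer(0), mapq = integer(0), offset = integer(0),
                      crit_i = logical(0), crit_ii = logical(0),
                      crit_iii = logical(0), crit_iv = logical(0),
                      crit_v = logical(0), crit_vi = logical(0),
                      crit_vii = logical(0), is_rbsm = logical(0),
                      failed = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Count reliable alt-supporting base-calls (RBSM count) at a site
#'
#' @inheritParams classify_base_call
#' @param ... passed to [classify_base_call()].
#' @return a non-negative integer, never exceeding the alt depth; 0 when no
#'   read covers the site or no alt call exists.
#' @export
count_rbsm <- function(reads, genome, chrom, pos, alt, ...) {
  v <- tryCatch(classify_base_call(reads, genome, chrom, pos, alt, ...),
                error = function(e) NULL)
  if (is.null(v)) 0L else sum(v$is_rbsm)
}

#' Select high-confidence (HC) candidate sites
#'
#' A candidate is HC iff its RBSM count is at least `min_rbsm` (default 2)
#' and its sequence context is not difficult (no short tandem repeat or
#' poly-A/T run overlapping the context window).
#'
#' @param candidates `data.frame` with `chrom`, `pos`, `rbsm_count` and
#'   `seqcontext_difficult` columns.
#' @param min_rbsm inclusive RBSM count threshold.
#' @return the table sorted by (`chrom`, `pos`) with an `is_hc` column.
#' @export
select_hc <- function(candidates, min_rbsm = 2L) {
  stopifnot(all(c("chrom", "pos", "rbsm_count", "seqcontext_difficult") %in%
                  names(candidates)))
  out <- candidates
  out$is_hc <- out$rbsm_count >= min_rbsm & !out$seqcontext_difficult
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
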