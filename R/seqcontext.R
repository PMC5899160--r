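#' Detect a difficult sequencing context around a site
#'
#' A site's context is difficult when a short tandem repeat or a
#' poly-A/poly-T homopolymer run overlaps the ±`window` bp window around
#' it — the contexts where slippage makes low-fraction alt calls
#' unreliable. Detection parameters:
#' \itemize{
#'   \item poly-A: an A or T run of at least `polyA_min_run` bases
#'     (poly-T is included by strand symmetry);
#'   \item STR: a tandem run with unit length in
#'     `[str_min_unit, str_max_unit]`, at least `str_min_copies` contiguous
#'     copies, and total run length at least `str_min_len` bases. The
#'     total-length floor keeps 4-base homopolymers (unit 1, 4 copies)
#'     from flagging effectively every window; unit-1 runs therefore need
#'     `str_min_len` copies, coinciding with the homopolymer rule.
#' }
#' Homopolymer A/T runs are reported as `polyA`; every other tandem run as
#' `str`. Detection is deterministic.
#'
#' @param genome genome (`twin_reference` or named character vector).
#' @param chrom,pos site (1-based).
#' @param window context half-width in bases.
#' @param str_min_unit,str_max_unit,str_min_copies,str_min_len STR
#'   detector parameters.
#' @param polyA_min_run homopolymer run threshold.
#' @return list with `is_difficult`, `reason` (`"str"`, `"polyA"` or
#'   `"none"`), and the examined `context_start`/`context_end` window.
#' @export
detect_difficult_seqcontext <- function(genome, chrom, pos, window = 15L,
                                        str_min_unit = 1L, str_max_unit = 6L,
                                        str_min_copies = 4L, str_min_len = 8L,
                                        polyA_min_run = 8L) {
  genome <- as_genome(genome)
  L <- nchar(genome[[chrom]])
  stopifnot(pos >= 1L, pos <= L)
  win_s <- max(1L, pos - window)
  win_e <- min(L, pos + window)
  # a run overlapping the window can start well before it; scan an extended
  # region long enough to contain any qualifying run touching the window
  reach <- max(polyA_min_run, str_max_unit * (str_min_copies + 1L), str_min_len)
  ext_s <- max(1L, win_s - reach)
  ext_e <- min(L, win_e + reach)
  ctx <- strsplit(substring(genome[[chrom]], ext_s, ext_e), "")[[1L]]
  nc <- length(ctx)
  overlaps_win <- function(run_s, run_e) {
    (ext_s + run_s - 1L) <= win_e && (ext_s + run_e - 1L) >= win_s
  }

  # homopolymer A/T runs
  r <- rle(ctx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k] %in% c("A", "T") && r$lengths[k] >= polyA_min_run &&
        overlaps_win(starts[k], ends[k])) {
      return(list(is_difficult = TRUE, reason = "polyA",
                  context_start = win_s, context_end = win_e))
    }
  }

  # tandem repeats: every unit length and phase in the extended region
  for (u in max(1L, str_min_unit):str_max_unit) {
    s <- 1L
    while (s + u - 1L <= nc) {
      k <- 1L
      while (s + (k + 1L) * u - 1L <= nc &&
             identical(ctx[(s + k * u):(s + (k + 1L) * u - 1L)],
                       ctx[s:(s + u - 1L)])) {
        k <- k + 1L
      }
      if (k >= str_min_copies && k * u >= str_min_len &&
          overlaps_win(s, s + k * u - 1L)) {
        return(list(is_difficult = TRUE, reason = "str",
                    context_start = win_s, context_end = win_e))
      }
      s <- s + 1L
    }
  }
  list(is_difficult = FALSE, reason = "none",
       context_start = win_s, context_end = win_e)
}
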