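#' Interval region sets for candidate exclusion
#'
#' A `region_set` is a labelled, sorted, overlap-merged collection of
#' 1-based closed genomic intervals (backed by a
#' [GenomicRanges::GRanges]), used for the multi-copy-region and
#' indel-proximity exclusion filters. Membership queries are overlap
#' lookups on the reduced ranges.
#'
#' @param intervals a `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based closed) or a `GRanges`.
#' @param label region-set label, e.g. `"mcr"` or `"indel_exclusion"`.
#' @return an object of class `region_set`.
#' @export
region_set <- function(intervals, label = "regions") {
  if (inherits(intervals, "GRanges")) {
    gr <- intervals
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
    gr <- GenomicRanges::GRanges(
      seqnames = intervals$chrom,
      ranges = IRanges::IRanges(start = intervals$start, end = intervals$end)
    )
  }
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(list(label = label, ranges = gr), class = "region_set")
}

#' Load a region set from a BED file
#'
#' BED is 0-based half-open; the imported intervals are converted to the
#' package's 1-based closed convention (rtracklayer does the conversion),
#' then sorted and merged.
#'
#' @param path BED file.
#' @param label region-set label.
#' @return a [region_set()].
#' @export
load_region_set <- function(path, label = "regions") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t| +")[[1L]]
    if (length(f) < 3L || is.na(suppressWarnings(as.numeric(f[2L]))) ||
        is.na(suppressWarnings(as.numeric(f[3L])))) {
      stop(sprintf("malformed BED line %d in %s: '%s'", i, path, lines[i]),
           call. = FALSE)
    }
  }
  if (!any(keep)) {
    return(region_set(data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0)), label))
  }
  gr <- rtracklayer::import(path, format = "BED")
  region_set(gr, label)
}

#' Write a region set (or reference annotation) to BED
#'
#' @param x a `region_set`, `GRanges`, or `data.frame(chrom, start, end)`
#'   in 1-based closed coordinates.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(x, path) {
  gr <- if (inherits(x, "region_set")) {
    x$ranges
  } else if (inherits(x, "GRanges")) {
    x
  } else {
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Test positions for region membership
#'
#' @param rs a `region_set`.
#' @param chrom,pos vectors of contigs and 1-based positions (recycled).
#' @return logical vector: does each position fall inside the set?
#' @export
in_region <- function(rs, chrom, pos) {
  stopifnot(inherits(rs, "region_set"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  if (length(rs$ranges) == 0L) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  subj <- rs$ranges
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(subj))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(subj) <- lv
  GenomicRanges::countOverlaps(q, subj) > 0L
}

#' Build the indel-proximity exclusion set
#'
#' Each indel position contributes the closed window
#' `[pos - window, pos + window]` (clipped at 1); overlapping windows are
#' merged. Candidates falling anywhere inside the window, endpoints
#' included, are excluded.
#'
#' @param indels `data.frame` with `chrom` and `pos` (1-based).
#' @param window half-width in bases (default 10).
#' @return a [region_set()] labelled `"indel_exclusion"`.
#' @export
build_indel_exclusion <- function(indels, window = 10L) {
  if (window < 0) stop("window must be non-negative", call. = FALSE)
  if (is.null(indels) || nrow(indels) == 0L) {
    return(region_set(data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0)), "indel_exclusion"))
  }
  region_set(data.frame(
    chrom = indels$chrom,
    start = pmax(1L, indels$pos - as.integer(window)),
    end = indels$pos + as.integer(window)
  ), "indel_exclusion")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("Region set '%s': %d merged interval(s), %d bp total\n",
              x$label, length(x$ranges),
              sum(GenomicRanges::width(x$ranges))))
  invisible(x)
}
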