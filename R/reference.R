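#' Generate a synthetic reference contig with annotated difficult contexts
#'
#' Builds a random reference sequence and plants the sequence contexts the
#' somatic-mutation filters are designed around: short tandem repeats,
#' poly-A/poly-T runs, homologous duplicated blocks (segmental-duplication
#' style, two near-identical copies), and annotated multi-copy regions
#' (MCRs). All planted intervals are non-overlapping, kept away from the
#' contig ends, and recorded as 1-based closed intervals so they round-trip
#' through BED export ([write_region_bed()] / [load_region_set()]).
#'
#' @param length contig length in bases (at least 1000).
#' @param n_str number of tandem-repeat regions (unit length drawn from
#'   `str_units`, copy number from `str_copies`).
#' @param n_polyA number of homopolymer runs (A or T, run length from
#'   `polyA_run`).
#' @param n_dup_blocks number of duplicated block pairs; each contributes a
#'   source and a copy interval at `dup_identity` sequence identity.
#' @param n_mcr number of annotated multi-copy region intervals.
#' @param seed RNG seed (required; generation is deterministic given it).
#' @param contig contig name, `"chr"`-prefixed by convention.
#' @param str_units,str_copies,polyA_run integer vectors to sample from.
#' @param dup_block_len,dup_identity,mcr_len duplication block length,
#'   fractional identity of the copy, and MCR interval length.
#' @return an object of class `twin_reference`: the sequence plus
#'   data frames `str_regions`, `polyA_regions`, `duplicated_blocks`,
#'   `mcr_regions` (all 1-based closed coordinates).
#' @export
generate_reference <- function(length, n_str = 2L, n_polyA = 2L,
                               n_dup_blocks = 1L, n_mcr = 1L, seed,
                               contig = "chr1",
                               str_units = 2:6, str_copies = 6:12,
                               polyA_run = 12:18,
                               dup_block_len = 500L, dup_identity = 0.98,
                               mcr_len = 300L) {
  stopifnot(length >= 1000L)
  length <- as.integer(length)
  with_seed(seed, {
    bases <- sample(DNA_BASES, length, replace = TRUE)

    margin <- 200L
    gap <- 50L
    occupied <- matrix(numeric(0), ncol = 2)
    claim <- function(width) {
      # rejection-sample a start so [start, start+width-1] clears margins,
      # existing features, and a `gap` buffer
      for (i in 1:500) {
        s <- sample.int(length - width - 2L * margin, 1L) + margin
        e <- s + width - 1L
        if (nrow(occupied) == 0L ||
            all(e < occupied[, 1] - gap | s > occupied[, 2] + gap)) {
          occupied <<- rbind(occupied, c(s, e))
          return(c(s, e))
        }
      }
      stop("cannot place requested annotations without overlap; ",
           "reduce counts or increase contig length", call. = FALSE)
    }

    dup <- data.frame(src_start = integer(0), src_end = integer(0),
                      copy_start = integer(0), copy_end = integer(0),
                      identity = numeric(0))
    for (i in seq_len(n_dup_blocks)) {
      src <- claim(dup_block_len)
      cp <- claim(dup_block_len)
      block <- bases[src[1]:src[2]]
      n_mut <- max(0L, round((1 - dup_identity) * dup_block_len))
      if (n_mut > 0) {
        at <- sample.int(dup_block_len, n_mut)
        block[at] <- other_base(block[at])
      }
      bases[cp[1]:cp[2]] <- block
      dup[i, ] <- c(src[1], src[2], cp[1], cp[2], dup_identity)
    }

    mcr <- data.frame(start = integer(0), end = integer(0))
    for (i in seq_len(n_mcr)) {
      iv <- claim(mcr_len)
      mcr[i, ] <- iv
    }

    str_df <- data.frame(start = integer(0), end = integer(0),
                         unit = character(0), copies = integer(0))
    for (i in seq_len(n_str)) {
      u <- sample(str_units, 1L)
      k <- sample(str_copies, 1L)
      repeat {
        unit <- sample(DNA_BASES, u, replace = TRUE)
        if (u == 1L || length(unique(unit)) > 1L) break
      }
      iv <- claim(u * k)
      bases[iv[1]:iv[2]] <- rep(unit, k)
      str_df[i, ] <- list(iv[1], iv[2], paste(unit, collapse = ""), k)
    }

    polyA <- data.frame(start = integer(0), end = integer(0),
                        run = integer(0), base = character(0))
    for (i in seq_len(n_polyA)) {
      run <- sample(polyA_run, 1L)
      b <- sample(c("A", "T"), 1L)
      iv <- claim(run)
      bases[iv[1]:iv[2]] <- b
      # break accidental run extensions at the flanks
      if (iv[1] > 1L && bases[iv[1] - 1L] == b) bases[iv[1] - 1L] <- other_base(b)
      if (iv[2] < length && bases[iv[2] + 1L] == b) bases[iv[2] + 1L] <- other_base(b)
      polyA[i, ] <- list(iv[1], iv[2], run, b)
    }

    sort_iv <- function(df, by = "start") {
      df <- df[order(df[[by]]), , drop = FALSE]
      rownames(df) <- NULL
      df
    }
    structure(
      list(
        contig = contig,
        length = length,
        sequence = paste(bases, collapse = ""),
        str_regions = sort_iv(str_df),
        polyA_regions = sort_iv(polyA),
        duplicated_blocks = sort_iv(dup, "src_start"),
        mcr_regions = sort_iv(mcr)
      ),
      class = "twin_reference"
    )
  })
}

#' @export
print.twin_reference <- function(x, ...) {
  cat(sprintf("Synthetic reference %s (%d bp)\n", x$contig, x$length))
  cat(sprintf("  %d STR, %d poly-A/T, %d duplicated block(s), %d MCR interval(s)\n",
              nrow(x$str_regions), nrow(x$polyA_regions),
              nrow(x$duplicated_blocks), nrow(x$mcr_regions)))
  invisible(x)
}

# genome accessor: twin_reference or named character vector of contigs
as_genome <- function(x) {
  if (inherits(x, "twin_reference")) {
    stats::setNames(x$sequence, x$contig)
  } else if (is.character(x) && !is.null(names(x))) {
    x
  } else {
    stop("genome must be a twin_reference or a named character vector of contig sequences",
         call. = FALSE)
  }
}

genome_base <- function(genome, chrom, pos) {
  genome <- as_genome(genome)
  substring(genome[[chrom]], pos, pos)
}

genome_subseq <- function(genome, chrom, start, end) {
  genome <- as_genome(genome)
  substring(genome[[chrom]], start, end)
}

#' Annotated intervals of a synthetic reference as GRanges
#'
#' @param ref a `twin_reference`.
#' @param what one of `"mcr"`, `"str"`, `"polyA"`, `"dup"`.
#' @return a [GenomicRanges::GRanges] (1-based closed, GRanges convention).
#' @export
reference_regions <- function(ref, what = c("mcr", "str", "polyA", "dup")) {
  stopifnot(inherits(ref, "twin_reference"))
  what <- match.arg(what)
  df <- switch(what,
    mcr = ref$mcr_regions,
    str = ref$str_regions,
    polyA = ref$polyA_regions,
    dup = data.frame(
      start = c(ref$duplicated_blocks$src_start, ref$duplicated_blocks$copy_start),
      end = c(ref$duplicated_blocks$src_end, ref$duplicated_blocks$copy_end)
    )
  )
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges()))
  }
  GenomicRanges::sort(GenomicRanges::GRanges(
    seqnames = ref$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  ))
}
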