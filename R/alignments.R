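#' Construct a validated table of planted mutations
#'
#' Mutations are planted into synthetic twin reads by
#' [generate_twin_alignments()]. Germline variants are shared by both
#' co-twins (heterozygous at expected allele fraction 0.5, homozygous at
#' 1.0); somatic variants are carried by one sample (or both) at a
#' sub-heterozygous true allele fraction. The `wes_artifact` origin models a
#' discovery-stage false positive: alt reads are planted into the carrier's
#' exome-style reads at `true_aaf`, but the underlying true allele fraction
#' (what ultra-deep amplicon resequencing would see) is zero.
#'
#' @param ref a `twin_reference` from [generate_reference()].
#' @param pos 1-based positions on the reference contig.
#' @param alt alternate bases (must differ from the reference base).
#' @param origin one of `"germline_het"`, `"germline_hom"`, `"somatic"`,
#'   `"wes_artifact"` (recycled).
#' @param true_aaf true allele fraction for somatic / `wes_artifact` plants;
#'   ignored (and forced to 0.5 / 1.0) for germline origins.
#' @param carrier `"case"`, `"control"` or `"both"`; germline plants are
#'   always `"both"`. Defaults to `"case"` for somatic origins.
#' @param artifact read-level artifact class attached to the planted alt
#'   reads: `"none"`, `"softclip"`, `"xa"` or `"edge"` (alt calls confined to
#'   the 10-base read edges).
#' @return a `data.frame` with one row per planted mutation.
#' @export
plant_mutations <- function(ref, pos, alt, origin, true_aaf = NULL,
                            carrier = NULL, artifact = "none") {
  stopifnot(inherits(ref, "twin_reference"))
  n <- length(pos)
  origin <- rep_len(origin, n)
  artifact <- rep_len(artifact, n)
  alt <- rep_len(alt, n)
  stopifnot(all(origin %in% c("germline_het", "germline_hom", "somatic", "wes_artifact")),
            all(artifact %in% c("none", "softclip", "xa", "edge")),
            all(pos >= 1L & pos <= ref$length))

  germ <- origin %in% c("germline_het", "germline_hom")
  if (is.null(carrier)) carrier <- ifelse(germ, "both", "case")
  carrier <- rep_len(carrier, n)
  if (any(germ & carrier != "both")) {
    stop("germline mutations are carried by both co-twins", call. = FALSE)
  }
  stopifnot(all(carrier %in% c("case", "control", "both")))

  if (is.null(true_aaf)) true_aaf <- rep(NA_real_, n)
  true_aaf <- rep_len(true_aaf, n)
  true_aaf[origin == "germline_het"] <- 0.5
  true_aaf[origin == "germline_hom"] <- 1.0
  som <- origin %in% c("somatic", "wes_artifact")
  if (any(som & (is.na(true_aaf) | true_aaf <= 0 | true_aaf >= 0.5))) {
    stop("somatic plants need 0 < true_aaf < 0.5", call. = FALSE)
  }
  if (any(germ & artifact != "none")) {
    stop("artifact classes apply to somatic plants only", call. = FALSE)
  }

  refb <- vapply(pos, function(p) substring(ref$sequence, p, p), "")
  if (any(alt == refb)) stop("alt base equals the reference base", call. = FALSE)

  out <- data.frame(
    chrom = ref$contig, pos = as.integer(pos), ref = refb, alt = alt,
    true_aaf = true_aaf, carrier = carrier, origin = origin,
    artifact = artifact, stringsAsFactors = FALSE
  )
  dup <- duplicated(out$pos) | duplicated(out$pos, fromLast = TRUE)
  if (any(dup)) {
    key <- paste(out$pos, out$ref, out$alt)
    if (anyDuplicated(out$pos) && length(unique(key[dup])) != length(unique(out$pos[dup]))) {
      stop("inconsistent plant: same position with differing ref/alt", call. = FALSE)
    }
    stop("duplicate planted position", call. = FALSE)
  }
  out
}

plant_prob <- function(m, sample) {
  if (m$origin %in% c("germline_het", "germline_hom")) return(m$true_aaf)
  if (m$carrier == "both" || m$carrier == sample) m$true_aaf else 0
}

#' Simulate paired exome-style alignments for a monozygotic twin pair
#'
#' Both samples derive from one identical germline: every germline variant
#' is planted into both read sets at its expected allele fraction, while
#' somatic plants appear only in their carrier sample, with alt read counts
#' binomially sampled at the true allele fraction. Per-base qualities and
#' substitution errors follow the Phred error model `err`; artifact reads
#' (soft-clips, XA multi-mapping tags, edge-concentrated errors, and
#' mismatch clusters flanking planted deletions) carry the corresponding
#' alignment marks. Reads are emitted pre-aligned at their true positions:
#' the downstream filters operate on alignment features, not on mapping.
#'
#' Indel realignment artifacts are locus-specific in real alignments, so
#' they are planted at `indel_loci` (a fraction of overlapping reads carries
#' a short deletion plus a nearby mismatch cluster and is marked as
#' realigned); `err$indel_read_rate` additionally disperses rare
#' single-read indels.
#'
#' @param ref a `twin_reference`.
#' @param germline,somatic mutation tables from [plant_mutations()] (either
#'   may be `NULL`).
#' @param depth target mean coverage depth per sample.
#' @param err a [error_model()].
#' @param seed RNG seed; identical seed reproduces identical read sets.
#' @param indel_loci optional `data.frame(pos, frac, del_len)` of deletion
#'   loci (`frac` defaults to 0.5, `del_len` to 2).
#' @param alt_downsample multiplicative factor on somatic alt-read planting
#'   probability, emulating capture bias against non-reference alleles
#'   (default 1, i.e. no bias).
#' @return an object of class `twin_alignments` with elements `case` and
#'   `control` (alignment record data frames), the inputs, and the realized
#'   indel locus table.
#' @export
generate_twin_alignments <- function(ref, germline = NULL, somatic = NULL,
                                     depth, err = error_model(), seed,
                                     indel_loci = NULL, alt_downsample = 1) {
  stopifnot(inherits(ref, "twin_reference"), depth >= 1,
            inherits(err, "twinsom_error_model"))
  muts <- rbind(germline, somatic)
  if (!is.null(muts) && nrow(muts)) {
    if (any(muts$pos > ref$length - 1L)) {
      stop("mutation position outside reference", call. = FALSE)
    }
    key <- paste(muts$chrom, muts$pos)
    if (anyDuplicated(key)) {
      kd <- key[duplicated(key)]
      sub <- muts[key %in% kd, ]
      if (nrow(unique(sub[, c("chrom", "pos", "ref", "alt")])) != length(unique(kd))) {
        stop("inconsistent plant: same position with differing ref/alt", call. = FALSE)
      }
    }
  }
  if (!is.null(indel_loci) && nrow(indel_loci)) {
    if (is.null(indel_loci$frac)) indel_loci$frac <- 0.5
    if (is.null(indel_loci$del_len)) indel_loci$del_len <- 2L
  }
  with_seed(seed, {
    case <- simulate_sample_reads(ref, muts, "case", depth, err,
                                  indel_loci, alt_downsample)
    control <- simulate_sample_reads(ref, muts, "control", depth, err,
                                     indel_loci, alt_downsample)
    structure(
      list(case = case, control = control, reference = ref,
           germline = germline, somatic = somatic, indel_loci = indel_loci,
           err = err, depth = depth),
      class = "twin_alignments"
    )
  })
}

simulate_sample_reads <- function(ref, muts, sample, depth, err,
                                  indel_loci, alt_downsample) {
  rl <- err$read_length
  L <- ref$length
  n <- max(1L, as.integer(round(depth * L / rl)))
  starts <- sort(sample.int(L - rl + 1L, n, replace = TRUE))
  seqs <- substring(ref$sequence, starts, starts + rl - 1L)
  cigar <- rep(sprintf("%dM", rl), n)
  pos <- starts
  mapq <- rep(60L, n)
  xa <- rep(NA_character_, n)
  realigned <- rep(FALSE, n)
  simple <- rep(TRUE, n)

  plant_deletion <- function(i, at, del_len) {
    # read i gets a del_len-bp deletion after query offset `at`, plus a
    # small mismatch cluster just 3' of the gap; sequence is rebuilt from
    # the reference so the CIGAR stays consistent
    if (starts[i] + rl + del_len - 1L > L) return(FALSE)
    k <- at
    if (k < 5L || k > rl - 5L) return(FALSE)
    gpos <- starts[i] + k - 1L
    newseq <- paste0(
      substring(ref$sequence, starts[i], gpos),
      substring(ref$sequence, gpos + del_len + 1L, starts[i] + rl + del_len - 1L)
    )
    for (o in c(k + 2L, k + 4L)) {
      b <- substring(newseq, o, o)
      substr(newseq, o, o) <- other_base(b)
    }
    seqs[i] <<- newseq
    cigar[i] <<- sprintf("%dM%dD%dM", k, del_len, rl - k)
    realigned[i] <<- TRUE
    simple[i] <<- FALSE
    TRUE
  }

  # locus-specific realignment artifacts first (they rebuild the sequence)
  if (!is.null(indel_loci) && nrow(indel_loci)) {
    for (j in seq_len(nrow(indel_loci))) {
      lp <- indel_loci$pos[j]
      hi <- findInterval(lp, starts)
      lo <- findInterval(lp - rl, starts) + 1L
      if (hi < lo) next
      idx <- lo:hi
      off <- lp - starts[idx] + 1L
      ok <- off >= 8L & off <= rl - 8L
      idx <- idx[ok]; off <- off[ok]
      sel <- stats::runif(length(idx)) < indel_loci$frac[j]
      for (k in which(sel)) plant_deletion(idx[k], off[k], indel_loci$del_len[j])
    }
  }
  if (err$indel_read_rate > 0) {
    for (i in which(stats::runif(n) < err$indel_read_rate)) {
      plant_deletion(i, sample.int(rl - 16L, 1L) + 8L, 2L)
    }
  }

  # plant germline and somatic variants (simple reads only; indel-carrier
  # reads were rebuilt from the reference and drop through to the pileup as
  # reference-supporting)
  if (!is.null(muts) && nrow(muts)) {
    for (j in seq_len(nrow(muts))) {
      m <- muts[j, ]
      p_carry <- plant_prob(m, sample)
      if (m$origin %in% c("somatic", "wes_artifact")) {
        p_carry <- min(1, p_carry * alt_downsample)
      }
      if (p_carry <= 0) next
      hi <- findInterval(m$pos, starts)
      lo <- findInterval(m$pos - rl, starts) + 1L
      if (hi < lo) next
      idx <- lo:hi
      off <- m$pos - starts[idx] + 1L
      ok <- off >= 1L & off <= rl & simple[idx]
      idx <- idx[ok]; off <- off[ok]
      if (m$artifact == "edge") {
        edge <- off <= 10L | off >= rl - 9L
        idx <- idx[edge]; off <- off[edge]
        p_use <- 0.5
      } else {
        p_use <- p_carry
      }
      sel <- stats::runif(length(idx)) < p_use
      idx <- idx[sel]; off <- off[sel]
      for (k in seq_along(idx)) substr(seqs[idx[k]], off[k], off[k]) <- m$alt
      if (m$artifact == "softclip" && length(idx)) {
        clip_start <- off > rl / 2
        for (k in seq_along(idx)) {
          i <- idx[k]
          if (clip_start[k]) {
            cigar[i] <- sprintf("10S%dM", rl - 10L)
            pos[i] <- starts[i] + 10L
          } else {
            cigar[i] <- sprintf("%dM10S", rl - 10L)
          }
          simple[i] <- FALSE
        }
      } else if (m$artifact == "xa" && length(idx)) {
        alt_pos <- ((starts[idx] + 7919L) %% (L - rl)) + 1L
        xa[idx] <- sprintf("%s,+%d,%dM,2;", ref$contig, alt_pos, rl)
        mapq[idx] <- 25L
      }
    }
  }

  # dispersed artifact reads
  sc <- which(stats::runif(n) < err$softclip_rate & simple)
  if (length(sc)) {
    at_start <- stats::runif(length(sc)) < 0.5
    cigar[sc] <- ifelse(at_start, sprintf("10S%dM", rl - 10L),
                        sprintf("%dM10S", rl - 10L))
    pos[sc][at_start] <- starts[sc][at_start] + 10L
    simple[sc] <- FALSE
  }
  xr <- which(stats::runif(n) < err$xa_rate & is.na(xa))
  if (length(xr)) {
    xa[xr] <- sprintf("%s,+%d,%dM,3;", ref$contig,
                      ((starts[xr] + 104729L) %% (L - rl)) + 1L, rl)
    mapq[xr] <- 25L
  }
  ee <- which(stats::runif(n) < err$edge_error_rate)
  if (length(ee)) {
    eo <- sample(c(1:5, (rl - 4L):rl), length(ee), replace = TRUE)
    for (k in seq_along(ee)) {
      b <- substring(seqs[ee[k]], eo[k], eo[k])
      substr(seqs[ee[k]], eo[k], eo[k]) <- other_base(b)
    }
  }

  # Phred qualities and quality-driven substitution errors
  qv <- err$quality_levels[sample.int(length(err$quality_levels), n * rl,
                                      replace = TRUE,
                                      prob = err$quality_probs)]
  eidx <- which(stats::runif(n * rl) < phred_error_prob(qv))
  for (t in eidx) {
    i <- (t - 1L) %/% rl + 1L
    o <- (t - 1L) %% rl + 1L
    b <- substring(seqs[i], o, o)
    substr(seqs[i], o, o) <- other_base(b)
  }
  qual <- substring(intToUtf8(qv + 33L), seq(1L, n * rl, by = rl),
                    seq(rl, n * rl, by = rl))

  out <- data.frame(
    qname = sprintf("%s_%06d", sample, seq_len(n)),
    flag = 0L, chrom = ref$contig, pos = pos, mapq = mapq,
    cigar = cigar, seq = seqs, qual = qual, xa = xa,
    realigned = realigned, stringsAsFactors = FALSE
  )
  attr(out, "n_seq_errors") <- length(eidx)
  attr(out, "n_bases") <- n * rl
  out
}

#' Count base-calls per allele at candidate sites from alignment records
#'
#' Walks every read covering each site (CIGAR-aware, so deletions and
#' soft-clipped segments contribute no base-call) and tallies qualified
#' base-calls by identity: matching the site's `ref`, its `alt`, or neither.
#'
#' @param reads an alignment record `data.frame` (one sample of a
#'   `twin_alignments` object, or reads loaded with [read_sam()]).
#' @param sites `data.frame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @param min_bq,min_mapq base-call quality / read mapping-quality floors; a
#'   base-call below either does not count.
#' @return `data.frame` with `ref_count`, `alt_count`, `other_count`,
#'   `depth` (qualified covering base-calls) and `alt_mean_bq` (mean Phred
#'   quality of the alt-supporting calls, `NaN` when there are none).
#' @export
allele_counts <- function(reads, sites, min_bq = 0, min_mapq = 0) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  simple <- !grepl("[^0-9M]", reads$cigar)
  maxspan <- if (length(span)) max(span) else 0L

  res <- sites[, c("chrom", "pos", "ref", "alt")]
  res$ref_count <- res$alt_count <- res$other_count <- res$depth <- 0L
  res$alt_mean_bq <- NaN

  for (ch in unique(sites$chrom)) {
    ci <- which(reads$chrom == ch)
    ord <- ci[order(reads$pos[ci])]
    p <- reads$pos[ord]
    si <- which(sites$chrom == ch)
    for (s in si) {
      sp <- sites$pos[s]
      hi <- findInterval(sp, p)
      lo <- findInterval(sp - maxspan, p) + 1L
      if (hi < lo) next
      cand <- ord[lo:hi]
      cand <- cand[reads$pos[cand] + span[cand] - 1L >= sp]
      cand <- cand[reads$mapq[cand] >= min_mapq]
      if (!length(cand)) next
      off <- integer(length(cand))
      fast <- simple[cand]
      off[fast] <- sp - reads$pos[cand[fast]] + 1L
      if (any(!fast)) {
        off[!fast] <- vapply(cand[!fast], function(i) {
          query_offset_at(reads$cigar[i], reads$pos[i], sp)
        }, integer(1))
      }
      keep <- !is.na(off)
      cand <- cand[keep]; off <- off[keep]
      if (!length(cand)) next
      b <- substring(reads$seq[cand], off, off)
      q <- vapply(substring(reads$qual[cand], off, off),
                  function(x) utf8ToInt(x) - 33L, integer(1), USE.NAMES = FALSE)
      ok <- q >= min_bq
      b <- b[ok]; q <- q[ok]
      res$depth[s] <- length(b)
      res$ref_count[s] <- sum(b == sites$ref[s])
      res$alt_count[s] <- sum(b == sites$alt[s])
      res$other_count[s] <- res$depth[s] - res$ref_count[s] - res$alt_count[s]
      if (res$alt_count[s] > 0) res$alt_mean_bq[s] <- mean(q[b == sites$alt[s]])
    }
  }
  res
}

#' Build a caller-style candidate table from synthetic twin alignments
#'
#' Emulates the fields a paired somatic caller reports for each candidate
#' SNV: mean alt base quality (`bq`, MuTect-style) or a somatic quality
#' score (`qss`, Strelka-style), site depth, and per-sample alt counts.
#' Also precomputes the quality-qualified co-twin alt count (base quality
#' >= 20, mapQ >= 30) consumed by the control-identity filter.
#'
#' @param aln a `twin_alignments` object.
#' @param sites candidate site table (`chrom`, `pos`, `ref`, `alt`).
#' @param caller `"mutect-like"` (populates `bq`) or `"strelka-like"`
#'   (populates `qss`).
#' @param drop_no_alt drop sites with no alt-supporting call in the case
#'   sample (a caller would not emit them).
#' @return a candidate `data.frame`.
#' @export
candidates_from_alignments <- function(aln, sites,
                                       caller = c("mutect-like", "strelka-like"),
                                       drop_no_alt = TRUE) {
  stopifnot(inherits(aln, "twin_alignments"))
  caller <- match.arg(caller)
  cc <- allele_counts(aln$case, sites)
  ctrl <- allele_counts(aln$control, sites)
  ctrl_q <- allele_counts(aln$control, sites, min_bq = 20, min_mapq = 30)
  out <- data.frame(
    chrom = cc$chrom, pos = cc$pos, ref = cc$ref, alt = cc$alt,
    caller = caller,
    bq = if (caller == "mutect-like") round(cc$alt_mean_bq, 1) else NA_real_,
    qss = if (caller == "strelka-like") round(cc$alt_mean_bq) else NA_real_,
    dp = cc$depth,
    alt_count_case = cc$alt_count,
    alt_count_control = ctrl$alt_count,
    control_dp = ctrl$depth,
    control_alt_qualified = ctrl_q$alt_count,
    stringsAsFactors = FALSE
  )
  if (drop_no_alt) out <- out[out$alt_count_case > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call diploid genotypes from allele counts
#'
#' A minimal binomial genotype caller used for the monozygosity check:
#' likelihoods for 0/0, 0/1 and 1/1 assume alt-supporting base-calls arise
#' with probability `error_rate`, 0.5, and `1 - error_rate` respectively.
#' `gq` is the Phred-scaled gap between the best and second-best genotype
#' (capped at 99, the conventional ceiling); `qual` is the Phred-scaled
#' posterior against the hom-ref genotype under a flat prior, so hom-ref
#' sites score near 0 and confident variant sites score in the thousands.
#'
#' @param counts output of [allele_counts()].
#' @param error_rate per-base miscall probability assumed by the likelihood.
#' @param gq_cap,qual_cap score ceilings.
#' @return `counts` with `gt`, `gq` and `qual` columns appended.
#' @export
call_genotypes <- function(counts, error_rate = 1e-3, gq_cap = 99L,
                           qual_cap = 99999) {
  alt <- counts$alt_count
  dp <- counts$alt_count + counts$ref_count + counts$other_count
  l00 <- stats::dbinom(alt, dp, error_rate, log = TRUE)
  l01 <- stats::dbinom(alt, dp, 0.5, log = TRUE)
  l11 <- stats::dbinom(alt, dp, 1 - error_rate, log = TRUE)
  L <- cbind(l00, l01, l11)
  best <- max.col(L, ties.method = "first")
  srt <- apply(L, 1L, sort, decreasing = TRUE)
  gq <- pmin(gq_cap, round(10 / log(10) * (srt[1L, ] - srt[2L, ])))
  m <- pmax(l00, l01, l11)
  lse <- m + log(exp(l00 - m) + exp(l01 - m) + exp(l11 - m))
  qual <- pmin(qual_cap, -10 / log(10) * (l00 - lse))
  out <- counts
  out$gt <- c("0/0", "0/1", "1/1")[best]
  out$gq <- as.integer(gq)
  out$qual <- round(qual, 2)
  out
}

#' @export
print.twin_alignments <- function(x, ...) {
  cat(sprintf("Twin pair alignments on %s (%d bp), target depth %g\n",
              x$reference$contig, x$reference$length, x$depth))
  cat(sprintf("  case: %d reads; control: %d reads\n",
              nrow(x$case), nrow(x$control)))
  cat(sprintf("  planted: %d germline, %d somatic\n",
              if (is.null(x$germline)) 0L else nrow(x$germline),
              if (is.null(x$somatic)) 0L else nrow(x$somatic)))
  invisible(x)
}
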