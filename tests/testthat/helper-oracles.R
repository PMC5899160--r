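# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most literal method available (linear scans, exhaustive
# enumeration, per-read re-evaluation) and share no code with the package
# implementations they check.

# interval membership by linear scan over the raw, unmerged intervals
oracle_in_intervals <- function(df, chrom, pos) {
  any(df$chrom == chrom & df$start <= pos & df$end >= pos)
}

# exhaustive sliding-window matches-minus-mismatches score of the flank
# around `pos` against every window of every contig, both strands,
# excluding windows overlapping the flank's own footprint
oracle_second_best <- function(genome, chrom, pos, flank = 100L) {
  g <- genome[[chrom]]
  L <- nchar(g)
  fs <- max(1L, pos - flank)
  fe <- min(L, pos + flank)
  f <- strsplit(substring(g, fs, fe), "")[[1L]]
  flen <- length(f)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- -Inf
  for (ctg in names(genome)) {
    gc <- strsplit(genome[[ctg]], "")[[1L]]
    Lc <- length(gc)
    if (Lc < flen) next
    for (s in 1:(Lc - flen + 1L)) {
      self <- ctg == chrom && s <= fe && (s + flen - 1L) >= fs
      if (self) next
      win <- gc[s:(s + flen - 1L)]
      best <- max(best, 2L * sum(win == f) - flen)
      rcwin <- rev(unname(comp[win]))
      best <- max(best, 2L * sum(rcwin == f) - flen)
    }
  }
  best
}

# naive CIGAR decomposition for the read-level oracle
oracle_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1L]]
  list(len = as.integer(sub("[A-Z=]$", "", m)), op = sub("^[0-9]+", "", m))
}

# per-read re-evaluation of the seven reliability criteria
oracle_rbsm_count <- function(reads, genome, chrom, pos, alt,
                              bq_min = 25, mapq_min = 30, edge = 10L,
                              mmw = 15L, piw = 15L) {
  gseq <- strsplit(genome[[chrom]], "")[[1L]]
  # pileup-level clause of criterion (vii)
  indel_near <- FALSE
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != chrom) next
    cg <- oracle_cigar(reads$cigar[i])
    r <- reads$pos[i]
    for (k in seq_along(cg$op)) {
      if (cg$op[k] %in% c("M", "=", "X", "N")) {
        r <- r + cg$len[k]
      } else if (cg$op[k] == "D") {
        if (r <= pos + piw && r + cg$len[k] - 1L >= pos - piw) indel_near <- TRUE
        r <- r + cg$len[k]
      } else if (cg$op[k] == "I") {
        if (r >= pos - piw && r <= pos + piw) indel_near <- TRUE
      }
    }
  }
  count <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != chrom) next
    cg <- oracle_cigar(reads$cigar[i])
    q <- 1L
    r <- reads$pos[i]
    qp <- integer(0); rp <- integer(0)
    ind_q <- integer(0)
    for (k in seq_along(cg$op)) {
      l <- cg$len[k]
      if (cg$op[k] %in% c("M", "=", "X")) {
        qp <- c(qp, q:(q + l - 1L)); rp <- c(rp, r:(r + l - 1L))
        q <- q + l; r <- r + l
      } else if (cg$op[k] == "S") {
        q <- q + l
      } else if (cg$op[k] == "I") {
        ind_q <- c(ind_q, q); q <- q + l
      } else if (cg$op[k] %in% c("D", "N")) {
        ind_q <- c(ind_q, q); r <- r + l
      }
    }
    hit <- which(rp == pos)
    if (length(hit) != 1L) next
    qidx <- qp[hit]
    bases <- strsplit(reads$seq[i], "")[[1L]]
    if (bases[qidx] != alt) next
    quals <- utf8ToInt(reads$qual[i]) - 33L
    c1 <- quals[qidx] >= bq_min
    c2 <- reads$mapq[i] >= mapq_min
    c3 <- (qidx - min(qp) + 1L) > edge && (max(qp) - qidx + 1L) > edge
    inw <- abs(qp - qidx) <= mmw
    c4 <- !any(bases[qp[inw]] != gseq[rp[inw]] & rp[inw] != pos) &&
      !any(abs(ind_q - qidx) <= mmw)
    c5 <- is.na(reads$xa[i])
    c6 <- !grepl("S", reads$cigar[i], fixed = TRUE)
    c7 <- !isTRUE(reads$realigned[i]) && !indel_near
    if (c1 && c2 && c3 && c4 && c5 && c6 && c7) count <- count + 1L
  }
  count
}

# exhaustive tandem-repeat / homopolymer detection over a window
oracle_difficult_context <- function(genome, chrom, pos, window = 15L,
                                     max_unit = 6L, min_copies = 4L,
                                     min_len = 8L, polyA_min = 8L) {
  g <- strsplit(genome[[chrom]], "")[[1L]]
  L <- length(g)
  win_s <- max(1L, pos - window)
  win_e <- min(L, pos + window)
  # every homopolymer A/T run
  r <- rle(g)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k] %in% c("A", "T") && r$lengths[k] >= polyA_min &&
        s[k] <= win_e && e[k] >= win_s) {
      return("polyA")
    }
  }
  # every (start, unit) tandem run in the whole contig
  for (u in 1:max_unit) {
    for (st in 1:(L - u + 1L)) {
      k <- 1L
      while (st + (k + 1L) * u - 1L <= L &&
             all(g[(st + k * u):(st + (k + 1L) * u - 1L)] ==
                   g[st:(st + u - 1L)])) {
        k <- k + 1L
      }
      if (k >= min_copies && k * u >= min_len &&
          st <= win_e && st + k * u - 1L >= win_s) {
        return("str")
      }
    }
  }
  "none"
}

# two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins
oracle_fisher <- function(case, control) {
  m <- sum(case)
  n <- sum(control)
  k <- case[2L] + control[2L]
  xs <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(xs, m, n, k)
  pobs <- stats::dhyper(case[2L], m, n, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# one-sided permutation test for mean(x) > mean(y)
oracle_perm_p <- function(x, y, B = 40000L, seed = 1L) {
  withr::with_seed(seed, {
    obs <- mean(x) - mean(y)
    pooled <- c(x, y)
    nx <- length(x)
    stat <- replicate(B, {
      i <- sample(length(pooled), nx)
      mean(pooled[i]) - mean(pooled[-i])
    })
    (1 + sum(stat >= obs)) / (B + 1)
  })
}

# shared toy fixture for cascade tests: 10 candidates, one in an MCR, one
# low-depth, one inside an exact duplicated flank
toy_cascade_fixture <- function() {
  genome <- random_genome(6000L, seed = 301L)
  # exact copy of the ±100 bp flank of position 4000 planted at 1100
  flank <- substring(genome[["chr1"]], 3900, 4100)
  g <- genome[["chr1"]]
  substr(g, 1100, 1300) <- flank
  genome[["chr1"]] <- g
  pos <- c(2100L, 5200L, 4000L, 500L, 800L, 2600L, 3000L, 3400L, 4600L, 5600L)
  cls <- c("mcr", "lowdp", "dup", rep("clean", 7L))
  ref <- substring(genome[["chr1"]], pos, pos)
  alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1L], "",
                USE.NAMES = FALSE)
  candidates <- data.frame(
    chrom = "chr1", pos = pos, ref = ref, alt = alt, caller = "mutect-like",
    bq = 33, qss = NA_real_, dp = ifelse(cls == "lowdp", 20L, 80L),
    control_alt_qualified = 0L, control_dp = 50L,
    stringsAsFactors = FALSE
  )
  list(
    genome = genome, candidates = candidates, class = cls,
    mcr = region_set(data.frame(chrom = "chr1", start = 2000L, end = 2200L),
                     "mcr")
  )
}
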