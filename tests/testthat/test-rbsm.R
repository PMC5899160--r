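## shared scaffolding: a 1 kb genome, a candidate site at 450, and reads of
## length 100 built directly from the reference with the alt planted
rbsm_scaffold <- function() {
  genome <- random_genome(1000L, seed = 88)
  pos <- 450L
  ref_base <- substring(genome[["chr1"]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
  list(genome = genome, pos = pos, alt = alt)
}

scaffold_read <- function(sc, start = 401L, qname = "r1", site_q = 35L, ...) {
  seq <- substring(sc$genome[["chr1"]], start, start + 99L)
  off <- sc$pos - start + 1L
  substr(seq, off, off) <- sc$alt
  qv <- rep(35L, 100L)
  qv[off] <- site_q
  make_read(seq, pos = start, qname = qname,
            qual = intToUtf8(qv + 33L), ...)
}

test_that("each reliability criterion is detected at its boundary", {
  sc <- rbsm_scaffold()
  check_failed <- function(reads, expected) {
    v <- classify_base_call(reads, sc$genome, "chr1", sc$pos, sc$alt)
    expect_equal(v$failed[1L], expected)
  }

  check_failed(scaffold_read(sc), "")                         # clean: RBSM
  check_failed(scaffold_read(sc, site_q = 25L), "")           # inclusive at 25
  check_failed(scaffold_read(sc, site_q = 24L), "i")
  check_failed(scaffold_read(sc, mapq = 29L), "ii")
  check_failed(scaffold_read(sc, start = 443L), "iii")        # offset 8
  check_failed(scaffold_read(sc, start = 360L), "iii")        # offset 91
  check_failed(scaffold_read(sc, xa = "chr1,+1,100M,2;"), "v")
  check_failed(scaffold_read(sc, realigned = TRUE), "vii")

  # one extra mismatch 12 bases away plus a soft-clip: exactly {iv, vi}
  r <- scaffold_read(sc, cigar = "90M10S")
  substr(r$seq, 38L, 38L) <-
    setdiff(c("A", "C", "G", "T"), substring(r$seq, 38L, 38L))[1L]
  check_failed(r, "iv,vi")
  # the same mismatch 16 bases away is outside the window
  r2 <- scaffold_read(sc)
  substr(r2$seq, 34L, 34L) <-
    setdiff(c("A", "C", "G", "T"), substring(r2$seq, 34L, 34L))[1L]
  check_failed(r2, "")

  # a deletion on the same read fails (iv) and, via the pileup clause, (vii)
  rd <- scaffold_read(sc, cigar = "40M2D60M")
  sq <- paste0(substring(sc$genome[["chr1"]], 401L, 440L),
               substring(sc$genome[["chr1"]], 443L, 502L))
  substr(sq, 48L, 48L) <- sc$alt   # site 450 sits at query offset 48
  rd$seq <- sq
  check_failed(rd, "iv,vii")

  # an indel on a *different* pileup read near the site fails only (vii)
  clean <- scaffold_read(sc)
  ind <- make_read(paste0(substring(sc$genome[["chr1"]], 401L, 440L),
                          substring(sc$genome[["chr1"]], 443L, 502L)),
                   pos = 401L, qname = "ind", cigar = "40M2D60M")
  v <- classify_base_call(bind_reads(clean, ind), sc$genome, "chr1",
                          sc$pos, sc$alt)
  expect_equal(v$failed[v$qname == "r1"], "vii")

  expect_error(classify_base_call(scaffold_read(sc, start = 700L),
                                  sc$genome, "chr1", sc$pos, sc$alt),
               "no read covers")
})

test_that("RBSM counts match a naive per-read oracle on random pileups", {
  for (seed in 1:4) {
    genome <- random_genome(1200L, seed = 500 + seed)
    pos <- 600L
    alt <- setdiff(c("A", "C", "G", "T"),
                   substring(genome[["chr1"]], pos, pos))[1L]
    reads <- make_site_pileup(genome, pos, alt, depth = 50L, aaf = 0.3,
                              seed = seed)
    # perturb: degrade some reads' mapq, site quality, or add XA tags
    reads <- withr::with_seed(900 + seed, {
      k <- sample(nrow(reads), 12L)
      reads$mapq[k[1:4]] <- 20L
      reads$xa[k[5:8]] <- "chr1,+5,100M,1;"
      for (i in k[9:12]) {
        off <- pos - reads$pos[i] + 1L
        qv <- utf8ToInt(reads$qual[i]) - 33L
        qv[off] <- 20L
        reads$qual[i] <- intToUtf8(qv + 33L)
      }
      reads
    })
    got <- count_rbsm(reads, genome, "chr1", pos, alt)
    want <- oracle_rbsm_count(reads, genome, "chr1", pos, alt)
    expect_equal(got, want)

    # never exceeds the alt depth
    pile <- pileup_at(reads, "chr1", pos)
    expect_lte(got, sum(pile$base == alt))

    # verdicts are invariant under read order
    shuf <- withr::with_seed(7, reads[sample(nrow(reads)), ])
    expect_equal(count_rbsm(shuf, genome, "chr1", pos, alt), got)

    # removing reads never increases the count (no indel reads present)
    for (drop in c(1L, 10L, 25L)) {
      expect_lte(count_rbsm(reads[-drop, ], genome, "chr1", pos, alt), got)
    }
  }
})

test_that("direct count examples: failing reads are subtracted, empty is zero", {
  sc <- rbsm_scaffold()
  reads <- bind_reads(
    scaffold_read(sc, qname = "a"),
    scaffold_read(sc, qname = "b", start = 420L),
    scaffold_read(sc, qname = "c", mapq = 20L)
  )
  expect_equal(count_rbsm(reads, sc$genome, "chr1", sc$pos, sc$alt), 2L)
  # covering reads but no alt call
  refread <- make_read(substring(sc$genome[["chr1"]], 401L, 500L), pos = 401L)
  expect_equal(count_rbsm(refread, sc$genome, "chr1", sc$pos, sc$alt), 0L)
})

test_that("artifact-supported sites never yield reliable calls", {
  genome <- random_genome(1200L, seed = 61)
  pos <- 600L
  alt <- setdiff(c("A", "C", "G", "T"),
                 substring(genome[["chr1"]], pos, pos))[1L]
  for (art in c("softclip", "xa", "edge")) {
    reads <- make_site_pileup(genome, pos, alt, depth = 60L, aaf = 0.3,
                              seed = 21, artifact = art)
    expect_gt(sum(reads$planted), 0L)
    expect_equal(count_rbsm(reads, genome, "chr1", pos, alt), 0L)
  }
})

test_that("difficult sequence contexts are flagged and agree with exhaustive scanning", {
  # homopolymer run of 10 at the site
  g <- random_genome(200L, seed = 71)
  s <- g[["chr1"]]
  substr(s, 95, 104) <- strrep("A", 10L)
  g[["chr1"]] <- s
  ctx <- detect_difficult_seqcontext(g, "chr1", 100L)
  expect_true(ctx$is_difficult)
  expect_equal(ctx$reason, "polyA")

  # tandem repeat adjacent to (not containing) the site
  g2 <- random_genome(200L, seed = 72)
  s2 <- g2[["chr1"]]
  substr(s2, 108, 119) <- strrep("ACG", 4L)
  g2[["chr1"]] <- s2
  ctx2 <- detect_difficult_seqcontext(g2, "chr1", 100L)
  expect_equal(ctx2$reason, "str")

  # a fixed non-repetitive context is clean
  g3 <- stats::setNames(paste0(strrep("TGACC", 1L),
                               "TAGCGATACGGTCAATGCCGTAGCTAGTCATGCAGTACCGATTGACCTAGC",
                               "GATTCAGGCATCCAGTTGACGATCAGTCCGATAGGCTAACGTCAGGCT"),
                        "chr1")
  ctx3 <- detect_difficult_seqcontext(g3, "chr1", 50L)
  expect_equal(ctx3$reason, oracle_difficult_context(g3, "chr1", 50L))

  # random contexts, some with planted repeats: exact agreement with the
  # exhaustive unit/phase enumeration
  for (seed in 1:12) {
    gg <- random_genome(160L, seed = 800 + seed)
    if (seed %% 3 == 0) {
      u <- c("AT", "CAG", "GATC")[[(seed %% 3) + 1L]]
      ss <- gg[["chr1"]]
      at <- 70L + seed
      substr(ss, at, at + nchar(u) * 4L - 1L) <- strrep(u, 4L)
      gg[["chr1"]] <- ss
    }
    expect_equal(detect_difficult_seqcontext(gg, "chr1", 80L)$reason,
                 oracle_difficult_context(gg, "chr1", 80L),
                 info = paste("seed", seed))
  }
})

test_that("HC selection combines the count threshold and the context veto", {
  tab <- data.frame(
    chrom = "chr1", pos = c(300L, 100L, 200L),
    rbsm_count = c(2L, 5L, 1L),
    seqcontext_difficult = c(FALSE, TRUE, FALSE)
  )
  hc <- select_hc(tab)
  expect_equal(hc$pos, c(100L, 200L, 300L))  # sorted
  expect_equal(hc$is_hc, c(FALSE, FALSE, TRUE))
})

test_that("clean somatic sites at adequate depth almost always reach RBSM >= 2", {
  genome <- random_genome(1200L, seed = 99)
  pos <- 600L
  alt <- setdiff(c("A", "C", "G", "T"),
                 substring(genome[["chr1"]], pos, pos))[1L]
  hits <- vapply(1:200, function(seed) {
    reads <- make_site_pileup(genome, pos, alt, depth = 120L, aaf = 0.10,
                              seed = 3000 + seed)
    count_rbsm(reads, genome, "chr1", pos, alt) >= 2L
  }, logical(1))
  expect_gt(mean(hits), 0.99)
})
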