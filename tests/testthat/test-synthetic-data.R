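test_that("reference generation is deterministic and plants verifiable contexts", {
  r1 <- generate_reference(10000, n_str = 2, n_polyA = 2, n_dup_blocks = 1,
                           seed = 7)
  r2 <- generate_reference(10000, n_str = 2, n_polyA = 2, n_dup_blocks = 1,
                           seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$str_regions), 2L)
  expect_equal(nrow(r1$polyA_regions), 2L)
  expect_equal(nrow(r1$duplicated_blocks), 1L)

  # each STR region is exactly its unit repeated its copy number
  for (i in seq_len(nrow(r1$str_regions))) {
    s <- r1$str_regions[i, ]
    expect_identical(substring(r1$sequence, s$start, s$end),
                     strrep(s$unit, s$copies))
  }

  # a brute-force homopolymer scan finds exactly the annotated poly-A runs
  runs <- rle(strsplit(r1$sequence, "")[[1L]])
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in seq_len(nrow(r1$polyA_regions))) {
    p <- r1$polyA_regions[i, ]
    k <- which(starts == p$start & runs$values == p$base)
    expect_length(k, 1L)
    expect_equal(runs$lengths[k], p$run)
  }

  # duplicated block copy matches its source at the stated identity
  d <- r1$duplicated_blocks[1L, ]
  src <- strsplit(substring(r1$sequence, d$src_start, d$src_end), "")[[1L]]
  cp <- strsplit(substring(r1$sequence, d$copy_start, d$copy_end), "")[[1L]]
  n_mut <- round((1 - d$identity) * length(src))
  expect_lte(sum(src != cp), n_mut)
  expect_gte(sum(src == cp), length(src) - n_mut)

  # all annotated intervals lie within bounds and do not overlap
  iv <- rbind(
    r1$str_regions[, c("start", "end")],
    r1$polyA_regions[, c("start", "end")],
    data.frame(start = c(d$src_start, d$copy_start),
               end = c(d$src_end, d$copy_end)),
    r1$mcr_regions
  )
  expect_true(all(iv$start >= 1 & iv$end <= r1$length & iv$start <= iv$end))
  iv <- iv[order(iv$start), ]
  expect_true(all(iv$start[-1L] > iv$end[-nrow(iv)]))
})

test_that("annotation intervals round-trip through BED export", {
  ref <- generate_reference(10000, n_str = 2, n_polyA = 1, n_dup_blocks = 1,
                            n_mcr = 2, seed = 21)
  for (what in c("mcr", "str", "dup")) {
    gr <- reference_regions(ref, what)
    f <- tempfile(fileext = ".bed")
    write_region_bed(gr, f)
    rs <- load_region_set(f, what)
    expect_equal(GenomicRanges::start(rs$ranges), GenomicRanges::start(gr))
    expect_equal(GenomicRanges::end(rs$ranges), GenomicRanges::end(gr))
  }
})

test_that("impossible annotation requests raise a capacity error", {
  expect_error(generate_reference(1000, n_str = 80, n_polyA = 0,
                                  n_dup_blocks = 0, seed = 1),
               "cannot place")
})

test_that("plants obey carrier semantics and binomial sampling", {
  # near-error-free model so any non-carrier alt call would be a leak
  err <- error_model(quality_levels = 60L, quality_probs = 1,
                     softclip_rate = 0, xa_rate = 0, edge_error_rate = 0,
                     indel_read_rate = 0)
  ref <- generate_reference(1500, n_str = 0, n_polyA = 0, n_dup_blocks = 0,
                            n_mcr = 0, seed = 5)
  p_som <- 700L
  p_het <- 1100L
  rb <- function(p) substring(ref$sequence, p, p)
  ob <- function(p) setdiff(c("A", "C", "G", "T"), rb(p))[1L]
  som <- plant_mutations(ref, p_som, ob(p_som), origin = "somatic",
                         true_aaf = 0.10, carrier = "case")
  germ <- plant_mutations(ref, p_het, ob(p_het), origin = "germline_het")
  aln <- generate_twin_alignments(ref, germ, som, depth = 1000, err = err,
                                  seed = 17)
  sites <- rbind(germ, som)[, c("chrom", "pos", "ref", "alt")]
  cc <- allele_counts(aln$case, sites)
  kk <- allele_counts(aln$control, sites)

  i_som <- which(cc$pos == p_som)
  i_het <- which(cc$pos == p_het)
  # somatic alt count within the central 99.9% binomial band at the
  # realized site depth
  dp <- cc$depth[i_som]
  expect_gte(cc$alt_count[i_som], qbinom(5e-4, dp, 0.10))
  expect_lte(cc$alt_count[i_som], qbinom(1 - 5e-4, dp, 0.10))
  # no leak into the non-carrier
  expect_equal(kk$alt_count[i_som], 0L)
  # germline het present in both samples around 0.5
  for (x in list(cc, kk)) {
    expect_gte(x$alt_count[i_het], qbinom(5e-4, x$depth[i_het], 0.5))
    expect_lte(x$alt_count[i_het], qbinom(1 - 5e-4, x$depth[i_het], 0.5))
  }
})

test_that("identical seeds give identical alignments; realized error rate matches the model", {
  ref <- generate_reference(20000, n_str = 1, n_polyA = 1, n_dup_blocks = 0,
                            seed = 31)
  a1 <- generate_twin_alignments(ref, NULL, NULL, depth = 50, seed = 77)
  a2 <- generate_twin_alignments(ref, NULL, NULL, depth = 50, seed = 77)
  expect_identical(a1$case, a2$case)
  expect_identical(a1$control, a2$control)

  p <- mean_error_prob(error_model())
  n <- attr(a1$case, "n_bases")
  realized <- attr(a1$case, "n_seq_errors") / n
  expect_lt(abs(realized - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("alignment records round-trip through the SAM writer and reader", {
  ref <- generate_reference(5000, n_str = 1, n_polyA = 1, n_dup_blocks = 0,
                            seed = 3)
  alt <- setdiff(c("A", "C", "G", "T"), substring(ref$sequence, 2500, 2500))[1L]
  som <- plant_mutations(ref, 2500, alt, origin = "somatic", true_aaf = 0.2,
                         artifact = "softclip")
  aln <- generate_twin_alignments(
    ref, NULL, som, depth = 30, seed = 9,
    indel_loci = data.frame(pos = 1000L, frac = 0.5, del_len = 2L)
  )
  f <- tempfile(fileext = ".sam")
  write_sam(aln$case, f, ref)
  back <- read_sam(f)
  a <- aln$case[order(aln$case$qname), ]
  b <- back[order(back$qname), ]
  rownames(a) <- rownames(b) <- NULL
  for (col in c("qname", "flag", "chrom", "pos", "mapq", "cigar", "seq",
                "qual", "xa", "realigned")) {
    expect_identical(a[[col]], b[[col]])
  }
  # the file really carries soft-clip, deletion, and XA structure
  expect_gt(sum(grepl("S", back$cigar)), 0L)
  expect_gt(sum(grepl("D", back$cigar)), 0L)
})

test_that("amplicon counts follow the uniform-miscall binomial contract", {
  # no signal, no noise
  z <- generate_tas_counts(0, 100000, error_rate = 0, seed = 1)
  expect_equal(z$alt_count, 0L)
  expect_equal(compute_aaf(z), 0)
  expect_equal(z$ref_count + z$alt_count + z$other_count, z$depth)

  # published regime: 7.32% at depth 179669
  x <- generate_tas_counts(0.0732, 179669, error_rate = 0, seed = 2)
  expect_lt(abs(compute_aaf(x) - 7.32), 0.2)

  # pure-error site: expected alt fraction is error_rate / 3
  e <- generate_tas_counts(0, 200000, error_rate = 0.00316, seed = 3)
  p_exp <- 0.00316 / 3
  expect_lt(abs(e$alt_count / e$depth - p_exp),
            4 * sqrt(p_exp * (1 - p_exp) / 200000))

  # deterministic under seed; totals always equal depth
  expect_identical(generate_tas_counts(0.03, 5000, 0.001, seed = 9),
                   generate_tas_counts(0.03, 5000, 0.001, seed = 9))
})

test_that("aggregated alt fraction converges to the planted fraction", {
  x <- generate_tas_counts(rep(0.05, 200), 1000, error_rate = 0, seed = 13)
  pooled <- sum(x$alt_count) / sum(x$depth)
  expect_lt(abs(pooled - 0.05), 0.005)
})

test_that("inconsistent plants are rejected", {
  ref <- generate_reference(2000, n_str = 0, n_polyA = 0, n_dup_blocks = 0,
                            n_mcr = 0, seed = 2)
  rb <- substring(ref$sequence, 900, 900)
  alts <- setdiff(c("A", "C", "G", "T"), rb)
  expect_error(
    plant_mutations(ref, c(900, 900), alts[1:2], origin = "somatic",
                    true_aaf = 0.1, carrier = c("case", "both")),
    "inconsistent plant"
  )
  expect_error(
    plant_mutations(ref, 900, rb, origin = "somatic", true_aaf = 0.1),
    "alt base equals"
  )
  expect_error(
    plant_mutations(ref, 900, alts[1], origin = "somatic", true_aaf = 0.6),
    "true_aaf"
  )
})
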