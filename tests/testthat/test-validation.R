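test_that("allele fractions and their display rounding reproduce worked examples", {
  expect_equal(round(compute_aaf(13152, 179669), 2), 7.32)
  expect_equal(round(compute_aaf(12, 182798), 3), 0.007)
  expect_equal(compute_aaf(0, 100), 0)
  expect_equal(format_aaf(compute_aaf(13152, 179669)), 7.32)
  expect_equal(format_aaf(compute_aaf(12, 182798)), 0.007)
  expect_error(compute_aaf(0, 0), "no coverage")

  # scale invariance: multiplying all counts by k leaves the AAF unchanged
  x <- data.frame(ref_count = 900L, alt_count = 60L, other_count = 40L)
  for (k in c(2L, 10L, 1000L)) {
    expect_equal(compute_aaf(x * k), compute_aaf(x))
  }
})

test_that("Phred scores convert to error percentages", {
  expect_equal(signif(phred_to_error_percent(25), 3), 0.316)
  expect_equal(phred_to_error_percent(10), 10)
  expect_equal(phred_to_error_percent(20), 1)
  expect_error(phred_to_error_percent(-1))
})

test_that("validation uses a strict threshold on the case AAF only", {
  v <- validate_site(c(7.32, 0.316, 1.12, 0.2), c(0.007, 0, 0, 0.5))
  expect_equal(v$validated, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(v$control_clean, c(TRUE, TRUE, TRUE, FALSE))
  # monotone in the case AAF; the validated flag ignores the control AAF
  expect_true(validate_site(0.4, 99)$validated)
  expect_false(validate_site(0.3, 0)$validated)
})

test_that("null amplicon sites almost never cross the validation threshold", {
  x <- generate_tas_counts(rep(0, 1000L), 200000L,
                           error_rate = 0.00316, seed = 8)
  false_rate <- mean(compute_aaf(x) > phred_to_error_percent(25))
  expect_lt(false_rate, 0.001)
})

test_that("Fisher test matches hypergeometric enumeration and published bounds", {
  # identical ratios: no evidence of difference
  expect_equal(fisher_ref_alt(c(100L, 10L), c(100L, 10L)), 1)
  # the deep-amplicon case/control counts of the strongest validated site
  p <- fisher_ref_alt(c(166517L, 13152L), c(182786L, 12L))
  expect_lt(p, 2.2e-16)
  # exact agreement with enumeration on small tables
  expect_equal(fisher_ref_alt(c(5L, 1L), c(1L, 5L)),
               oracle_fisher(c(5L, 1L), c(1L, 5L)), tolerance = 1e-12)
  withr::with_seed(15, {
    for (rep in 1:60) {
      tot <- sample(4:60, 1L)
      a <- sample.int(tot - 3L, 1L)
      b <- sample.int(tot - a - 2L, 1L)
      c_ <- sample.int(tot - a - b - 1L, 1L)
      d <- tot - a - b - c_
      tab <- list(case = c(a, b), control = c(c_, d))
      if (any(tab$case + tab$control == 0L)) next
      expect_equal(fisher_ref_alt(tab$case, tab$control),
                   oracle_fisher(tab$case, tab$control), tolerance = 1e-10,
                   info = paste(a, b, c_, d))
    }
  })
  expect_error(fisher_ref_alt(c(0L, 0L), c(5L, 5L)), "degenerate")
})

test_that("post hoc t-tests behave at the boundaries and match reconstructions", {
  # identical groups: t = 0, one-sided p = 0.5
  r <- posthoc_t_test(c(10, 20, 30), c(10, 20, 30))
  expect_equal(r$p_value, 0.5)

  # reconstruction from the published group summaries (means 81.6 vs 44.2,
  # sds 14.0 vs 12.5, n 7 vs 21): pooled-variance p is on the order of 1e-7
  m1 <- 81.6; s1 <- 14.0; n1 <- 7L
  m2 <- 44.2; s2 <- 12.5; n2 <- 21L
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t_student <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_student <- stats::pt(t_student, n1 + n2 - 2, lower.tail = FALSE)
  expect_gt(p_student, 1e-8)
  expect_lt(p_student, 1e-6)
  # the same reconstruction through the package's Student option
  x <- withr::with_seed(2, scale(stats::rnorm(n1)))
  y <- withr::with_seed(3, scale(stats::rnorm(n2)))
  xs <- as.numeric(m1 + s1 * x)  # exact mean m1, sd s1
  ys <- as.numeric(m2 + s2 * y)
  r2 <- posthoc_t_test(xs, ys, var_equal = TRUE)
  expect_equal(r2$p_value, p_student, tolerance = 1e-10)
  expect_equal(r2$mean_validated, m1)
  expect_equal(r2$sd_unvalidated, s2)
  # Welch default differs but stays strongly significant
  r3 <- posthoc_t_test(xs, ys)
  expect_lt(r3$p_value, 1e-3)

  # Welch p agrees with a permutation test within Monte-Carlo error
  a <- withr::with_seed(11, stats::rnorm(10, mean = 0.6))
  b <- withr::with_seed(12, stats::rnorm(12))
  pw <- posthoc_t_test(a, b)$p_value
  pp <- oracle_perm_p(a, b, B = 40000L, seed = 4)
  expect_lt(abs(pw - pp), 0.03)

  expect_error(posthoc_t_test(1, c(1, 2)), "insufficient data")
})

test_that("depth-threshold performance counts sensitivity and specificity", {
  # published configuration: 7 validated all > 60; 19 of 21 unvalidated <= 60
  dp <- c(rep(c(70, 75, 80, 85, 90, 95, 100)),
          c(rep(45, 19), 65, 70))
  lab <- c(rep(TRUE, 7L), rep(FALSE, 21L))
  perf <- dp_threshold_performance(dp, lab, 60)
  expect_equal(perf$sensitivity, 100)
  expect_equal(round(perf$specificity, 1), 90.5)

  perf2 <- dp_threshold_performance(c(100, 90, 80), c(TRUE, TRUE, FALSE), 60)
  expect_equal(perf2$sensitivity, 100)
  expect_equal(perf2$specificity, 0)

  # naive counting oracle on random labels/values
  withr::with_seed(31, {
    dpv <- sample(20:120, 50L, replace = TRUE)
    lbl <- sample(c(TRUE, FALSE), 50L, replace = TRUE, prob = c(.3, .7))
    got <- dp_threshold_performance(dpv, lbl, 60)
    expect_equal(got$sensitivity, 100 * sum(dpv > 60 & lbl) / sum(lbl))
    expect_equal(got$specificity, 100 * sum(dpv <= 60 & !lbl) / sum(!lbl))
  })

  expect_error(dp_threshold_performance(c(1, 2), c(TRUE, TRUE), 60),
               "undefined metric")
})

test_that("concordance arithmetic and credible-site filtering are exact", {
  mk <- function(n, gt) data.frame(
    chrom = "chr1", pos = seq_len(n), ref_count = 43L, alt_count = 42L,
    other_count = 0L, gt = gt, gq = 99L, qual = 2000
  )
  a <- mk(1000L, "0/1")
  b <- mk(1000L, "0/1")
  r <- monozygosity_concordance(a, b)
  expect_equal(r$concordance, 100)
  expect_equal(r$n_sites, 1000L)

  b$gt[5L] <- "1/1"
  r2 <- monozygosity_concordance(a, b)
  expect_equal(r2$concordance, 99.9)
  expect_equal(r2$n_discordant, 1L)

  # sites outside the credible filters do not enter the denominator
  b$gt[5L] <- "0/1"
  a$alt_count[1:10] <- 10L   # depth 53: fails the 80-90 window
  expect_equal(monozygosity_concordance(a, b)$n_sites, 990L)
  a$qual[11L] <- 500
  expect_equal(monozygosity_concordance(a, b)$n_sites, 989L)
  a$gq[12L] <- 80L
  expect_equal(monozygosity_concordance(a, b)$n_sites, 988L)

  a$qual <- 1
  expect_error(monozygosity_concordance(a, b), "no credible sites")
})

test_that("the mutation spectrum collapses strands and tallies classes", {
  sp <- mutation_spectrum(c("G"), c("A"))
  expect_equal(sp$count[sp$class == "C>T"], 1L)

  withr::with_seed(41, {
    ref <- sample(c("A", "C", "G", "T"), 60L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  "", USE.NAMES = FALSE)
    sp2 <- mutation_spectrum(ref, alt)
    expect_equal(sum(sp2$count), 60L)
    # naive tally of one class
    cmp <- c(A = "T", C = "G", G = "C", T = "A")
    want_ct <- sum((ref == "C" & alt == "T") | (ref == "G" & alt == "A"))
    expect_equal(sp2$count[sp2$class == "C>T"], want_ct)
  })

  expect_error(mutation_spectrum("A", "A"), "ref equals alt")
  expect_error(mutation_spectrum("N", "A"), "single A/C/G/T")
})
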