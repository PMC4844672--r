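test_that("read extension covers the fragment from the 5' end, per strand", {
  lens <- c(chr1 = 1000L)
  tr <- extend_reads(data.frame(chrom = "chr1", pos = 100L, strand = "+"),
                     130L, lens)
  v <- unclass(tr)$chr1
  expect_equal(which(v == 1) - 1L, 100:229)

  tr2 <- extend_reads(data.frame(chrom = "chr1", pos = c(100L, 100L),
                                 strand = "+"), 130L, lens)
  expect_equal(unclass(tr2)$chr1, 2 * v)

  tr3 <- extend_reads(data.frame(chrom = "chr1", pos = 500L, strand = "-"),
                      130L, lens)
  expect_equal(which(unclass(tr3)$chr1 == 1) - 1L, 371:500)

  expect_error(extend_reads(data.frame(chrom = "chr1", pos = 1000L,
                                       strand = "+"), 130L, lens),
               "outside chromosome")
})

test_that("read extension matches the per-base oracle and conserves mass", {
  set.seed(5)
  n <- 400L
  for (rep_ in 1:10) {
    reads <- data.frame(chrom = "chr1",
                        pos = sample.int(n, 25L) - 1L,
                        strand = sample(c("+", "-"), 25L, replace = TRUE))
    fl <- sample(10:60, 1L)
    tr <- extend_reads(reads, fl, c(chr1 = n))
    want <- bf_extend_reads(reads, fl, n)
    expect_equal(unclass(tr)$chr1, want)
    expect_equal(sum(unclass(tr)$chr1), sum(want))  # truncation-aware mass
  }
})

test_that("rudimentary peak finding returns maximal supra-cutoff runs", {
  v <- c(rep(0, 10), rep(25, 20), rep(0, 10))
  pk <- rudimentary_peak_find(coverage_track(list(chr1 = v)), cutoff = 20)
  expect_equal(pk$start, 10L)
  expect_equal(pk$end, 30L)

  expect_equal(nrow(rudimentary_peak_find(
    coverage_track(list(chr1 = rep(5, 50))), cutoff = 20)), 0L)

  set.seed(9)
  for (rep_ in 1:10) {
    v <- as.numeric(rpois(300L, 12))
    got <- rudimentary_peak_find(coverage_track(list(chr1 = v)),
                                 cutoff = 13, min_gap = 0L)
    want <- bf_peaks(v, 13)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("nearby peaks merge when a minimum gap is requested", {
  v <- c(rep(25, 10), rep(0, 5), rep(30, 10))
  tr <- coverage_track(list(chr1 = v))
  expect_equal(nrow(rudimentary_peak_find(tr, 20, min_gap = 0L)), 2L)
  merged <- rudimentary_peak_find(tr, 20, min_gap = 6L)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(0L, 25L))
})

test_that("replicate scale fit recovers exact and noisy slopes", {
  x <- 1:10
  expect_equal(fit_replicate_scale(x, 2 * x)$m, 2)
  expect_equal(fit_replicate_scale(x, x)$m, 1)
  expect_error(fit_replicate_scale(rep(0, 5), rep(0, 5)), "zero")

  set.seed(14)
  x <- runif(200L, 10, 500)
  y <- 1.5 * x * exp(rnorm(200L, 0, 0.1))
  m_hat <- fit_replicate_scale(x, y)$m
  expect_gte(m_hat, 1.4)
  expect_lte(m_hat, 1.6)
})

test_that("replicate fusion rescales replicate 2 onto replicate 1", {
  t1 <- coverage_track(list(chr1 = c(10, 0, 4)))
  expect_equal(unclass(fuse_replicates(t1, t1, 1))$chr1, c(10, 0, 4))

  t2 <- coverage_track(list(chr1 = c(20, 0, 8)))
  expect_equal(unclass(fuse_replicates(t1, t2, 2))$chr1, c(10, 0, 4))

  z <- coverage_track(list(chr1 = rep(0, 3)))
  expect_equal(unclass(fuse_replicates(z, z, 1.7))$chr1, rep(0, 3))

  t3 <- coverage_track(list(chr1 = c(1, 2)))
  expect_error(fuse_replicates(t1, t3, 1), "mismatched")
})

test_that("genotype scale fit recovers planted depth factors", {
  peaks <- genomic_intervals("chr1", (0:19) * 50, (0:19) * 50 + 40)
  base <- as.numeric(rep(30, 1000L))
  ctrl <- coverage_track(list(chr1 = base))
  expect_equal(fit_genotype_scale(
    coverage_track(list(chr1 = 3 * base)), ctrl, peaks)$m, 3)
  expect_equal(fit_genotype_scale(ctrl, ctrl, peaks)$m, 1)
  expect_error(fit_genotype_scale(
    ctrl, coverage_track(list(chr1 = rep(0, 1000))), peaks), "zero")

  set.seed(30)
  peaks100 <- genomic_intervals("chr1", (0:99) * 100, (0:99) * 100 + 60)
  lam <- runif(10000L, 20, 60)
  ctrl <- coverage_track(list(chr1 = as.numeric(rpois(10000L, lam))))
  geno <- coverage_track(list(chr1 = as.numeric(rpois(10000L, 2.5 * lam))))
  m_hat <- fit_genotype_scale(geno, ctrl, peaks100)$m
  expect_gte(m_hat, 2.3)
  expect_lte(m_hat, 2.7)
})

test_that("depth rescaling divides every position by m'", {
  tr <- coverage_track(list(chr1 = rep(10, 8)))
  expect_equal(unclass(apply_genotype_scale(tr, 1))$chr1, rep(10, 8))
  expect_equal(unclass(apply_genotype_scale(tr, 2))$chr1, rep(5, 8))
})

test_that("CFR is the normalized coverage ratio with a low-coverage cap", {
  reg <- genomic_intervals("chr1", 0, 10, id = "r1")
  mk <- function(total) coverage_track(list(chr1 = rep(total / 10, 10)))
  r <- compute_cfr(reg, mk(50), mk(10), cap = 300, min_alt_coverage = 1)
  expect_equal(r$cfr, 5)
  expect_false(r$capped)

  r2 <- compute_cfr(reg, mk(50), mk(0), cap = 300, min_alt_coverage = 1)
  expect_equal(r2$cfr, 300)
  expect_true(r2$capped)

  r3 <- compute_cfr(reg, mk(40), mk(40), cap = 300, min_alt_coverage = 1)
  expect_equal(r3$cfr, 1)

  # scale invariance: multiplying both tracks by c leaves CFR unchanged
  r4 <- compute_cfr(reg, mk(50 * 7), mk(10 * 7), cap = 300,
                    min_alt_coverage = 1)
  expect_equal(r4$cfr, r$cfr)
})

test_that("two-step normalization of a genotype against itself is the identity", {
  fx <- noise_free_fixture()
  m_hat <- fit_replicate_scale(
    region_coverage(fx$tracks$ref_rep1, fx$regions),
    region_coverage(fx$tracks$ref_rep2, fx$regions))$m
  expect_equal(m_hat, fx$config$m_true, tolerance = 1e-12)

  fused <- fuse_replicates(fx$tracks$ref_rep1, fx$tracks$ref_rep2, m_hat)
  bg <- rudimentary_peak_find(fx$tracks$control, cutoff = 20, min_gap = 30L)
  mp <- fit_genotype_scale(fused, fx$tracks$control, bg)$m
  expect_equal(mp, 1, tolerance = 1e-9)

  norm <- apply_genotype_scale(fused, mp)
  cfr <- compute_cfr(fx$regions, norm, norm, min_alt_coverage = 0)
  expect_equal(cfr$cfr, rep(1, nrow(fx$regions)))
  expect_false(any(cfr$capped))
})
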