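test_that("window scoring follows the max-0 additive convention", {
  w <- toy_pwm()
  bases <- c("A", "C", "G", "T")
  consensus <- paste(bases[apply(unclass(w), 1, which.max)], collapse = "")
  worst <- paste(bases[apply(unclass(w), 1, which.min)], collapse = "")
  expect_equal(score_window(w, consensus), 0)
  expect_equal(score_window(w, worst), pwm_min_score(w))
  expect_error(score_window(w, "ACG"), "length")
  expect_equal(score_window(w, "ANGTC"), -Inf)

  set.seed(4)
  for (rep_ in 1:25) {
    s <- random_sequence(pwm_length(w))
    expect_equal(score_window(w, s), bf_score(unclass(w), s))
  }
})

test_that("arbitrary log-odds matrices can be rescaled to max-0", {
  raw <- matrix(rnorm(20), ncol = 4)
  expect_error(pwm(raw), "maximum 0")
  x <- pwm(raw, normalize = TRUE)
  expect_equal(apply(unclass(x), 1, max), rep(0, 5))
  expect_lte(pwm_min_score(x), 0)
})

test_that("PWM TSV round trip preserves scores bit-exactly", {
  set.seed(8)
  x <- gen_pwm(19L, seed = 8L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(x, p)
  back <- read_pwm(p)
  expect_identical(unclass(back), unclass(x), ignore_attr = TRUE)
  s <- random_sequence(19L)
  expect_identical(score_window(back, s), score_window(x, s))
})

test_that("scanning finds planted sites and matches brute force", {
  w <- toy_pwm()
  bases <- c("A", "C", "G", "T")
  consensus <- paste(bases[apply(unclass(w), 1, which.max)], collapse = "")
  seq_ <- paste0("TTTTT", consensus, "TTTTT")
  hits <- scan_sequence(w, seq_, threshold = 0)
  # threshold 0 admits only exact consensus matches on either strand
  expect_true(any(hits$offset == 5L & hits$strand == "+"))
  expect_true(all(hits$score == 0))

  set.seed(12)
  for (rep_ in 1:5) {
    s <- random_sequence(80L)
    got <- scan_sequence(w, s, threshold = pwm_min_score(w))
    expect_equal(nrow(got), nchar(s) - pwm_length(w) + 1L)
    want <- bf_scan(unclass(w), s, pwm_min_score(w))
    expect_equal(got$offset, want$offset)
    expect_equal(got$score, want$score)
    expect_equal(got$strand, want$strand)
  }
})

test_that("scanning the reverse complement mirrors the site list", {
  w <- toy_pwm()
  set.seed(13)
  L <- pwm_length(w)
  for (rep_ in 1:5) {
    s <- random_sequence(60L)
    fwd <- scan_sequence(w, s)
    rev_ <- scan_sequence(w, revcomp(s))
    n <- nchar(s)
    mirrored <- sort(n - L - rev_$offset)
    expect_equal(fwd$offset, mirrored)
    expect_equal(sort(fwd$score), sort(rev_$score))
  }
})

test_that("GC content counts G+C over non-N bases", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AATT"), 0.0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("ACGN"), 2 / 3)
  expect_error(gc_content("NNN"), "all N")
})

test_that("negative-set sampling is GC-matched, non-overlapping, seeded", {
  fx <- small_fixture()
  bound <- fx$regions[1:25, ]
  neg <- sample_negative_set(bound, fx$genome, gc_tol = 0.05, seed = 99L)
  expect_equal(nrow(neg), 25L)
  expect_equal(neg$end - neg$start, bound$end - bound$start)
  for (i in 1:25) {
    gc_b <- gc_content(substr(fx$genome[[bound$chrom[i]]],
                              bound$start[i] + 1L, bound$end[i]))
    expect_lte(abs(neg$gc[i] - gc_b), 0.05 + 1e-12)
  }
  expect_equal(nrow(intersect_regions(neg, bound)), 0L)

  neg2 <- sample_negative_set(bound, fx$genome, gc_tol = 0.05, seed = 99L)
  expect_identical(neg, neg2)
  ann <- sample_negative_set(bound[1:5, ], fx$genome,
                             annotation = fx$annotation, seed = 1L)
  expect_true(all(ann$category %in%
                    c("CDS", "intron", "upstream", "downstream",
                      "intergenic")))
})

test_that("window densities partition the scanned sites by unit score", {
  fx <- small_fixture()
  w <- fx$pwm
  regions <- fx$regions[1:10, ]
  wd <- window_densities(regions, fx$genome, w)
  expect_equal(ncol(wd$counts), ceiling(-pwm_min_score(w)))
  for (i in 1:10) {
    sites <- scan_sequence(w, substr(fx$genome[[regions$chrom[i]]],
                                     regions$start[i] + 1L, regions$end[i]))
    expect_equal(sum(wd$counts[i, ]), nrow(sites))  # windows partition scores
    # brute-force refilter per window
    for (j in c(1L, 5L, 20L)) {
      in_win <- sum(sites$score <= -(j - 1L) & sites$score > -j |
                      (j == 1L & sites$score == 0))
      expect_equal(wd$counts[i, j], in_win)
    }
  }
  expect_equal(wd$densities, wd$counts / ((regions$end - regions$start) / 1000))
})

test_that("threshold is the end of the contiguous significant run", {
  set.seed(31)
  nw <- 40L
  n <- 60L
  pos <- matrix(0, n, nw)
  neg <- matrix(0, n, nw)
  # enrich windows 1..25 ([0;-1] .. [-24;-25]) only
  for (j in 1:25) pos[, j] <- rpois(n, 3)
  for (j in 1:nw) neg[, j] <- rpois(n, 0.05)
  res <- determine_threshold(pos, neg)
  expect_equal(res$threshold, -25L)
  expect_true(all(res$table$significant[1:25]))

  same <- matrix(rpois(n * nw, 1), n, nw)
  res2 <- determine_threshold(same, same)
  expect_true(is.na(res2$threshold))

  expect_error(determine_threshold(pos, neg[, 1:10]), "window grids")
})

test_that("a gap in significance stops the run even if deeper windows pass", {
  set.seed(32)
  n <- 60L
  pos <- matrix(0, n, 10L)
  neg <- matrix(0, n, 10L)
  for (j in c(1:3, 6:8)) pos[, j] <- rpois(n, 4)
  res <- determine_threshold(pos, neg)
  expect_equal(res$threshold, -3L)
})

test_that("per-region best score and density agree with the scan", {
  fx <- small_fixture()
  w <- fx$pwm
  for (i in c(2L, 7L, 19L)) {
    reg <- fx$regions[i, ]
    sites <- scan_sequence(w, substr(fx$genome[[reg$chrom]],
                                     reg$start + 1L, reg$end))
    expect_equal(region_best_score(reg, fx$genome, w), max(sites$score))
    thr <- -20
    expect_equal(region_site_density(reg, fx$genome, w, thr),
                 sum(sites$score >= thr) * 1000 / (reg$end - reg$start))
  }
  tiny <- genomic_intervals("chr1", 0, 5)
  expect_error(region_best_score(tiny, fx$genome, w), "shorter")
})

test_that("pairwise distances are inter-footprint gaps", {
  expect_equal(pairwise_site_distances(c(0, 20), 19L), 1)
  expect_equal(pairwise_site_distances(c(0, 19), 19L), 0)
  expect_equal(pairwise_site_distances(c(5), 19L), numeric(0))

  set.seed(17)
  for (rep_ in 1:10) {
    offs <- sort(sample.int(300L, sample(3:8, 1L)))
    got <- sort(pairwise_site_distances(offs, 19L))
    expect_equal(got, sort(bf_pairwise_gaps(offs, 19L)))
    expect_equal(length(got), choose(length(offs), 2))
  }
})

test_that("unit-gap pair counting matches brute force", {
  expect_equal(count_unit_gap_pairs(integer(0), 19L), 0)
  expect_equal(count_unit_gap_pairs(c(0, 20), 19L), 1)
  expect_equal(count_unit_gap_pairs(c(0, 20, 40), 19L), 2)
  set.seed(18)
  for (rep_ in 1:10) {
    offs <- sort(sample.int(200L, 6L))
    expect_equal(count_unit_gap_pairs(offs, 19L),
                 sum(bf_pairwise_gaps(offs, 19L) == 1))
  }
})

test_that("decile spacing matrix conserves the pooled pair count", {
  set.seed(19)
  n <- 40L
  recs <- data.frame(id = paste0("r", 1:n), cfr = runif(n, 1, 50),
                     rank = 1:n)
  site_map <- lapply(1:n, function(i) {
    sort(sample.int(250L, sample(1:6, 1L)))
  })
  names(site_map) <- recs$id
  mat <- spacing_by_decile(recs, site_map, L = 19L, max_distance = 40L)
  expect_equal(dim(mat), c(10L, 40L))
  total <- sum(vapply(site_map, function(o) {
    g <- bf_pairwise_gaps(o, 19L)
    sum(g >= 0 & g < 40)
  }, numeric(1)))
  expect_equal(sum(mat), total)

  single <- lapply(site_map, function(o) o[1L])
  names(single) <- recs$id
  expect_equal(sum(spacing_by_decile(recs, single, 19L)), 0)

  expect_error(spacing_by_decile(recs[1:5, ], site_map, 19L), "10")
})
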