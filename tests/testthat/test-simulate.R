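test_that("generated genomes hit the requested GC and are seed-stable", {
  g <- gen_genome(1e5, gc = 0.5, seed = 61L, gc_sd = 0)
  gc <- gc_content(g[["chr1"]])
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
  expect_identical(g, gen_genome(1e5, gc = 0.5, seed = 61L, gc_sd = 0))
  expect_error(gen_genome(100, gc = 1.0, seed = 1L), "gc")

  # block heterogeneity preserves the genome-wide mean
  g2 <- gen_genome(2e5, gc = 0.36, seed = 62L, gc_sd = 0.08)
  expect_lt(abs(gc_content(g2[["chr1"]]) - 0.36), 0.03)
  g3 <- gen_genome(9e4, gc = 0.4, seed = 63L, n_chrom = 3L)
  expect_equal(names(g3), c("chr1", "chr2", "chr3"))
  expect_equal(sum(nchar(g3)), 9e4)
})

test_that("generated PWMs follow the max-0 convention and are informative", {
  x <- gen_pwm(19L, seed = 64L)
  expect_equal(apply(unclass(x), 1, max), rep(0, 19))
  expect_lt(pwm_min_score(x), -10)
  bases <- c("A", "C", "G", "T")
  consensus <- paste(bases[apply(unclass(x), 1, which.max)], collapse = "")
  expect_equal(score_window(x, consensus), 0)
})

test_that("site planting reaches the target score within tolerance", {
  x <- gen_pwm(19L, seed = 65L)
  g <- gen_genome(500, gc = 0.4, seed = 65L)
  res0 <- plant_site(g, x, "chr1", 100L, target_score = 0, tol = 0.5)
  expect_equal(res0$score, 0)
  expect_equal(score_window(x, substr(res0$genome[["chr1"]], 101, 119)),
               0)

  for (target in c(-5, -12, -19.5)) {
    res <- plant_site(g, x, "chr1", 200L, target_score = target, tol = 1,
                      seed = 66L)
    expect_lte(abs(res$score - target), 1)
    expect_equal(
      score_window(x, substr(res$genome[["chr1"]], 201, 200 + 19)),
      res$score)
  }
  expect_error(plant_site(g, x, "chr1", 10L, target_score = -1000),
               "outside")
})

test_that("noise-free tracks reproduce planted fold reductions exactly", {
  cfg <- sim_config(seed = 1L, noise = "none", background_floor = 0,
                    m_true = 1, mprime_true = 1)
  lens <- c(chr1 = 5e4)
  regions <- genomic_intervals("chr1", 1000, 1300, id = "r1")
  regions$amplitude <- 60
  regions$fold_reduction <- 5
  bg <- genomic_intervals("chr1", 10000, 10400)
  tr <- gen_tracks(cfg, lens, regions, bg, seed = 2L)
  expect_equal(region_coverage(tr$ref_rep1, regions) /
                 region_coverage(tr$alt_rep1, regions), 5)
  # control carries background peaks but no bound-region signal
  expect_equal(region_coverage(tr$control, regions), 0)
  expect_gt(region_coverage(tr$control, bg), 0)
  # replicate 2 scales by m_true; mutant library by mprime_true
  cfg2 <- sim_config(seed = 1L, noise = "none", background_floor = 0,
                     m_true = 2, mprime_true = 3)
  tr2 <- gen_tracks(cfg2, lens, regions, bg, seed = 2L)
  expect_equal(unclass(tr2$ref_rep2)$chr1, 2 * unclass(tr2$ref_rep1)$chr1)
  expect_equal(region_coverage(tr2$alt_rep1, regions),
               3 * region_coverage(tr$alt_rep1, regions))
  # zero-occupancy regions are flat in the mutant
  regions$fold_reduction <- Inf
  tr3 <- gen_tracks(cfg, lens, regions, bg, seed = 2L)
  expect_equal(region_coverage(tr3$alt_rep1, regions), 0)
})

test_that("fixture files are consistent with the truth manifest", {
  fx <- small_fixture()
  genome <- read_fasta(fx$paths$genome)
  x <- read_pwm(fx$paths$pwm)
  L <- pwm_length(x)
  manifest <- jsonlite::read_json(fx$paths$manifest)
  regions <- read_bed(fx$paths$regions)
  expect_equal(regions$id, fx$regions$id)

  for (rec in manifest$regions[c(1L, 10L, 25L, 60L)]) {
    reg <- regions[regions$id == rec$id, ]
    offs <- unlist(rec$site_offsets)
    scores <- unlist(rec$site_scores)
    for (k in seq_along(offs)) {
      planted <- substr(genome[[reg$chrom]],
                        reg$start + offs[k] + 1L,
                        reg$start + offs[k] + L)
      expect_equal(score_window(x, planted), scores[k], tolerance = 1e-9)
    }
    expect_equal(count_unit_gap_pairs(offs, L) >= rec$unit_gap_pairs, TRUE)
  }

  # openness flags round-trip through the emitted DHS BED
  open_set <- read_open_set(fx$paths$open_bed)
  for (i in seq_len(nrow(regions))) {
    expect_equal(is_open_region(regions[i, ], open_set),
                 fx$truth$open[i])
  }
})

test_that("identical seeds give byte-identical fixture directories", {
  d1 <- file.path(tempdir(), "fx_det_a")
  d2 <- file.path(tempdir(), "fx_det_b")
  cfg <- sim_config(genome_length = 1e5, n_regions = 15L,
                    n_background = 10L, seed = 77L)
  gen_fixture(cfg, d1)
  gen_fixture(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})
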