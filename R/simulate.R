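#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults
#' sized so that the full pipeline exercises realistic structure in
#' minutes on one CPU: one 2-Mb chromosome, 300 bound regions of 300 bp,
#' 100 control background peaks, reads extended to 130 bp, Poisson read
#' noise with at least ~50 expected reads per peak.
#'
#' @param genome_length Total genome length in bp.
#' @param n_chrom Number of chromosomes (length split evenly).
#' @param gc Genome GC fraction (Arabidopsis-like default 0.36).
#' @param n_regions Number of bound regions.
#' @param region_length Bound-region length in bp.
#' @param pwm_length Motif length in bp.
#' @param fragment_length Read extension length in bp.
#' @param m_true Replicate-2 / replicate-1 depth ratio (both genotypes).
#' @param mprime_true Mutant-genotype library depth relative to the
#'   control (the reference genotype is emitted at control depth).
#' @param n_background Number of shared background peaks.
#' @param background_amplitude Peak height of background peaks (expected
#'   reads per base at the apex).
#' @param background_width Background peak width in bp.
#' @param background_floor Expected nonspecific read depth per base.
#' @param amplitude_range Range of bound-region peak heights in the
#'   reference genotype.
#' @param site_score_floor Most negative planted site score; the
#'   enrichment of bound regions over the negative set extends down to
#'   this score, which is what the threshold procedure should recover.
#' @param best_score_range Range of the per-region best-site score.
#'   Every bound region carries at least one site of moderate-to-high
#'   affinity (bound regions without any reasonable match are not called
#'   as peaks in the first place), while the additional low-affinity
#'   sites extend down to `site_score_floor`.
#' @param n_zero_occupancy Regions with no mutant-genotype signal at all
#'   (their CFR must be capped).
#' @param noise `"poisson"` (default) or `"none"` for exact expected
#'   counts.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6, n_chrom = 1L, gc = 0.36,
                       n_regions = 300L, region_length = 300L,
                       pwm_length = 19L, fragment_length = 130L,
                       m_true = 1.3, mprime_true = 1.8,
                       n_background = 100L, background_amplitude = 40,
                       background_width = 400L, background_floor = 0.25,
                       amplitude_range = c(50, 100),
                       site_score_floor = -20,
                       best_score_range = c(-16, 0),
                       n_zero_occupancy = 3L,
                       noise = c("poisson", "none"), seed) {
  noise <- match.arg(noise)
  stopifnot(genome_length >= 1, gc > 0, gc < 1, n_regions >= 10L,
            m_true > 0, mprime_true > 0, site_score_floor < 0,
            best_score_range[1L] >= site_score_floor,
            n_zero_occupancy >= 0L, !missing(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a random genome with block-wise GC heterogeneity
#'
#' Bases are drawn independently with `P(G) + P(C)` varying between
#' consecutive blocks: each block's GC fraction is Beta-distributed with
#' mean `gc` and standard deviation `gc_sd`. Real genomes are GC
#' mosaics, and that heterogeneity is what makes GC-matched negative-set
#' sampling a meaningful constraint; `gc_sd = 0` recovers the i.i.d.
#' uniform-GC genome.
#'
#' @param length Total length in bp.
#' @param gc Mean GC fraction in `(0, 1)`.
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param gc_sd Between-block standard deviation of the GC fraction.
#' @param block_length Block size in bp.
#' @return Named character vector of sequences.
#' @export
gen_genome <- function(length, gc, seed, n_chrom = 1L, gc_sd = 0.08,
                       block_length = 1000L) {
  stopifnot(length >= 1, gc > 0, gc < 1, gc_sd >= 0)
  with_seed(seed, {
    per <- rep(length %/% n_chrom, n_chrom)
    per[1L] <- per[1L] + length %% n_chrom
    seqs <- vapply(per, function(n) {
      n_blocks <- ceiling(n / block_length)
      block_gc <- if (gc_sd == 0) rep(gc, n_blocks) else {
        nu <- gc * (1 - gc) / gc_sd^2 - 1
        stats::rbeta(n_blocks, gc * nu, (1 - gc) * nu)
      }
      p_gc <- rep(block_gc, each = block_length, length.out = n)
      u <- stats::runif(n)
      is_gc <- u < p_gc
      half <- stats::runif(n) < 0.5
      base <- ifelse(is_gc, ifelse(half, "G", "C"),
                     ifelse(half, "A", "T"))
      paste(base, collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    seqs
  })
}

#' Generate a random informative PWM
#'
#' One consensus base per position scores 0; the other three bases get
#' random penalties drawn from `penalty_range`, giving a worst score
#' well below -10 for the default length of 19. The default penalties
#' make the matrix sharp enough that random genomic sequence rarely
#' scores within 25 units of the optimum, as a highly predictive motif
#' model should.
#'
#' @param L Motif length (>= 2).
#' @param seed Integer seed.
#' @param penalty_range Range of per-base substitution penalties.
#' @return A `pwm`.
#' @export
gen_pwm <- function(L, seed, penalty_range = c(1.5, 6)) {
  stopifnot(L >= 2L)
  with_seed(seed, {
    w <- matrix(0, nrow = L, ncol = 4L)
    for (i in seq_len(L)) {
      cons <- sample.int(4L, 1L)
      w[i, -cons] <- -stats::runif(3L, penalty_range[1L], penalty_range[2L])
    }
    pwm(w)
  })
}

pwm_consensus <- function(x) {
  bases <- c("A", "C", "G", "T")
  paste(bases[apply(unclass(x), 1L, which.max)], collapse = "")
}

#' Plant a motif instance of controlled score into the genome
#'
#' Writes an L-mer at the given position whose plus-strand score is
#' within `tol` of `target_score`, found by hill-climbing on single-base
#' substitutions starting from the consensus.
#'
#' @param genome Named character vector of sequences.
#' @param x A `pwm`.
#' @param chrom,position Chromosome and 0-based start of the planted
#'   window.
#' @param target_score Desired score (in `[min_score, 0]`).
#' @param tol Acceptable absolute score deviation.
#' @param seed Optional seed for tie-breaking among substitutions.
#' @return List with `genome` (modified) and `score` (achieved).
#' @export
plant_site <- function(genome, x, chrom, position, target_score, tol = 0.5,
                       seed = NULL) {
  L <- pwm_length(x)
  if (target_score < pwm_min_score(x) || target_score > 0) {
    stop("target score ", target_score, " outside [",
         pwm_min_score(x), ", 0]")
  }
  if (position + L > nchar(genome[[chrom]])) {
    stop("planted window exceeds chromosome length")
  }
  w <- unclass(x)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    cur <- base_index(pwm_consensus(x))
    cur_score <- 0
    for (step in seq_len(200L)) {
      if (abs(cur_score - target_score) <= tol) break
      best_gain <- 0
      best_move <- NULL
      cur_err <- abs(cur_score - target_score)
      cands <- list()
      for (i in seq_len(L)) {
        for (b in seq_len(4L)) {
          if (b == cur[i]) next
          s2 <- cur_score - unname(w[i, cur[i]]) + unname(w[i, b])
          if (abs(s2 - target_score) < cur_err - 1e-12) {
            cands[[length(cands) + 1L]] <- c(i, b, s2)
          }
        }
      }
      if (length(cands) == 0L) break
      errs <- vapply(cands, function(m) abs(m[3L] - target_score),
                     numeric(1))
      pick <- cands[[sample(which(errs == min(errs)), 1L)]]
      cur[pick[1L]] <- pick[2L]
      cur_score <- pick[3L]
    }
    planted <- paste(bases[cur], collapse = "")
    substr(genome[[chrom]], position + 1L, position + L) <- planted
    list(genome = genome, score = cur_score)
  })
}

# Triangular kernel over [0, len): apex 1 at the centre.
triangular_kernel <- function(len) {
  x <- seq_len(len) - 0.5
  pmax(0, 1 - abs(x - len / 2) / (len / 2))
}

#' Generate the five expected-coverage tracks and sample read noise
#'
#' Builds expected per-base extended-read counts for the reference
#' genotype (two replicates), the mutant genotype (two replicates) and
#' the non-transgenic control, then draws Poisson counts per base.
#' Bound-region peaks use a triangular kernel; the mutant's amplitude at
#' each region is the reference amplitude divided by that region's
#' planted fold reduction. Background peaks and a flat floor are shared
#' by all five tracks; replicate 2 of each genotype is scaled by
#' `m_true` and the whole mutant library by `mprime_true`.
#'
#' @param config A `sim_config`.
#' @param chrom_lengths Named integer vector.
#' @param regions Bound-region intervals with columns `amplitude` and
#'   `fold_reduction` attached.
#' @param background Background-peak intervals.
#' @param seed Integer seed for the Poisson draws.
#' @return Named list of `coverage_track`s: `ref_rep1`, `ref_rep2`,
#'   `alt_rep1`, `alt_rep2`, `control`.
#' @export
gen_tracks <- function(config, chrom_lengths, regions, background, seed) {
  floor_ <- config$background_floor
  zero <- lapply(chrom_lengths, function(n) rep(0, n))
  names(zero) <- names(chrom_lengths)
  add_kernel <- function(vals, iv, amp) {
    for (i in seq_len(nrow(iv))) {
      len <- iv$end[i] - iv$start[i]
      idx <- (iv$start[i] + 1L):iv$end[i]
      vals[[iv$chrom[i]]][idx] <- vals[[iv$chrom[i]]][idx] +
        amp[i] * triangular_kernel(len)
    }
    vals
  }
  shared <- lapply(zero, function(v) v + floor_)
  shared <- add_kernel(shared, background,
                       rep(config$background_amplitude, nrow(background)))
  ref_e <- add_kernel(shared, regions, regions$amplitude)
  alt_amp <- ifelse(is.finite(regions$fold_reduction),
                    regions$amplitude / regions$fold_reduction, 0)
  alt_e <- add_kernel(shared, regions, alt_amp)
  alt_e <- lapply(alt_e, function(v) v * config$mprime_true)
  draw <- function(expect, scale = 1) {
    vals <- lapply(expect, function(v) {
      ev <- v * scale
      if (config$noise == "poisson") as.numeric(stats::rpois(length(ev), ev))
      else ev
    })
    coverage_track(vals)
  }
  with_seed(seed, list(
    ref_rep1 = draw(ref_e),
    ref_rep2 = draw(ref_e, config$m_true),
    alt_rep1 = draw(alt_e),
    alt_rep2 = draw(alt_e, config$m_true),
    control = draw(shared)
  ))
}

#' Generate open-chromatin intervals and a DHS signal track
#'
#' Regions flagged open receive a DNase-hypersensitive interval that
#' covers their centred half with a 10-bp margin and a high per-base DHS
#' signal that decreases with the planted fold reduction; closed regions
#' receive only a fragment smaller than their centred half and a low
#' signal, so the centred-half openness rule reproduces the flags
#' exactly.
#'
#' @param regions Bound-region intervals with columns `open` and
#'   `fold_reduction`.
#' @param chrom_lengths Named integer vector.
#' @param seed Integer seed.
#' @return List with `open_set` (interval `data.frame`) and `dhs_track`
#'   (`coverage_track`).
#' @export
gen_dhs <- function(regions, chrom_lengths, seed) {
  with_seed(seed, {
    vals <- lapply(chrom_lengths, function(n) rep(0, n))
    names(vals) <- names(chrom_lengths)
    iv <- vector("list", nrow(regions))
    for (i in seq_len(nrow(regions))) {
      len <- regions$end[i] - regions$start[i]
      quarter <- len %/% 4L
      f <- if (is.finite(regions$fold_reduction[i]))
        regions$fold_reduction[i] else 300
      if (regions$open[i]) {
        s <- max(0L, regions$start[i] + quarter - 10L)
        e <- min(chrom_lengths[[regions$chrom[i]]],
                 regions$end[i] - quarter + 10L)
        level <- 200 / f^0.7 * exp(stats::rnorm(1L, 0, 0.3))
      } else {
        # fragment strictly inside the centred half: region stays closed
        s <- regions$start[i] + quarter + 2L
        e <- s + max(2L, (len %/% 2L) %/% 4L)
        level <- stats::runif(1L, 0, 3)
      }
      iv[[i]] <- data.frame(chrom = regions$chrom[i], start = s, end = e)
      vals[[regions$chrom[i]]][(s + 1L):e] <-
        vals[[regions$chrom[i]]][(s + 1L):e] + level
    }
    iv <- do.call(rbind, iv)
    list(open_set = genomic_intervals(iv$chrom, iv$start, iv$end),
         dhs_track = coverage_track(vals))
  })
}

# Draw the per-region ground truth: planted site structure, fold
# reduction and openness, linked so that high fold reduction goes with
# poor best sites, more 1-bp-gap pairs, and closed chromatin.
draw_region_truth <- function(config, n) {
  n_extra <- 2L + stats::rpois(n, 3)
  unit_pairs <- sample(0:2, n, replace = TRUE, prob = c(0.70, 0.20, 0.10))
  best_target <- stats::runif(n, config$best_score_range[1L],
                              config$best_score_range[2L])
  logf <- log(2) + 0.8 * (-best_target / 10) + 0.7 * unit_pairs +
    0.15 * (n_extra - 4) + stats::rnorm(n, 0, 0.35)
  f <- pmin(pmax(exp(logf), 1.3), 60)
  closed <- stats::rbinom(n, 1L, stats::plogis(
    1.8 * (log(f) - stats::median(log(f))))) == 1L
  if (config$n_zero_occupancy > 0L) {
    zero <- sample.int(n, config$n_zero_occupancy)
    f[zero] <- Inf
    closed[zero] <- TRUE
  }
  data.frame(n_extra_sites = n_extra, unit_gap_pairs = unit_pairs,
             best_target = best_target, fold_reduction = f,
             open = !closed)
}

# Place sites inside one region: unit-gap pairs first, then isolated
# extras, rejecting footprint overlaps. The designated best site gets
# the region's best-score target; every other site is drawn below it,
# so the per-region best score is a controlled covariate. Returns
# region-relative offsets and target scores.
place_region_sites <- function(region_len, L, truth_row, score_floor) {
  taken <- integer(0)  # occupied site starts
  offsets <- integer(0)
  targets <- numeric(0)
  best <- truth_row$best_target
  lo <- 5L
  hi <- region_len - L - 5L
  ok <- function(o) all(abs(o - taken) >= L + 2L) && o >= lo && o <= hi
  for (p in seq_len(truth_row$unit_gap_pairs)) {
    for (try in 1:100) {
      o1 <- sample(lo:(hi - L - 1L), 1L)
      o2 <- o1 + L + 1L  # 1-bp gap between footprints
      if (ok(o1) && o2 <= hi && all(abs(o2 - taken) >= L + 2L)) {
        taken <- c(taken, o1, o2)
        offsets <- c(offsets, o1, o2)
        targets <- c(targets, stats::runif(2L, score_floor, best))
        break
      }
    }
  }
  best_placed <- FALSE
  for (k in seq_len(truth_row$n_extra_sites)) {
    for (try in 1:100) {
      o <- sample(lo:hi, 1L)
      if (ok(o)) {
        taken <- c(taken, o)
        offsets <- c(offsets, o)
        targets <- c(targets, if (!best_placed) best else
          stats::runif(1L, score_floor, best))
        best_placed <- TRUE
        break
      }
    }
  }
  list(offsets = offsets, targets = targets)
}

#' Generate a complete synthetic input directory with ground truth
#'
#' Writes everything the pipeline consumes — genome FASTA, PWM TSV,
#' bound-region BED, five bedGraph coverage tracks, annotation BEDs,
#' open-chromatin BED, DHS bedGraph — plus a JSON truth manifest, all
#' derived deterministically from the config seed. Site structure, fold
#' reduction and chromatin state are planted with the dependencies the
#' pipeline is meant to detect (see [sim_config()]).
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list: `dir`, `paths` (named file paths), `truth`
#'   (per-region `data.frame`), `site_map` (region-relative planted
#'   offsets by region id), `config`, plus in-memory `genome`, `pwm`,
#'   `tracks`, `regions`, `background`, `open_set`, `dhs_track`.
#' @export
gen_fixture <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    L <- config$pwm_length
    genome <- gen_genome(config$genome_length, config$gc,
                         seed = sample.int(1e6, 1L),
                         n_chrom = config$n_chrom)
    x <- gen_pwm(L, seed = sample.int(1e6, 1L))
    glen <- nchar(genome)

    # non-overlapping placements for bound regions and background peaks
    slots <- config$n_regions + config$n_background
    width <- max(config$region_length, config$background_width) + 200L
    placements <- list()
    occupied <- lapply(names(genome), function(ch) integer(0))
    names(occupied) <- names(genome)
    for (k in seq_len(slots)) {
      repeat {
        chr <- sample(names(genome), 1L, prob = glen)
        s <- sample.int(glen[[chr]] - width, 1L)
        blocks <- occupied[[chr]]
        if (all(abs(blocks - s) >= width)) {
          occupied[[chr]] <- c(blocks, s)
          placements[[k]] <- list(chrom = chr, start = s)
          break
        }
      }
    }
    reg_idx <- seq_len(config$n_regions)
    regions <- genomic_intervals(
      chrom = vapply(placements[reg_idx], `[[`, character(1), "chrom"),
      start = vapply(placements[reg_idx], `[[`, numeric(1), "start"),
      end = vapply(placements[reg_idx], `[[`, numeric(1), "start") +
        config$region_length,
      id = sprintf("reg_%03d", reg_idx), rank = reg_idx)
    bg_idx <- config$n_regions + seq_len(config$n_background)
    background <- genomic_intervals(
      chrom = vapply(placements[bg_idx], `[[`, character(1), "chrom"),
      start = vapply(placements[bg_idx], `[[`, numeric(1), "start"),
      end = vapply(placements[bg_idx], `[[`, numeric(1), "start") +
        config$background_width)

    truth <- draw_region_truth(config, config$n_regions)
    truth$id <- regions$id
    truth$amplitude <- stats::runif(config$n_regions,
                                    config$amplitude_range[1L],
                                    config$amplitude_range[2L])

    # plant motif instances and record achieved scores
    site_map <- list()
    score_map <- list()
    for (i in reg_idx) {
      pl <- place_region_sites(config$region_length, L, truth[i, ],
                               config$site_score_floor)
      achieved <- numeric(length(pl$offsets))
      # plant on the region substring, then write it back once, which
      # avoids copying the chromosome string per site
      reg_seq <- c(reg = interval_sequence(genome, regions[i, ]))
      for (k in seq_along(pl$offsets)) {
        res <- plant_site(reg_seq, x, "reg", pl$offsets[k],
                          pl$targets[k], tol = 0.5,
                          seed = sample.int(1e6, 1L))
        reg_seq <- res$genome
        achieved[k] <- res$score
      }
      substr(genome[[regions$chrom[i]]], regions$start[i] + 1L,
             regions$end[i]) <- reg_seq[["reg"]]
      ord <- order(pl$offsets)
      site_map[[regions$id[i]]] <- pl$offsets[ord]
      score_map[[regions$id[i]]] <- achieved[ord]
    }
    truth$n_sites <- lengths(site_map)[truth$id]
    truth$best_score <- vapply(score_map, max, numeric(1))[truth$id]

    regions_amp <- regions
    regions_amp$amplitude <- truth$amplitude
    regions_amp$fold_reduction <- truth$fold_reduction
    tracks <- gen_tracks(config, glen, regions_amp, background,
                         seed = sample.int(1e6, 1L))

    regions_dhs <- regions
    regions_dhs$open <- truth$open
    regions_dhs$fold_reduction <- truth$fold_reduction
    dhs <- gen_dhs(regions_dhs, glen, seed = sample.int(1e6, 1L))

    # simple annotation mosaic: consecutive blocks of random category
    ann <- list(CDS = list(), intron = list(), upstream = list(),
                downstream = list())
    for (chr in names(genome)) {
      pos <- 0L
      while (pos < glen[[chr]]) {
        blk <- sample(1000:5000, 1L)
        e <- min(glen[[chr]], pos + blk)
        cat_ <- sample(c("CDS", "intron", "upstream", "downstream",
                         "intergenic"), 1L)
        if (cat_ != "intergenic") {
          ann[[cat_]][[length(ann[[cat_]]) + 1L]] <-
            data.frame(chrom = chr, start = pos, end = e)
        }
        pos <- e
      }
    }
    annotation <- lapply(ann, function(lst) {
      if (length(lst) == 0L)
        genomic_intervals(character(0), integer(0), integer(0))
      else {
        d <- do.call(rbind, lst)
        genomic_intervals(d$chrom, d$start, d$end)
      }
    })

    paths <- list(
      genome = file.path(dir, "genome.fa"),
      pwm = file.path(dir, "pwm.tsv"),
      regions = file.path(dir, "regions.bed"),
      ref_rep1 = file.path(dir, "ref_rep1.bedgraph"),
      ref_rep2 = file.path(dir, "ref_rep2.bedgraph"),
      alt_rep1 = file.path(dir, "alt_rep1.bedgraph"),
      alt_rep2 = file.path(dir, "alt_rep2.bedgraph"),
      control = file.path(dir, "control.bedgraph"),
      open_bed = file.path(dir, "dhs_open.bed"),
      dhs_bedgraph = file.path(dir, "dhs_signal.bedgraph"),
      manifest = file.path(dir, "truth_manifest.json")
    )
    write_fasta(genome, paths$genome)
    write_pwm(x, paths$pwm)
    write_bed(regions, paths$regions)
    for (tn in c("ref_rep1", "ref_rep2", "alt_rep1", "alt_rep2",
                 "control")) {
      write_bedgraph(tracks[[tn]], paths[[tn]])
    }
    write_bed(dhs$open_set, paths$open_bed)
    write_bedgraph(dhs$dhs_track, paths$dhs_bedgraph)
    for (cat_ in names(annotation)) {
      p <- file.path(dir, paste0("annotation_", cat_, ".bed"))
      write_bed(annotation[[cat_]], p)
      paths[[paste0("annotation_", cat_)]] <- p
    }

    manifest <- list(
      seed = config$seed,
      m_true = config$m_true,
      mprime_true = config$mprime_true,
      site_score_floor = config$site_score_floor,
      fragment_length = config$fragment_length,
      regions = lapply(seq_len(nrow(truth)), function(i) {
        list(id = truth$id[i],
             fold_reduction = if (is.finite(truth$fold_reduction[i]))
               truth$fold_reduction[i] else NULL,
             zero_occupancy = !is.finite(truth$fold_reduction[i]),
             site_offsets = site_map[[truth$id[i]]],
             site_scores = score_map[[truth$id[i]]],
             unit_gap_pairs = truth$unit_gap_pairs[i],
             best_score = truth$best_score[i],
             open = truth$open[i])
      })
    )
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, null = "null")

    invisible(list(dir = dir, paths = paths, config = config,
                   truth = truth, site_map = site_map,
                   score_map = score_map, genome = genome, pwm = x,
                   tracks = tracks, regions = regions,
                   background = background, open_set = dhs$open_set,
                   dhs_track = dhs$dhs_track, annotation = annotation))
  })
}
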