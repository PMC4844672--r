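#' Classify a position by annotation category
#'
#' Categories are looked up in the fixed priority order CDS, intron,
#' upstream, downstream; a position matched by none is intergenic (the
#' complement fallback).
#'
#' @param catalog Named list of interval `data.frame`s, names among
#'   `CDS`, `intron`, `upstream`, `downstream`.
#' @param chrom,pos Chromosome and 0-based position to classify.
#' @return Category label.
#' @export
annotation_category <- function(catalog, chrom, pos) {
  for (cat in c("CDS", "intron", "upstream", "downstream")) {
    iv <- catalog[[cat]]
    if (is.null(iv) || nrow(iv) == 0L) next
    sel <- iv$chrom == chrom & iv$start <= pos & iv$end > pos
    if (any(sel)) return(cat)
  }
  "intergenic"
}

#' Sample a GC-matched negative region set
#'
#' For each bound region, draws random same-length intervals from the
#' genome until one matches the bound region's GC content within
#' `gc_tol` and overlaps no bound region; its annotation category is
#' recorded but not constrained. Deterministic for a given seed.
#'
#' @param bound_regions Interval `data.frame` (the positive set).
#' @param genome Named character vector of chromosome sequences.
#' @param annotation Optional annotation catalog (see
#'   [annotation_category()]).
#' @param gc_tol Maximum absolute GC difference (default 0.05).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param max_tries Attempts per region before giving up.
#' @return Interval `data.frame` with one negative region per bound
#'   region (id `neg_<i>`), plus columns `gc` and `category`.
#' @export
sample_negative_set <- function(bound_regions, genome, annotation = NULL,
                                gc_tol = 0.05, seed = NULL,
                                max_tries = 2000L) {
  bound_regions <- as_intervals(bound_regions)
  n <- nrow(bound_regions)
  glen <- nchar(genome)
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      len <- bound_regions$end[i] - bound_regions$start[i]
      target_gc <- gc_content(interval_sequence(genome, bound_regions[i, ]))
      found <- FALSE
      for (try in seq_len(max_tries)) {
        chr <- sample(names(genome), 1L, prob = glen)
        if (glen[[chr]] < len) next
        start <- sample.int(glen[[chr]] - len + 1L, 1L) - 1L
        cand <- genomic_intervals(chr, start, start + len,
                                  id = paste0("neg_", i))
        same_chr <- bound_regions$chrom == chr
        if (any(same_chr & bound_regions$start < cand$end &
                  bound_regions$end > cand$start)) next
        seq_ <- interval_sequence(genome, cand)
        gc <- tryCatch(gc_content(seq_), error = function(e) NA_real_)
        if (is.na(gc) || abs(gc - target_gc) > gc_tol) next
        cand$gc <- gc
        cand$category <- if (is.null(annotation)) NA_character_ else
          annotation_category(annotation, chr,
                              start + len %/% 2L)
        out[[i]] <- cand
        found <- TRUE
        break
      }
      if (!found) {
        stop("no GC-matched candidate found for region ", i, " (",
             bound_regions$chrom[i], ":", bound_regions$start[i], "-",
             bound_regions$end[i], ") within ", max_tries, " tries")
      }
    }
    do.call(rbind, out)
  })
}

# Number of unit score windows of a PWM: [0;-1] down to [min+1;min].
n_score_windows <- function(x) as.integer(ceiling(-pwm_min_score(x)))

# Map scores to window indices: window k holds scores in (-k, -(k-1)].
score_window_index <- function(score) pmax(1L, as.integer(ceiling(-score)))

#' Per-region binding-site densities in unit score windows
#'
#' Scans each region and counts its sites per unit score window, from
#' `[0; -1]` down to the window ending at the PWM's worst score. The
#' window of a site of score s is the unit interval `(u - 1, u]`
#' containing s; counts are converted to densities in sites per kb.
#'
#' @param regions Interval `data.frame`.
#' @param genome Named character vector of sequences.
#' @param x A `pwm`.
#' @return List with `counts` and `densities` (region x window matrices)
#'   and `windows` (`data.frame` of window `upper`/`lower` bounds).
#' @export
window_densities <- function(regions, genome, x) {
  regions <- as_intervals(regions)
  nw <- n_score_windows(x)
  counts <- matrix(0L, nrow = nrow(regions), ncol = nw)
  len_kb <- (regions$end - regions$start) / 1000
  for (i in seq_len(nrow(regions))) {
    sites <- scan_sequence(x, interval_sequence(genome, regions[i, ]))
    if (nrow(sites) > 0L) {
      tab <- tabulate(score_window_index(sites$score), nbins = nw)
      counts[i, ] <- tab
    }
  }
  list(counts = counts, densities = counts / len_kb,
       windows = data.frame(upper = -(seq_len(nw) - 1L),
                            lower = -seq_len(nw)))
}

#' Data-driven binding-site score threshold
#'
#' Compares per-region site densities between bound regions and the
#' GC-matched negative set, one unit score window at a time, with a
#' one-sided Mann-Whitney test (bound > negative). The threshold is the
#' lower bound of the most negative window in the maximal contiguous run
#' of significant windows starting at `[0; -1]`; if even the first
#' window is not significant the result is `NA` ("none").
#'
#' @param pos_densities,neg_densities Region x window density matrices on
#'   identical window grids (from [window_densities()]).
#' @param alpha Per-window significance level (default 0.05, uncorrected;
#'   set `adjust = "BH"` for a Benjamini-Hochberg variant).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list of class `threshold_result`: `threshold` (integer score
#'   or `NA`) and `table` (per-window medians, p-values, significance).
#' @export
determine_threshold <- function(pos_densities, neg_densities, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (ncol(pos_densities) != ncol(neg_densities)) {
    stop("positive and negative density matrices have different window grids")
  }
  if (nrow(pos_densities) < 2L || nrow(neg_densities) < 2L) {
    stop("need at least 2 regions per set")
  }
  nw <- ncol(pos_densities)
  pvals <- numeric(nw)
  med_pos <- numeric(nw)
  med_neg <- numeric(nw)
  mean_pos <- numeric(nw)
  mean_neg <- numeric(nw)
  for (j in seq_len(nw)) {
    x <- pos_densities[, j]
    y <- neg_densities[, j]
    pvals[j] <- mann_whitney_u(x, y, alternative = "greater")$p_value
    med_pos[j] <- stats::median(x)
    med_neg[j] <- stats::median(y)
    mean_pos[j] <- mean(x)
    mean_neg[j] <- mean(y)
  }
  p_use <- if (adjust == "BH") stats::p.adjust(pvals, "BH") else pvals
  # direction guard on means: sparse windows have median 0 in both sets
  # even under strong enrichment, so medians cannot carry the direction
  significant <- p_use < alpha & mean_pos > mean_neg
  run <- 0L
  for (j in seq_len(nw)) {
    if (significant[j]) run <- j else break
  }
  structure(list(
    threshold = if (run == 0L) NA_integer_ else -run,
    table = data.frame(upper = -(seq_len(nw) - 1L), lower = -seq_len(nw),
                       median_pos = med_pos, median_neg = med_neg,
                       mean_pos = mean_pos, mean_neg = mean_neg,
                       p_value = pvals, p_adjusted = p_use,
                       significant = significant)
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "none" else x$threshold
  nsig <- sum(x$table$significant)
  cat(sprintf("threshold_result: threshold = %s (%d/%d windows significant)\n",
              thr, nsig, nrow(x$table)))
  invisible(x)
}

#' Best binding-site score of a region
#'
#' @param region Single-row interval `data.frame`, length >=
#'   `pwm_length(x)`.
#' @param genome Named character vector of sequences.
#' @param x A `pwm`.
#' @return Maximum site score over both strands.
#' @export
region_best_score <- function(region, genome, x) {
  region <- as_intervals(region)
  if (region$end - region$start < pwm_length(x)) {
    stop("region shorter than PWM length")
  }
  sites <- scan_sequence(x, interval_sequence(genome, region))
  if (nrow(sites) == 0L) return(-Inf)
  max(sites$score)
}

#' Binding-site density of a region
#'
#' @inheritParams region_best_score
#' @param threshold Minimum site score.
#' @return Sites per kb at or above the threshold.
#' @export
region_site_density <- function(region, genome, x, threshold) {
  region <- as_intervals(region)
  if (region$end - region$start < pwm_length(x)) {
    stop("region shorter than PWM length")
  }
  sites <- scan_sequence(x, interval_sequence(genome, region),
                         threshold = threshold)
  nrow(sites) * 1000 / (region$end - region$start)
}

#' All pairwise gap distances between sites of one region
#'
#' The distance between two sites is the gap between their L-bp
#' footprints: `start_downstream - (start_upstream + L)`. A 1-bp
#' distance therefore means a single spacer base between adjacent
#' footprints. Overlapping sites produce negative gaps, reported as-is.
#'
#' @param offsets Sorted 0-based site start offsets within the region.
#' @param L Site (PWM) length in bp.
#' @return Numeric vector of gaps, one per unordered site pair.
#' @export
pairwise_site_distances <- function(offsets, L) {
  n <- length(offsets)
  if (n < 2L) return(numeric(0))
  offsets <- sort(offsets)
  d <- outer(offsets, offsets, "-")
  d[lower.tri(d)] - L
}

#' Number of site pairs separated by exactly 1 bp
#'
#' @inheritParams pairwise_site_distances
#' @return Integer pair count.
#' @export
count_unit_gap_pairs <- function(offsets, L) {
  sum(pairwise_site_distances(offsets, L) == 1)
}

#' Site-spacing histogram stratified by CFR decile
#'
#' Regions are split into deciles by CFR; within each decile all pairwise
#' site gaps are pooled and histogrammed over `[0, max_distance)` (1-bp
#' bins; negative gaps from overlapping sites are excluded).
#'
#' @param cfr_records CFR table (from [compute_cfr()]), one row per
#'   region with an `id` column.
#' @param site_map Named list (by region id) of 0-based site offset
#'   vectors within each region.
#' @param L Site (PWM) length.
#' @param max_distance Upper bound (exclusive) of the histogram.
#' @return 10 x `max_distance` integer matrix; rows are deciles
#'   (1 = lowest CFR), columns are distances `0 .. max_distance - 1`.
#' @export
spacing_by_decile <- function(cfr_records, site_map, L, max_distance = 40L) {
  dec <- decile_partition(cfr_records, "cfr")
  mat <- matrix(0L, nrow = 10L, ncol = max_distance,
                dimnames = list(decile = 1:10,
                                distance = 0:(max_distance - 1L)))
  for (i in seq_len(nrow(cfr_records))) {
    offs <- site_map[[cfr_records$id[i]]]
    if (is.null(offs) || length(offs) < 2L) next
    gaps <- pairwise_site_distances(offs, L)
    gaps <- gaps[gaps >= 0 & gaps < max_distance]
    if (length(gaps) > 0L) {
      mat[dec[i], ] <- mat[dec[i], ] +
        tabulate(gaps + 1L, nbins = max_distance)
    }
  }
  mat
}
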