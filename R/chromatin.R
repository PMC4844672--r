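#' Load and merge an open-chromatin interval set
#'
#' DNase I hypersensitive intervals are merged into their union on
#' loading (adjacent intervals fused), so openness queries see one
#' non-overlapping interval per accessible block.
#'
#' @param path BED file of open intervals.
#' @return Merged interval `data.frame`.
#' @export
read_open_set <- function(path) {
  merge_intervals(read_bed(path))
}

# Centred half of a region: the middle 50%, floor division on both flanks.
centred_half <- function(region) {
  len <- region$end - region$start
  quarter <- len %/% 4L
  c(start = region$start + quarter, end = region$end - quarter)
}

#' Is a bound region open?
#'
#' A bound region counts as open when its centred half — the middle 50%,
#' `[start + floor(len/4), end - floor(len/4))` — is entirely covered by
#' the union of open intervals. A single uncovered base makes the region
#' closed.
#'
#' @param region Single-row interval `data.frame`, length >= 2.
#' @param open_set Interval `data.frame` of open intervals (merged or
#'   not; the union is what matters).
#' @return Logical.
#' @export
is_open_region <- function(region, open_set) {
  region <- as_intervals(region)
  stopifnot(nrow(region) == 1L, region$end - region$start >= 2L)
  half <- centred_half(region)
  merged <- merge_intervals(open_set)
  sel <- merged$chrom == region$chrom & merged$start <= half[["start"]] &
    merged$end >= half[["end"]]
  any(sel)
}

#' Quantitative DHS signal over a region
#'
#' Same area-above-the-curve definition as ChIP coverage: the sum of
#' per-base DHS track values over the region.
#'
#' @param region Interval `data.frame` (one or more rows).
#' @param dhs_track A `coverage_track` of DHS signal.
#' @return Numeric vector of signals.
#' @export
region_dhs_signal <- function(region, dhs_track) {
  region_coverage(dhs_track, region)
}

#' Build the per-region accessibility table
#'
#' @param cfr_records CFR table (from [compute_cfr()]).
#' @param open_set Open-chromatin interval set.
#' @param dhs_track Optional quantitative DHS `coverage_track`.
#' @return `cfr_records` with added columns `open` (centred-half rule)
#'   and `dhs_signal` (NA when no track is given).
#' @export
accessibility_table <- function(cfr_records, open_set, dhs_track = NULL) {
  open <- vapply(seq_len(nrow(cfr_records)), function(i) {
    is_open_region(cfr_records[i, ], open_set)
  }, logical(1))
  dhs <- if (is.null(dhs_track)) rep(NA_real_, nrow(cfr_records)) else
    region_dhs_signal(cfr_records, dhs_track)
  cfr_records$open <- open
  cfr_records$dhs_signal <- dhs
  cfr_records
}

#' Fraction of closed regions per CFR decile
#'
#' @param records Accessibility table with `cfr` and `open` columns,
#'   >= 10 rows.
#' @return Numeric vector of 10 closed fractions (decile 1 = lowest CFR).
#' @export
fraction_closed_by_decile <- function(records) {
  dec <- decile_partition(records, "cfr")
  vapply(1:10, function(d) mean(!records$open[dec == d]), numeric(1))
}

#' Relate CFR to quantitative chromatin accessibility
#'
#' Pearson correlation between CFR and DHS signal (optionally on log10
#' scale), plus the Mann-Whitney comparison of CFR between the regions
#' of lowest and highest DHS signal (first vs last DHS decile).
#'
#' @param records Accessibility table with finite `cfr` and `dhs_signal`.
#' @param log10_scale Correlate `log10` of both variables instead
#'   (pseudocount 1 on the DHS signal).
#' @return List with `pearson` (a `test_report`) and `extreme_deciles`
#'   (a `test_report` of CFR across the DHS extremes).
#' @export
cfr_vs_dhs <- function(records, log10_scale = FALSE) {
  stopifnot(nrow(records) >= 10L)
  cfr <- records$cfr
  dhs <- records$dhs_signal
  if (log10_scale) {
    cfr <- log10(cfr)
    dhs <- log10(dhs + 1)
  }
  list(
    pearson = pearson_r(cfr, dhs),
    extreme_deciles = extreme_decile_compare(
      data.frame(dhs = records$dhs_signal, cfr = records$cfr,
                 id = records$id, rank = records$rank),
      key = "dhs", value = "cfr")
  )
}
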