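#' Build an extended-read coverage track
#'
#' Each aligned read is extended to the expected fragment length from its
#' 5' end in read orientation and contributes +1 to every base it covers;
#' extensions are truncated at chromosome edges. A plus-strand read at
#' position p covers `[p, p + fragment_length)`; a minus-strand read with
#' 5' end at p covers `(p - fragment_length, p]`.
#'
#' @param reads `data.frame` with columns `chrom`, `pos` (0-based 5' end)
#'   and `strand` (`"+"` or `"-"`).
#' @param fragment_length Extension length in bp (default 130).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A `coverage_track` of integer-valued read counts.
#' @export
extend_reads <- function(reads, fragment_length = 130L, chrom_lengths) {
  stopifnot(fragment_length >= 1L, is.data.frame(reads),
            all(c("chrom", "pos", "strand") %in% names(reads)))
  if (nrow(reads) > 0L) {
    unknown <- which(!reads$chrom %in% names(chrom_lengths))
    if (length(unknown) > 0L) {
      stop("read on undeclared chromosome ", reads$chrom[unknown[1L]])
    }
    out_of_range <- which(reads$pos < 0L |
                            reads$pos >= chrom_lengths[reads$chrom])
    if (length(out_of_range) > 0L) {
      stop("read position outside chromosome at row ", out_of_range[1L])
    }
    if (!all(reads$strand %in% c("+", "-"))) stop("strand must be + or -")
  }
  vals <- lapply(chrom_lengths, function(n) numeric(n))
  names(vals) <- names(chrom_lengths)
  for (chr in unique(reads$chrom)) {
    n <- chrom_lengths[[chr]]
    idx <- which(reads$chrom == chr)
    pos <- reads$pos[idx]
    plus <- reads$strand[idx] == "+"
    # half-open [from, to) in 0-based coordinates, truncated at edges
    from <- ifelse(plus, pos, pmax(0L, pos - fragment_length + 1L))
    to <- ifelse(plus, pmin(n, pos + fragment_length), pos + 1L)
    # difference-array accumulation, then cumulative sum
    d <- numeric(n + 1L)
    tf <- tabulate(from + 1L, nbins = n + 1L)
    tt <- tabulate(to + 1L, nbins = n + 1L)
    d <- tf - tt
    vals[[chr]] <- cumsum(d)[seq_len(n)]
  }
  coverage_track(vals)
}

#' Find background peaks by signal thresholding
#'
#' A deliberately rudimentary peak caller used on the control genotype:
#' maximal runs of positions whose signal is at least `cutoff` become
#' peaks. Runs separated by fewer than `min_gap` sub-cutoff bases are
#' merged; the default `min_gap = 0` performs no merging.
#'
#' @param track A `coverage_track`.
#' @param cutoff Signal cutoff (default 20).
#' @param min_gap Merge runs separated by fewer than this many bases.
#' @return Interval `data.frame` of peaks, ordered by chromosome then
#'   position.
#' @export
rudimentary_peak_find <- function(track, cutoff = 20, min_gap = 0L) {
  stopifnot(cutoff > 0)
  out <- list()
  for (chr in names(track)) {
    v <- track_chrom(track, chr)
    r <- rle(v >= cutoff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) next
    s <- starts[keep]
    e <- ends[keep]
    if (min_gap > 0L && length(s) > 1L) {
      merged_s <- s[1L]
      merged_e <- e[1L]
      for (i in 2L:length(s)) {
        if (s[i] - merged_e[length(merged_e)] < min_gap) {
          merged_e[length(merged_e)] <- e[i]
        } else {
          merged_s <- c(merged_s, s[i])
          merged_e <- c(merged_e, e[i])
        }
      }
      s <- merged_s
      e <- merged_e
    }
    out[[chr]] <- data.frame(chrom = chr, start = s, end = e,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(genomic_intervals(character(0), integer(0), integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  genomic_intervals(res$chrom, res$start, res$end)
}

#' Fit the intra-genotype replicate scale factor
#'
#' Regresses replicate-2 peak coverages on replicate-1 peak coverages.
#' The default is least squares through the origin (no signal in one
#' replicate implies no signal in the other), giving
#' `m = sum(x * y) / sum(x^2)`; a free-intercept ordinary least squares
#' alternative is available.
#'
#' @param cov_rep1,cov_rep2 Numeric vectors of peak coverages, same
#'   length, typically over the most significant peaks.
#' @param intercept If `TRUE`, fit a free intercept and return the slope.
#' @return A list of class `scale_fit` with elements `m`, `n`,
#'   `residual_sd`.
#' @export
fit_replicate_scale <- function(cov_rep1, cov_rep2, intercept = FALSE) {
  stopifnot(length(cov_rep1) == length(cov_rep2), length(cov_rep1) >= 2L,
            all(cov_rep1 >= 0), all(cov_rep2 >= 0))
  if (intercept) {
    fit <- stats::lm(cov_rep2 ~ cov_rep1)
    m <- unname(stats::coef(fit)[2L])
    res <- stats::residuals(fit)
  } else {
    sxx <- sum(cov_rep1^2)
    if (sxx == 0) stop("all replicate-1 coverages are zero; cannot fit m")
    m <- sum(cov_rep1 * cov_rep2) / sxx
    res <- cov_rep2 - m * cov_rep1
  }
  if (m <= 0) stop("fitted scale factor is not positive: ", m)
  structure(list(m = m, n = length(cov_rep1),
                 residual_sd = stats::sd(res)),
            class = "scale_fit")
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf("scale_fit: m = %.6g (n = %d, residual sd = %.4g)\n",
              x$m, x$n, x$residual_sd))
  invisible(x)
}

#' Fuse two replicate tracks into one normalized track
#'
#' Replicate 2 is first rescaled onto replicate 1 by the fitted factor
#' `m`, then the two are averaged position-wise:
#' `fused(x) = (rep1(x) + rep2(x) / m) / 2`.
#' The symmetric alternative `(rep1(x)/sqrt(m') + rep2(x)*sqrt(m')) / 2`
#' style anchoring is not used; replicate 1 is the reference, which makes
#' fusing a genotype with itself the identity.
#'
#' @param track1,track2 `coverage_track`s on the same chromosome
#'   namespace.
#' @param m Replicate scale factor (`> 0`), as fitted by
#'   [fit_replicate_scale()].
#' @return A fused `coverage_track`.
#' @export
fuse_replicates <- function(track1, track2, m) {
  stopifnot(m > 0)
  l1 <- chrom_lengths(track1)
  l2 <- chrom_lengths(track2)
  if (!identical(l1[sort(names(l1))], l2[sort(names(l2))])) {
    stop("replicate tracks have mismatched chromosome namespaces")
  }
  vals <- lapply(names(track1), function(chr) {
    (track_chrom(track1, chr) + track_chrom(track2, chr) / m) / 2
  })
  names(vals) <- names(track1)
  coverage_track(vals)
}

#' Fit the inter-genotype depth scale factor
#'
#' Background peaks called in the non-transgenic control carry no
#' specific signal, so coverage differences over them between a fused
#' genotype track and the control track reflect sequencing depth only.
#' The factor `m'` is the through-origin regression slope of genotype
#' peak coverage on control peak coverage.
#'
#' @param fused_track Fused genotype `coverage_track`.
#' @param control_track Control `coverage_track`.
#' @param background_peaks Interval `data.frame` of control background
#'   peaks.
#' @param intercept Fit a free intercept instead (slope still returned).
#' @return A `scale_fit` list with element `m` holding `m'`.
#' @export
fit_genotype_scale <- function(fused_track, control_track, background_peaks,
                               intercept = FALSE) {
  background_peaks <- as_intervals(background_peaks)
  if (nrow(background_peaks) == 0L) stop("no background peaks supplied")
  x <- region_coverage(control_track, background_peaks)
  y <- region_coverage(fused_track, background_peaks)
  if (all(x == 0)) stop("all control background-peak coverages are zero")
  fit_replicate_scale(x, y, intercept = intercept)
}

#' Rescale a fused track by the inter-genotype factor
#'
#' `normalized(x) = fused(x) / m'`, putting both genotypes on the control
#' sample's depth scale so their coverages are directly comparable.
#'
#' @param fused_track Fused `coverage_track`.
#' @param m_prime Inter-genotype scale factor (`> 0`).
#' @return Normalized `coverage_track`.
#' @export
apply_genotype_scale <- function(fused_track, m_prime) {
  stopifnot(m_prime > 0)
  vals <- lapply(unclass(fused_track), function(v) v / m_prime)
  coverage_track(vals)
}

#' Compute per-region coverage fold reductions
#'
#' The coverage fold reduction (CFR) of a bound region is the ratio of
#' its normalized coverage in the reference genotype (intact
#' oligomerization) to that in the mutant genotype. Regions whose mutant
#' coverage falls below `min_alt_coverage` would yield unstable or
#' infinite ratios, so their CFR is set to `cap` and flagged. The default
#' `min_alt_coverage` is the coverage contributed by a single extended
#' read (the fragment length), i.e. essentially no mutant signal.
#'
#' @param regions Interval `data.frame` of bound regions.
#' @param ref_track,alt_track Normalized `coverage_track`s for the
#'   reference and mutant genotypes (both on the control depth scale).
#' @param cap CFR value assigned to capped regions (default 300).
#' @param min_alt_coverage Mutant-coverage floor below which the CFR is
#'   capped (default 130, one extended read).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `id`,
#'   `rank`, `cov_ref`, `cov_alt`, `cfr`, `capped`, in input order.
#' @export
compute_cfr <- function(regions, ref_track, alt_track, cap = 300,
                        min_alt_coverage = 130) {
  regions <- as_intervals(regions)
  cov_ref <- region_coverage(ref_track, regions)
  cov_alt <- region_coverage(alt_track, regions)
  capped <- cov_alt < min_alt_coverage
  cfr <- ifelse(capped, cap, cov_ref / cov_alt)
  if (any(!capped & cfr <= 0)) {
    warning("non-positive CFR for region(s) with zero reference coverage")
  }
  cbind(regions[, c("chrom", "start", "end", "id", "rank")],
        data.frame(cov_ref = cov_ref, cov_alt = cov_alt, cfr = cfr,
                   capped = capped))
}
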