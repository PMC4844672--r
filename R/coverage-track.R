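#' Construct a per-base coverage track
#'
#' A coverage track stores one non-negative real value per base for each
#' chromosome. Values are real, not integer, because normalization rescales
#' raw read counts.
#'
#' @param values Named list of numeric vectors, one per chromosome; the
#'   vector length is the chromosome length.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values) {
  stopifnot(is.list(values), length(values) > 0L,
            !is.null(names(values)), all(nzchar(names(values))))
  for (chr in names(values)) {
    v <- values[[chr]]
    if (!is.numeric(v) || length(v) == 0L) {
      stop("track for ", chr, " must be a non-empty numeric vector")
    }
    if (anyNA(v) || any(v < 0)) {
      stop("track for ", chr, " has NA or negative values")
    }
    values[[chr]] <- as.numeric(v)
  }
  structure(values, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  lens <- vapply(x, length, integer(1))
  cat("coverage_track:", length(x), "chromosome(s)\n")
  for (chr in names(x)) {
    cat(sprintf("  %s  length %d  total %.4g\n", chr, lens[[chr]],
                sum(x[[chr]])))
  }
  invisible(x)
}

#' Chromosome lengths of a coverage track
#' @param track A `coverage_track`.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(track) {
  vapply(unclass(track), length, integer(1))
}

track_chrom <- function(track, chrom) {
  if (!chrom %in% names(track)) {
    stop("chromosome ", chrom, " not present in track")
  }
  unclass(track)[[chrom]]
}

#' Read a bedGraph file into a dense coverage track
#'
#' Records are 0-based half-open; positions not covered by any record are
#' zero. Overlapping records are rejected: the normalized tracks this
#' package consumes and produces are non-overlapping by construction, so
#' an overlap indicates a malformed input rather than a value to be summed.
#'
#' @param path Path to a 4-column bedGraph without header.
#' @param chrom_lengths Named integer vector declaring the chromosome
#'   namespace; records on undeclared chromosomes or beyond a declared
#'   length are errors.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  vals <- lapply(chrom_lengths, function(n) numeric(n))
  names(vals) <- names(chrom_lengths)
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  if (file.size(path) > 0L) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1L),
                            data.table = FALSE)
    if (ncol(dt) < 4L) stop("bedGraph needs 4 columns: ", path)
    chrom <- dt[[1L]]
    start <- suppressWarnings(as.integer(dt[[2L]]))
    end <- suppressWarnings(as.integer(dt[[3L]]))
    val <- suppressWarnings(as.numeric(dt[[4L]]))
    bad <- which(is.na(start) | is.na(end) | is.na(val) | start < 0L |
                   start >= end)
    if (length(bad) > 0L) {
      stop("malformed bedGraph record at line ", bad[1L], " of ", path)
    }
    unknown <- which(!chrom %in% names(vals))
    if (length(unknown) > 0L) {
      stop("bedGraph record on undeclared chromosome ", chrom[unknown[1L]],
           " at line ", unknown[1L])
    }
    over <- which(end > chrom_lengths[chrom])
    if (length(over) > 0L) {
      stop("bedGraph record exceeds chromosome length at line ", over[1L])
    }
    for (chr in unique(chrom)) {
      idx <- which(chrom == chr)
      o <- idx[order(start[idx])]
      if (length(o) > 1L && any(start[o][-1L] < end[o][-length(o)])) {
        stop("overlapping bedGraph records on ", chr, " in ", path)
      }
      lens_rec <- end[o] - start[o]
      pos <- sequence(lens_rec) + rep(start[o], lens_rec)
      vals[[chr]][pos] <- rep(val[o], lens_rec)
    }
  }
  coverage_track(vals)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are emitted as single maximal records; zero runs
#' are omitted. Values are printed with 17 significant digits so the
#' read/write round trip is value-identical.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  all_lines <- character(0)
  for (chr in names(track)) {
    v <- track_chrom(track, chr)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    v <- r$values[keep]
    # integer-valued runs (raw counts) take a fast formatting path;
    # 17 significant digits keep real values round-trip exact
    val_str <- if (all(v == floor(v)) && max(v) < 2^31) {
      as.character(as.integer(v))
    } else {
      formatC(v, digits = 17, format = "g")
    }
    all_lines <- c(all_lines,
                   paste0(chr, "\t", starts[keep], "\t", ends[keep], "\t",
                          val_str))
  }
  writeLines(all_lines, path)
  invisible(path)
}

#' Area under a coverage track over a region
#'
#' The coverage of a region is defined as the area of the read-count
#' curve: the sum of per-base track values over `[start, end)`.
#'
#' @param track A `coverage_track`.
#' @param interval A single-row interval `data.frame` (or a multi-row one,
#'   yielding one value per row).
#' @return Numeric vector of region coverages.
#' @export
region_coverage <- function(track, interval) {
  interval <- as_intervals(interval)
  lens <- chrom_lengths(track)
  vapply(seq_len(nrow(interval)), function(i) {
    chr <- interval$chrom[i]
    v <- track_chrom(track, chr)
    if (interval$end[i] > lens[[chr]]) {
      stop("interval [", interval$start[i], ", ", interval$end[i],
           ") exceeds length of ", chr)
    }
    sum(v[(interval$start[i] + 1L):interval$end[i]])
  }, numeric(1))
}
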