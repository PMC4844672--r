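#' Construct a set of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Conversion to 1-based coordinates happens only
#' at the boundary with Bioconductor containers, never in user-facing
#' tables.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions; `end > start`.
#' @param id Optional character vector of region labels.
#' @param rank Optional integer vector of peak ranks (1 = most significant).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `id`,
#'   `rank`, one row per interval.
#' @export
genomic_intervals <- function(chrom, start, end, id = NA_character_,
                              rank = NA_integer_) {
  n <- max(length(chrom), length(start))
  chrom <- rep_len(as.character(chrom), n)
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == n, length(end) == n)
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0L) {
    stop("invalid interval at index ", bad[1L],
         ": need 0 <= start < end, got [", start[bad[1L]], ", ",
         end[bad[1L]], ")")
  }
  data.frame(chrom = chrom, start = start, end = end,
             id = rep_len(as.character(id), n),
             rank = rep_len(as.integer(rank), n),
             stringsAsFactors = FALSE)
}

#' Read genomic intervals from a BED file
#'
#' Accepts 3- to 5-column BED (chrom, start, end, name, score); column 4
#' is mapped to `id` and column 5 to `rank`. Coordinates are kept 0-based
#' half-open exactly as in the file.
#'
#' @param path Path to a tab-separated BED file without header.
#' @return Interval `data.frame` as from [genomic_intervals()], in file
#'   order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) {
    return(genomic_intervals(character(0), integer(0), integer(0)))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1L),
                          fill = TRUE, data.table = FALSE)
  if (ncol(dt) < 3L) stop("BED file needs >= 3 tab-separated columns: ", path)
  start <- suppressWarnings(as.integer(dt[[2L]]))
  end <- suppressWarnings(as.integer(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0L) {
    stop("malformed BED record at line ", bad[1L], " of ", path)
  }
  id <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NA_character_
  rank <- if (ncol(dt) >= 5L) suppressWarnings(as.integer(dt[[5L]])) else
    NA_integer_
  genomic_intervals(dt[[1L]], start, end, id, rank)
}

#' Write genomic intervals to a BED file
#'
#' Emits as many columns as are informative: 3 when no interval has an id,
#' 4 when ids but no ranks are present, 5 otherwise. Round-trips through
#' [read_bed()] bit-exactly.
#'
#' @param intervals Interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_intervals(intervals)
  n <- nrow(intervals)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  have_rank <- !all(is.na(intervals$rank))
  have_id <- have_rank || !all(is.na(intervals$id))
  lines <- sprintf("%s\t%d\t%d", intervals$chrom, intervals$start,
                   intervals$end)
  if (have_id) {
    id <- ifelse(is.na(intervals$id), ".", intervals$id)
    lines <- paste(lines, id, sep = "\t")
  }
  if (have_rank) {
    rk <- ifelse(is.na(intervals$rank), ".", as.character(intervals$rank))
    lines <- paste(lines, rk, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# Coerce/validate an interval table; tolerant of extra columns.
as_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("interval table needs columns chrom, start, end")
  }
  if (is.null(x$id)) x$id <- NA_character_
  if (is.null(x$rank)) x$rank <- NA_integer_
  if (nrow(x) > 0L && any(x$start < 0L | x$start >= x$end)) {
    stop("interval table violates 0 <= start < end")
  }
  x
}

#' Keep intervals of one set that overlap another
#'
#' Returns the members of `a` that share at least one base with some
#' member of `b`, preserving the order of `a`. Overlap is computed on the
#' half-open convention, so touching intervals (`end == start`) do not
#' overlap.
#'
#' @param a,b Interval `data.frame`s on the same chromosome namespace.
#' @return The overlapping subset of `a`.
#' @export
intersect_regions <- function(a, b) {
  a <- as_intervals(a)
  b <- as_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a[integer(0), , drop = FALSE])
  hit <- logical(nrow(a))
  for (chr in unique(a$chrom)) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    if (length(ib) == 0L) next
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    hit[ia] <- IRanges::overlapsAny(ra, rb)
  }
  a[hit, , drop = FALSE]
}

# Merge intervals into their union (adjacent runs fused), per chromosome.
# Returns an interval data.frame sorted by chrom then start.
merge_intervals <- function(x) {
  x <- as_intervals(x)
  if (nrow(x) == 0L) return(x[, c("chrom", "start", "end", "id", "rank")])
  out <- lapply(split(seq_len(nrow(x)), x$chrom), function(idx) {
    r <- IRanges::reduce(IRanges::IRanges(x$start[idx] + 1L, x$end[idx]))
    data.frame(chrom = x$chrom[idx][1L], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  genomic_intervals(out$chrom, out$start, out$end)
}
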