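# Independent brute-force oracles. Each is deliberately the dumbest
# correct implementation, so the optimized package code is checked
# against a different computational path.

bf_region_coverage <- function(values, start, end) {
  total <- 0
  for (p in seq(start, end - 1L)) total <- total + values[p + 1L]
  total
}

bf_intersect <- function(a, b) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
            a$start[i] < b$end[j] && a$end[i] > b$start[j]) {
        keep[i] <- TRUE
      }
    }
  }
  a[keep, , drop = FALSE]
}

bf_peaks <- function(values, cutoff) {
  above <- values >= cutoff
  starts <- integer(0)
  ends <- integer(0)
  in_peak <- FALSE
  for (p in seq_along(values)) {
    if (above[p] && !in_peak) {
      starts <- c(starts, p - 1L)
      in_peak <- TRUE
    }
    if (!above[p] && in_peak) {
      ends <- c(ends, p - 1L)
      in_peak <- FALSE
    }
  }
  if (in_peak) ends <- c(ends, length(values))
  data.frame(start = starts, end = ends)
}

bf_extend_reads <- function(reads, fl, n) {
  v <- numeric(n)
  for (i in seq_len(nrow(reads))) {
    if (reads$strand[i] == "+") {
      span <- reads$pos[i]:(reads$pos[i] + fl - 1L)
    } else {
      span <- (reads$pos[i] - fl + 1L):reads$pos[i]
    }
    span <- span[span >= 0L & span < n]
    for (p in span) v[p + 1L] <- v[p + 1L] + 1
  }
  v
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1L]]),
        collapse = "")
}

bf_score <- function(w, seq) {
  ch <- strsplit(seq, "")[[1L]]
  total <- 0
  for (i in seq_along(ch)) {
    j <- match(ch[i], c("A", "C", "G", "T"))
    if (is.na(j)) return(-Inf)
    total <- total + unname(w[i, j])
  }
  total
}

# enumerate both strands at every offset, keep the better strand
bf_scan <- function(w, sequence, threshold) {
  L <- nrow(w)
  out <- list()
  for (o in 0:(nchar(sequence) - L)) {
    sub <- substr(sequence, o + 1L, o + L)
    sp <- bf_score(w, sub)
    sm <- bf_score(w, revcomp(sub))
    sc <- max(sp, sm)
    if (is.finite(sc) && sc >= threshold) {
      out[[length(out) + 1L]] <-
        data.frame(offset = o, strand = if (sp >= sm) "+" else "-",
                   score = sc)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, out)
}

bf_pairwise_gaps <- function(offsets, L) {
  offsets <- sort(offsets)
  gaps <- numeric(0)
  n <- length(offsets)
  if (n < 2L) return(gaps)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      gaps <- c(gaps, offsets[j] - (offsets[i] + L))
    }
  }
  gaps
}

# exact Mann-Whitney p by full enumeration of group assignments
bf_mw_exact_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  switch(alternative,
         greater = mean(us >= u_obs),
         less = mean(us <= u_obs),
         two.sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_len = 1000L) {
  start <- sample.int(max_len, n, replace = TRUE) - 1L
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(50L, n, replace = TRUE),
                    id = paste0("iv", seq_len(n)))
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_pwm <- function() {
  pwm(matrix(c(0, -1, -2, -3,
               -2, 0, -1, -4,
               -3, -2, 0, -1,
               -1, -3, -4, 0,
               0, -2, -1, -2), ncol = 4L, byrow = TRUE))
}
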