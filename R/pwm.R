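#' Construct a position weight matrix
#'
#' The matrix scores fixed-length windows additively: each position
#' contributes the weight of the base observed there. Weights follow the
#' max-0 convention — the per-position maximum is 0, so the optimal
#' window scores exactly 0 and every other window scores negative, down
#' to `min_score` (the sum of per-position minima).
#'
#' @param weights Numeric L x 4 matrix, columns `A`, `C`, `G`, `T`.
#' @param normalize If `TRUE`, rescale an arbitrary log-odds matrix into
#'   the max-0 convention by subtracting each row's maximum.
#' @return A `pwm` object (matrix with attribute `min_score`).
#' @export
pwm <- function(weights, normalize = FALSE) {
  weights <- as.matrix(weights)
  stopifnot(ncol(weights) == 4L, nrow(weights) >= 2L,
            is.numeric(weights), !anyNA(weights))
  colnames(weights) <- c("A", "C", "G", "T")
  if (normalize) {
    weights <- weights - apply(weights, 1L, max)
  }
  if (any(abs(apply(weights, 1L, max)) > 1e-9)) {
    stop("PWM rows must have maximum 0; use normalize = TRUE to rescale")
  }
  structure(weights, min_score = sum(apply(weights, 1L, min)),
            class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: length %d, score range [%.4g, 0]\n", nrow(x),
              attr(x, "min_score")))
  print(unclass(x))
  invisible(x)
}

#' PWM length (bp)
#' @param x A `pwm`.
#' @export
pwm_length <- function(x) nrow(x)

#' Worst attainable PWM score
#' @param x A `pwm`.
#' @export
pwm_min_score <- function(x) attr(x, "min_score")

#' Read a PWM from a tab-separated file
#'
#' Expects a header line `A C G T` (tab-separated) and one row of weights
#' per motif position, already in (or rescalable to) the max-0
#' convention.
#'
#' @param path Input path.
#' @param normalize Passed to [pwm()].
#' @return A `pwm`.
#' @export
read_pwm <- function(path, normalize = FALSE) {
  dt <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!identical(toupper(names(dt)), c("A", "C", "G", "T"))) {
    stop("PWM file must have header columns A, C, G, T: ", path)
  }
  pwm(as.matrix(dt), normalize = normalize)
}

#' Write a PWM to a tab-separated file
#'
#' Weights are printed with 17 significant digits so scores survive a
#' round trip bit-exactly.
#'
#' @param x A `pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  lines <- c(paste(c("A", "C", "G", "T"), collapse = "\t"),
             apply(unclass(x), 1L, function(r) {
               paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
             }))
  writeLines(lines, path)
  invisible(path)
}

base_index <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T"))
}

#' Score a single window
#'
#' Sums the per-position weights of the bases of an L-mer. Windows
#' containing any non-ACGT character score `-Inf` (a sentinel: such
#' windows are skipped by the scanner).
#'
#' @param x A `pwm`.
#' @param seq Character scalar of length exactly `pwm_length(x)`.
#' @return Numeric score in `[min_score, 0]`, or `-Inf`.
#' @export
score_window <- function(x, seq) {
  L <- pwm_length(x)
  if (nchar(seq) != L) {
    stop("sequence length ", nchar(seq), " != PWM length ", L)
  }
  idx <- base_index(seq)
  if (anyNA(idx)) return(-Inf)
  sum(unclass(x)[cbind(seq_len(L), idx)])
}

# Reverse-complement a PWM: scanning the forward sequence with rc(pwm)
# scores each window as its reverse complement under pwm.
reverse_complement_pwm <- function(x) {
  w <- unclass(x)[rev(seq_len(nrow(x))), c("T", "G", "C", "A")]
  colnames(w) <- c("A", "C", "G", "T")
  structure(w, min_score = attr(x, "min_score"), class = c("pwm", "matrix"))
}

# Vector of window scores at every offset of a sequence (forward strand).
scan_scores_forward <- function(x, idx) {
  L <- pwm_length(x)
  n <- length(idx)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  w <- unclass(x)
  scores <- numeric(nw)
  for (i in seq_len(L)) {
    col <- idx[i:(i + nw - 1L)]
    wi <- w[i, ][col]
    wi[is.na(col)] <- -Inf
    scores <- scores + wi
  }
  scores
}

#' Scan a sequence for binding sites on both strands
#'
#' Every offset is scored on the forward strand and as its reverse
#' complement; by default only the better-scoring strand per offset is
#' reported, so palindromic matches are not double-counted.
#'
#' @param x A `pwm`.
#' @param sequence Character scalar, length at least `pwm_length(x)`.
#' @param threshold Minimum reported score (default `pwm_min_score(x)`,
#'   i.e. everything).
#' @param collapse_strands If `FALSE`, report both strands per offset.
#' @return `data.frame` with columns `offset` (0-based start), `strand`,
#'   `score`, sorted by offset.
#' @export
scan_sequence <- function(x, sequence, threshold = pwm_min_score(x),
                          collapse_strands = TRUE) {
  L <- pwm_length(x)
  if (nchar(sequence) < L) {
    stop("sequence shorter than PWM length ", L)
  }
  idx <- base_index(sequence)
  fwd <- scan_scores_forward(x, idx)
  rev_ <- scan_scores_forward(reverse_complement_pwm(x), idx)
  nw <- length(fwd)
  if (collapse_strands) {
    strand <- ifelse(fwd >= rev_, "+", "-")
    score <- pmax(fwd, rev_)
    out <- data.frame(offset = seq_len(nw) - 1L, strand = strand,
                      score = score, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(offset = rep(seq_len(nw) - 1L, 2L),
                      strand = rep(c("+", "-"), each = nw),
                      score = c(fwd, rev_), stringsAsFactors = FALSE)
  }
  out <- out[is.finite(out$score) & out$score >= threshold, , drop = FALSE]
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GC content of a sequence
#'
#' Fraction of G or C among non-N bases.
#'
#' @param seq Character scalar.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(nchar(seq) > 0L)
  ch <- strsplit(toupper(seq), "")[[1L]]
  denom <- sum(ch != "N")
  if (denom == 0L) stop("sequence is all N; GC content undefined")
  sum(ch %in% c("G", "C")) / denom
}
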