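# RNG helper: evaluate code under a seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Mann-Whitney rank test
#'
#' Thin wrapper around [stats::wilcox.test()] pinning this package's
#' conventions: the exact null distribution is used when both samples
#' have at most 8 observations and there are no ties; otherwise the
#' normal approximation with mid-rank tie correction and continuity
#' correction. Two samples whose pooled values are all identical carry no
#' rank information and return p = 1.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return A list of class `test_report` with elements `test`,
#'   `statistic` (U of `x`), `p_value`, `alternative`, `n_x`, `n_y`,
#'   `exact`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(structure(list(test = "mann_whitney_u", statistic =
                            length(x) * length(y) / 2, p_value = 1,
                          alternative = alternative, n_x = length(x),
                          n_y = length(y), exact = FALSE),
                     class = "test_report"))
  }
  use_exact <- length(x) <= 8L && length(y) <= 8L &&
    !any(duplicated(pooled))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = use_exact,
                       correct = TRUE)
  )
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # zero-variance rank statistic under heavy ties
  structure(list(test = "mann_whitney_u",
                 statistic = unname(ht$statistic), p_value = p,
                 alternative = alternative, n_x = length(x),
                 n_y = length(y), exact = use_exact),
            class = "test_report")
}

#' Pearson correlation test
#'
#' Correlation coefficient with the two-sided p-value from the t
#' transform on n - 2 degrees of freedom, via [stats::cor.test()].
#'
#' @param x,y Numeric vectors, length >= 3, finite, non-constant.
#' @return A `test_report` list with `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in correlation input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in correlation input")
  }
  ht <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ht$estimate)
  structure(list(test = "pearson_r", r = r, r_squared = r^2,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 alternative = "two.sided", n = length(x)),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(x$test, ": ")
  if (!is.null(x$r)) {
    cat(sprintf("r = %.4f (r^2 = %.4f), ", x$r, x$r_squared))
  } else {
    cat(sprintf("U = %g, ", x$statistic))
  }
  cat(sprintf("p = %.4g (%s)\n", x$p_value, x$alternative))
  invisible(x)
}

#' Partition records into deciles by a sort key
#'
#' Records are ordered by the key ascending (ties broken by `rank` then
#' `id` when present, keeping the split deterministic) and divided into
#' 10 groups whose sizes differ by at most 1; when the count is not a
#' multiple of 10, the remainder goes to the lowest deciles.
#'
#' @param records A `data.frame` with at least the key column.
#' @param key Name of the numeric sort-key column (e.g. `"cfr"`).
#' @return Integer vector of decile assignments (1 = lowest key values,
#'   10 = highest), aligned with the rows of `records`.
#' @export
decile_partition <- function(records, key) {
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 records for a decile partition")
  k <- records[[key]]
  if (is.null(k)) stop("key column not found: ", key)
  tie1 <- if (!is.null(records$rank)) records$rank else rep(0L, n)
  tie2 <- if (!is.null(records$id)) records$id else as.character(seq_len(n))
  ord <- order(k, tie1, tie2)
  sizes <- rep(n %/% 10L, 10L) + as.integer(seq_len(10L) <= n %% 10L)
  dec <- integer(n)
  dec[ord] <- rep(seq_len(10L), times = sizes)
  dec
}

#' Compare a value across the extreme deciles of a key ordering
#'
#' Splits the records into deciles of `key` and runs a two-sided
#' Mann-Whitney test of `value` between the first (lowest-key) and last
#' (highest-key) decile.
#'
#' @param records A `data.frame`.
#' @param key Column to sort into deciles by.
#' @param value Column whose distribution is compared.
#' @param alternative Test sidedness (default two-sided).
#' @return A `test_report` with extra elements `median_low` and
#'   `median_high` (value medians in the extreme deciles).
#' @export
extreme_decile_compare <- function(records, key, value,
                                   alternative = "two.sided") {
  dec <- decile_partition(records, key)
  lo <- records[[value]][dec == 1L]
  hi <- records[[value]][dec == 10L]
  rep_ <- mann_whitney_u(hi, lo, alternative = alternative)
  rep_$median_low <- stats::median(lo)
  rep_$median_high <- stats::median(hi)
  rep_$key <- key
  rep_$value <- value
  rep_
}
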