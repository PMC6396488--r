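# Run code with a locally set RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Dixon ratio for the smallest value of a sorted (ascending) sample, with the
# statistic variant chosen by sample size: r10 (n <= 7), r11 (8-10),
# r21 (11-13), r22 (n >= 14).
.dixon_ratio <- function(x) {
  n <- length(x)
  if (n <= 7L) {
    num <- x[2L] - x[1L]; den <- x[n] - x[1L]
  } else if (n <= 10L) {
    num <- x[2L] - x[1L]; den <- x[n - 1L] - x[1L]
  } else if (n <= 13L) {
    num <- x[3L] - x[1L]; den <- x[n - 1L] - x[1L]
  } else {
    num <- x[3L] - x[1L]; den <- x[n - 2L] - x[1L]
  }
  if (den <= 0) return(0)
  num / den
}

.dixon_cache <- new.env(parent = emptyenv())

# Monte-Carlo null distribution of the Dixon ratio for the minimum of a
# standard-normal sample of size n (the statistic is location/scale free and
# symmetric, so the same null serves the maximum via reflection).
.dixon_null <- function(n, nrep, seed) {
  key <- sprintf("n%d_rep%d_seed%d", n, nrep, seed)
  hit <- .dixon_cache[[key]]
  if (!is.null(hit)) return(hit)
  null <- .with_seed(seed, {
    # the ratio only uses the 3 smallest and 3 largest order statistics,
    # so a partial sort suffices for large samples
    part <- if (n > 8L) c(1L, 2L, 3L, n - 2L, n - 1L, n) else seq_len(n)
    vapply(seq_len(nrep), function(r) {
      .dixon_ratio(sort(stats::rnorm(n), partial = part))
    }, numeric(1))
  })
  .dixon_cache[[key]] <- null
  null
}

#' Dixon outlier test with Monte-Carlo p-value
#'
#' Tests whether the extreme value at the chosen end of a sample is an
#' outlier, using the classical Dixon gap-to-range ratio with the statistic
#' variant appropriate to the sample size (r10 for n <= 7, r11 for 8-10,
#' r21 for 11-13, r22 for n >= 14). The p-value is the upper-tail
#' probability of the observed ratio under a simulated null of
#' standard-normal samples of the same size. Monte-Carlo simulation (with a
#' fixed, configurable seed and cached null distributions) supports any
#' sample size, in contrast to published critical-value tables that stop
#' around n = 30, and reproduces those tables at the sizes they cover.
#'
#' @param sample Numeric vector, length >= 3.
#' @param position Which extreme to test: \code{"min"} or \code{"max"}.
#' @param nrep Number of Monte-Carlo null replicates (default 10000).
#' @param seed RNG seed for the null simulation; the caller's RNG state is
#'   left untouched.
#' @return One-sided p-value. A constant sample returns 1.
#' @export
dixon_test <- function(sample, position = c("min", "max"), nrep = 10000L,
                       seed = 1905L) {
  position <- match.arg(position)
  x <- as.numeric(sample)
  if (anyNA(x)) x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("Dixon test needs at least 3 values", call. = FALSE)
  if (diff(range(x)) == 0) return(1)
  x <- sort(if (position == "max") -x else x)
  r <- .dixon_ratio(x)
  null <- .dixon_null(n, nrep, seed)
  (1 + sum(null >= r)) / (nrep + 1)
}
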