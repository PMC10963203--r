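# Sampling mechanics: SRSWOR draws, respondent/non-respondent realization,
# Hansen-Hurwitz subsampling of non-respondents, and base design weights.

#' Simple random sample without replacement
#'
#' @param N population size.
#' @param n sample size, `1 <= n <= N`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return Sorted vector of `n` distinct indices in `1..N`, uniform over all
#'   n-subsets.
#' @export
draw_srswor <- function(N, n, seed = NULL) {
  if (length(N) != 1L || length(n) != 1L || n < 1L || n > N) {
    stop("invalid design: need 1 <= n <= N", call. = FALSE)
  }
  with_seed(seed, sort(sample.int(N, n)))
}

#' Split a sample into respondents and non-respondents
#'
#' Partitions the sampled unit ids by the unit's fixed response stratum in
#' the population frame.
#'
#' @param s sampled unit ids.
#' @param frame a `population_frame`.
#' @return A list with elements `s1` (respondents) and `s2`
#'   (non-respondents).
#' @export
realize_response <- function(s, frame) {
  idx <- match(s, frame$unit_id)
  if (anyNA(idx)) {
    stop("sample contains unit ids absent from the frame", call. = FALSE)
  }
  str <- frame$stratum[idx]
  list(s1 = s[str == "R"], s2 = s[str == "NR"])
}

#' Hansen-Hurwitz subsample of the non-respondents
#'
#' Draws an SRSWOR subsample of size `min(n2r_target, n2)` from the sampled
#' non-respondents; its units are re-contacted and their values expanded by
#' the subsampling factor `k = n2 / n2r`.  When the target exceeds `n2` the
#' whole set is taken and `k = 1`.  An empty `s2` yields an empty subsample
#' with `k = NA` (flagged via `empty`), not an error.
#'
#' @param s2 non-respondent unit ids.
#' @param n2r_target requested subsample size (>= 1).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return List with `s2r` (subsampled ids, sorted), `k` (real subsampling
#'   factor), and `empty` flag.
#' @export
subsample_nonrespondents <- function(s2, n2r_target, seed = NULL) {
  if (n2r_target < 1L) stop("n2r_target must be at least 1", call. = FALSE)
  n2 <- length(s2)
  if (n2 == 0L) {
    return(list(s2r = s2[0], k = NA_real_, empty = TRUE))
  }
  n2r <- min(n2r_target, n2)
  s2r <- with_seed(seed, sort(s2[sample.int(n2, n2r)]))
  list(s2r = s2r, k = n2 / n2r, empty = FALSE)
}

#' Draw a full single-phase sample realization
#'
#' Draws an SRSWOR sample of size `n` from the frame, splits it by response
#' stratum, and subsamples the non-respondents.  The base design weights are
#' `d1 = N/n` for every sampled unit (inverse first-stage inclusion
#' probability) times `d2prime = k = n2/n2r` for subsampled non-respondents.
#'
#' @param frame a `population_frame`.
#' @param n sample size.
#' @param n2r_target requested non-respondent subsample size.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return A `sample_realization`: list with unit-id sets `s`, `s1`, `s2`,
#'   `s2r`, counts `n`, `n1`, `n2`, `n2r`, subsampling factor `k`, population
#'   size `N`, and weights `d1`, `d2prime`.
#' @export
draw_sample <- function(frame, n, n2r_target, seed = NULL) {
  frame <- as_population_frame(frame)
  N <- nrow(frame)
  with_seed(seed, {
    s <- frame$unit_id[draw_srswor(N, n)]
    rr <- realize_response(s, frame)
    sub <- subsample_nonrespondents(rr$s2, n2r_target)
    structure(
      list(s = s, s1 = rr$s1, s2 = rr$s2, s2r = sub$s2r,
           n = length(s), n1 = length(rr$s1), n2 = length(rr$s2),
           n2r = length(sub$s2r),
           k = sub$k, N = N,
           d1 = N / n, d2prime = sub$k),
      class = "sample_realization")
  })
}

#' @export
print.sample_realization <- function(x, ...) {
  cat("Sample realization: n =", x$n, "of N =", x$N, "\n")
  cat("  respondents n1 =", x$n1,
      " non-respondents n2 =", x$n2,
      " subsampled n2r =", x$n2r,
      " k =", format(x$k, digits = 4), "\n")
  cat("  design weights: d1 =", format(x$d1, digits = 6),
      " d2' =", format(x$d2prime, digits = 6), "\n")
  invisible(x)
}

#' Base design weights of a realization
#'
#' Every unit in `s1` carries weight `d1 = N/n`; every unit in `s2r` carries
#' `d1 * d2prime = (N/n) * (n2/n2r)`.  These weights define the base
#' Hansen-Hurwitz estimator of the population total,
#' `sum(d1 * y[s1]) + sum(d1 * d2prime * y[s2r])`.
#'
#' @param r a `sample_realization`.
#' @return List with scalars `d1`, `d2prime` and a named per-unit weight
#'   vector `w` over `c(s1, s2r)`.
#' @export
base_weights <- function(r) {
  stopifnot(inherits(r, "sample_realization"))
  if (r$n2 > 0L && r$n2r == 0L) {
    stop("unusable realization: non-respondents present but none subsampled",
         call. = FALSE)
  }
  w <- c(rep(r$d1, r$n1), rep(r$d1 * r$d2prime, r$n2r))
  names(w) <- as.character(c(r$s1, r$s2r))
  list(d1 = r$d1, d2prime = r$d2prime, w = w)
}

#' Base Hansen-Hurwitz estimate of the population total
#'
#' @param r a `sample_realization`.
#' @param frame the `population_frame` it was drawn from.
#' @return The uncalibrated design-weighted total of `y`.
#' @export
hh_total <- function(r, frame) {
  bw <- base_weights(r)
  y1 <- frame$y[match(r$s1, frame$unit_id)]
  y2 <- frame$y[match(r$s2r, frame$unit_id)]
  sum(bw$d1 * y1) + sum(bw$d1 * bw$d2prime * y2)
}
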