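# Two-phase (double sampling) calibration for the case where domain
# auxiliary totals are unknown.  A large first-phase sample measures the
# auxiliary and yields estimated domain auxiliary totals (x1a', x2a'); the
# phase-1 weights are calibrated to those targets; a smaller second-phase
# subsample measures the study variable and its weights -- chained onto the
# phase-1 calibrated weights -- are calibrated to the same targets.
#
# Response is a fixed unit attribute, so the phase-2 respondents are a
# subset of the phase-1 respondents.  Non-respondents only have x observed
# if they were re-contacted at phase 1, so the phase-2 non-respondent
# subsample is drawn from phase-2 units already in the phase-1
# non-respondent subsample; with that nesting every chained weight is
# defined and weights multiply across phases.

#' Draw a two-phase sample
#'
#' Phase 1 is a per-domain SRSWOR of `floor(fraction * Na + 0.5)` units (the
#' per-unit first-phase weight is the exact inverse inclusion probability
#' `Na / n1a'`), followed by response realization and Hansen-Hurwitz
#' subsampling of the phase-1 non-respondents.  Phase 2 is an SRSWOR of
#' `n_phase2` units from the whole phase-1 sample (conditional weight
#' `n' / n''`), again split by the fixed response stratum; its non-respondent
#' subsample is drawn from phase-2 units that are in the phase-1
#' non-respondent subsample (only those have the auxiliary observed).
#'
#' @param frame a `population_frame`.
#' @param phase1_fraction fraction of each domain drawn at phase 1, in
#'   (0, 1]; 1 gives a census first phase.
#' @param n_phase2 phase-2 sample size (<= phase-1 sample size).
#' @param n2r_phase1 requested phase-1 non-respondent subsample size.
#' @param n2r_phase2 requested phase-2 non-respondent subsample size.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return A `twophase_sample` list: phase-1 ids `s1p`, `s11p`, `s12p`,
#'   `s12rp` with per-unit weights `d11` (named by unit id) and factor `k1`;
#'   phase-2 ids `s2p`, `s11pp`, `s12rpp` with conditional weight `d11pp`
#'   and factor `k2`; sizes and the generating parameters.
#' @export
draw_two_phase <- function(frame, phase1_fraction = 0.6, n_phase2,
                           n2r_phase1, n2r_phase2 = n2r_phase1,
                           seed = NULL) {
  frame <- as_population_frame(frame)
  if (phase1_fraction <= 0 || phase1_fraction > 1) {
    stop("phase1_fraction must lie in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    doms <- sort(unique(frame$domain))
    s1p <- integer(0)
    d11 <- numeric(0)
    for (a in doms) {
      ids <- frame$unit_id[frame$domain == a]
      Na <- length(ids)
      na1 <- round_half_up(phase1_fraction * Na)
      if (na1 < 1L || na1 > Na) {
        stop("infeasible phase-1 allocation in domain ", a, call. = FALSE)
      }
      sel <- if (na1 == Na) ids else sort(ids[sample.int(Na, na1)])
      s1p <- c(s1p, sel)
      d11 <- c(d11, rep(Na / na1, na1))
    }
    names(d11) <- as.character(s1p)
    rr1 <- realize_response(s1p, frame)
    sub1 <- subsample_nonrespondents(rr1$s2, n2r_phase1)
    n1p <- length(s1p)
    if (n_phase2 < 1L || n_phase2 > n1p) {
      stop("infeasible phase-2 size: need 1 <= n_phase2 <= ", n1p, call. = FALSE)
    }
    s2p <- sort(s1p[sample.int(n1p, n_phase2)])
    rr2 <- realize_response(s2p, frame)
    candidates <- intersect(s2p, sub1$s2r)
    sub2 <- subsample_nonrespondents(candidates, n2r_phase2)
    structure(
      list(s1p = s1p, s11p = rr1$s1, s12p = rr1$s2, s12rp = sub1$s2r,
           k1 = sub1$k, d11 = d11, n1p = n1p,
           s2p = s2p, s11pp = rr2$s1, s12rpp = sub2$s2r,
           k2 = sub2$k, d11pp = n1p / n_phase2,
           phase1_fraction = phase1_fraction, n_phase2 = n_phase2),
      class = "twophase_sample")
  })
}

#' @export
print.twophase_sample <- function(x, ...) {
  cat("Two-phase sample:\n")
  cat("  phase 1: n' =", x$n1p,
      " respondents =", length(x$s11p),
      " NR subsample =", length(x$s12rp),
      " k' =", format(x$k1, digits = 4), "\n")
  cat("  phase 2: n'' =", length(x$s2p),
      " respondents =", length(x$s11pp),
      " NR subsample =", length(x$s12rpp),
      " k'' =", format(x$k2, digits = 4), "\n")
  invisible(x)
}

#' Phase-1 estimated domain auxiliary totals
#'
#' The calibration targets of both phases: per domain,
#' `x1a' = sum(d11 * x)` over phase-1 respondents in the domain and
#' `x2a' = sum(d11 * k1 * x)` over subsampled phase-1 non-respondents in the
#' domain -- the phase-1 Hansen-Hurwitz domain totals of the auxiliary.
#' A domain with no phase-1 respondents is flagged non-estimable.
#'
#' @param tp a `twophase_sample`.
#' @param frame the `population_frame`.
#' @return Data frame with columns `domain`, `x1a`, `x2a`, `estimable`.
#' @export
phase1_targets <- function(tp, frame) {
  stopifnot(inherits(tp, "twophase_sample"))
  doms <- sort(unique(frame$domain))
  dom_of <- function(ids) frame$domain[match(ids, frame$unit_id)]
  x_of <- function(ids) frame$x[match(ids, frame$unit_id)]
  d_resp <- tp$d11[as.character(tp$s11p)]
  d_nr <- tp$d11[as.character(tp$s12rp)] * tp$k1
  dom_r <- dom_of(tp$s11p); x_r <- x_of(tp$s11p)
  dom_n <- dom_of(tp$s12rp); x_n <- x_of(tp$s12rp)
  rows <- lapply(doms, function(a) {
    x1a <- sum(d_resp[dom_r == a] * x_r[dom_r == a])
    x2a <- if (length(x_n)) sum(d_nr[dom_n == a] * x_n[dom_n == a]) else 0
    data.frame(domain = a, x1a = x1a, x2a = x2a, estimable = x1a > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate the phase-1 weights to one domain's estimated targets
#'
#' Calibrates the full phase-1 respondent sample to `x1a` and the full
#' phase-1 non-respondent subsample to `x2a` (indirect estimation), under
#' the chosen q-weight policy.
#'
#' @param tp a `twophase_sample`.
#' @param frame the `population_frame`.
#' @param x1a,x2a the domain's phase-1 targets (see [phase1_targets()]).
#' @param policy one of `"unit"`, `"inverse_x"`, `"exponential"`, `"power"`.
#' @param tolerance,max_iter solver controls.
#' @return List with `resp` and `nr` `stratum_calibration` objects (the
#'   weights in `$t` are named by unit id; `nr` is `NULL` when the phase-1
#'   non-respondent subsample is empty or `x2a` is zero).
#' @export
phase1_calibrate <- function(tp, frame, x1a, x2a,
                             policy = c("unit", "inverse_x", "exponential", "power"),
                             tolerance = 1e-10, max_iter = 100L) {
  stopifnot(inherits(tp, "twophase_sample"))
  policy <- match.arg(policy)
  x_of <- function(ids) frame$x[match(ids, frame$unit_id)]
  d_r <- tp$d11[as.character(tp$s11p)]
  resp <- calibrate_stratum(unname(d_r), x_of(tp$s11p), x1a, policy,
                            tolerance, max_iter)
  names(resp$t) <- as.character(tp$s11p)
  nr <- NULL
  if (length(tp$s12rp) > 0L && x2a > 0) {
    d_n <- tp$d11[as.character(tp$s12rp)] * tp$k1
    nr <- calibrate_stratum(unname(d_n), x_of(tp$s12rp), x2a, policy,
                            tolerance, max_iter)
    names(nr$t) <- as.character(tp$s12rp)
  }
  list(resp = resp, nr = nr)
}

#' Calibrate the phase-2 weights to the same targets
#'
#' The phase-2 baseline weight of a unit is its own phase-1 calibrated
#' weight times the conditional phase-2 design weight(s):
#' `t' * d11''` for respondents, `t' * d11'' * k2` for subsampled
#' non-respondents.  Those baselines are calibrated to `x1a` and `x2a`
#' under the same policy, so the final weighted auxiliary sums reproduce
#' the phase-1 targets.
#'
#' @inheritParams phase1_calibrate
#' @param p1 result of [phase1_calibrate()] for the same domain and policy.
#' @return List with `resp` and `nr` `stratum_calibration` objects (named
#'   weights; `nr` is `NULL` when the phase-2 non-respondent subsample is
#'   empty).
#' @export
phase2_calibrate <- function(tp, frame, p1, x1a, x2a,
                             policy = c("unit", "inverse_x", "exponential", "power"),
                             tolerance = 1e-10, max_iter = 100L) {
  stopifnot(inherits(tp, "twophase_sample"))
  policy <- match.arg(policy)
  x_of <- function(ids) frame$x[match(ids, frame$unit_id)]
  ids_r <- as.character(tp$s11pp)
  base_r <- p1$resp$t[ids_r] * tp$d11pp
  if (anyNA(base_r)) {
    stop("phase-2 respondent outside the phase-1 respondent sample", call. = FALSE)
  }
  resp <- calibrate_stratum(unname(base_r), x_of(tp$s11pp), x1a, policy,
                            tolerance, max_iter)
  names(resp$t) <- ids_r
  nr <- NULL
  if (length(tp$s12rpp) > 0L && !is.null(p1$nr) && x2a > 0) {
    ids_n <- as.character(tp$s12rpp)
    base_n <- p1$nr$t[ids_n] * tp$d11pp * tp$k2
    if (anyNA(base_n)) {
      stop("phase-2 non-respondent outside the phase-1 subsample", call. = FALSE)
    }
    nr <- calibrate_stratum(unname(base_n), x_of(tp$s12rpp), x2a, policy,
                            tolerance, max_iter)
    names(nr$t) <- ids_n
  }
  list(resp = resp, nr = nr)
}

#' All two-phase calibrated domain estimates
#'
#' Chains [phase1_targets()], [phase1_calibrate()] and [phase2_calibrate()]
#' per domain and estimator and returns the phase-2 calibrated weighted
#' total of `y`.  Per-domain solver failures yield `NA` cells; the batch
#' continues.  Domains with no phase-1 respondents are non-estimable
#' (`NA`, `degenerate`); replicates whose phase-2 non-respondent subsample
#' is empty use the respondent term only and are flagged `degenerate`.
#'
#' @param tp a `twophase_sample`.
#' @param frame the `population_frame`.
#' @param estimators subset of `c("ratio", "greg", "exponential", "power")`.
#' @param tolerance,max_iter solver controls.
#' @return A `domain_estimates` data frame (as [estimate_all()]).
#' @export
two_phase_estimates <- function(tp, frame,
                                estimators = c("ratio", "greg",
                                               "exponential", "power"),
                                tolerance = 1e-10, max_iter = 100L) {
  stopifnot(inherits(tp, "twophase_sample"))
  frame <- as_population_frame(frame)
  estimators <- match.arg(estimators, several.ok = TRUE)
  targets <- phase1_targets(tp, frame)
  y_of <- function(ids) frame$y[match(ids, frame$unit_id)]
  has_nr <- length(tp$s12p) > 0L
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    a <- targets$domain[i]
    for (est in estimators) {
      if (!targets$estimable[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          domain = a, estimator = est, value = NA_real_,
          converged = FALSE, degenerate = TRUE, negative_weights = 0L)
        next
      }
      res <- tryCatch({
        pol <- estimator_policy[[est]]
        p1 <- phase1_calibrate(tp, frame, targets$x1a[i], targets$x2a[i],
                               pol, tolerance, max_iter)
        p2 <- phase2_calibrate(tp, frame, p1, targets$x1a[i], targets$x2a[i],
                               pol, tolerance, max_iter)
        value <- sum(p2$resp$t * y_of(tp$s11pp))
        negative <- p2$resp$negative
        if (!is.null(p2$nr)) {
          value <- value + sum(p2$nr$t * y_of(tp$s12rpp))
          negative <- negative + p2$nr$negative
        }
        list(value = value,
             converged = p2$resp$converged &&
               (is.null(p2$nr) || p2$nr$converged),
             degenerate = has_nr && is.null(p2$nr),
             negative = negative)
      }, error = function(e) list(value = NA_real_, converged = FALSE,
                                  degenerate = TRUE, negative = 0L))
      rows[[length(rows) + 1L]] <- data.frame(
        domain = a, estimator = est, value = res$value,
        converged = res$converged, degenerate = res$degenerate,
        negative_weights = res$negative)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("domain_estimates", "data.frame")
  out
}
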