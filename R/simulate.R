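# Design-based Monte Carlo engine: repeated sampling from a fixed finite
# population, per-replicate calibration estimates, and ARB/SMSE/SRSE
# aggregation per estimator and domain.

#' Run a design-based Monte Carlo study
#'
#' Repeatedly samples the fixed population, computes every requested
#' calibrated domain estimate per replicate, and aggregates absolute
#' relative bias ([arb()]), simulated MSE ([smse()]) and simulated relative
#' standard error ([srse()]) per (estimator, domain) against the population
#' truth.  Deterministic given `seed`.
#'
#' In `"single_phase"` mode each replicate is a [draw_sample()] followed by
#' [estimate_all()] calibrated to the supplied `targets` (the true domain
#' auxiliary totals by default).  In `"two_phase"` mode each replicate is a
#' [draw_two_phase()] followed by [two_phase_estimates()]; the targets are
#' then estimated from the phase-1 sample, so `targets` is ignored.  The
#' `"base"` estimator (uncalibrated Hansen-Hurwitz) targets the population
#' total `Y` and is reported with `domain = NA`.
#'
#' Failed solver cells are dropped from that cell's replicate set (counted
#' in `reps_used`); degenerate replicates (no sampled non-respondents, or a
#' non-estimable domain) are counted in `degenerate`.
#'
#' @param frame the `population_frame` to sample from; the truth is
#'   `summarize_domains(frame)`.
#' @param n single-phase sample size.
#' @param n2r_target requested non-respondent subsample size (phase 1 in
#'   two-phase mode).
#' @param reps number of Monte Carlo replicates (>= 1).
#' @param estimators subset of
#'   `c("base", "ratio", "greg", "exponential", "power")`.
#' @param mode `"single_phase"` or `"two_phase"`.
#' @param targets calibration targets (`domain_totals`); defaults to the
#'   truth.  Single-phase mode only.
#' @param phase1_fraction,n_phase2,n2r_phase2 two-phase design parameters,
#'   see [draw_two_phase()].
#' @param seed master seed (optional).
#' @param tolerance,max_iter solver controls.
#' @return A `domain_sim` object: list with `results` (data frame
#'   `estimator, domain, arb, smse, srse, reps_used, degenerate,
#'   negative_weight_rate`), `truth`, and `meta` (the configuration,
#'   including the seed).
#' @examples
#' frame <- generate_population(population_spec(seed = 1))
#' sim <- run_study(frame, n = 70, n2r_target = 12, reps = 50, seed = 2)
#' print(sim)
#' @export
run_study <- function(frame, n, n2r_target, reps,
                      estimators = c("base", "ratio", "greg",
                                     "exponential", "power"),
                      mode = c("single_phase", "two_phase"),
                      targets = NULL,
                      phase1_fraction = 0.6,
                      n_phase2 = n,
                      n2r_phase2 = n2r_target,
                      seed = NULL,
                      tolerance = 1e-10, max_iter = 100L) {
  frame <- as_population_frame(frame)
  mode <- match.arg(mode)
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (reps < 1L) stop("reps must be at least 1", call. = FALSE)
  if (mode == "single_phase" && n > nrow(frame)) {
    stop("population infeasible for the design: n > N", call. = FALSE)
  }
  truth <- summarize_domains(frame)
  if (is.null(targets)) targets <- truth
  targets <- as_domain_totals(targets)
  if (!is.null(seed)) set.seed(seed)

  cal_estimators <- setdiff(estimators, "base")
  doms <- targets$domain
  cells <- expand.grid(estimator = estimators, domain_idx = seq_along(doms),
                       stringsAsFactors = FALSE)
  # base occupies a single population-level cell
  cells <- cells[!(cells$estimator == "base" & cells$domain_idx > 1L), ]
  values <- matrix(NA_real_, nrow = reps, ncol = nrow(cells))
  degen <- matrix(FALSE, nrow = reps, ncol = nrow(cells))
  negw <- matrix(FALSE, nrow = reps, ncol = nrow(cells))

  cell_key <- paste(cells$estimator,
                    ifelse(cells$estimator == "base", "NA", doms[cells$domain_idx]))
  for (s in seq_len(reps)) {
    est <- if (mode == "single_phase") {
      r <- draw_sample(frame, n, n2r_target)
      estimate_all(r, frame, targets, estimators,
                   tolerance = tolerance, max_iter = max_iter)
    } else {
      tp <- draw_two_phase(frame, phase1_fraction, n_phase2,
                           n2r_target, n2r_phase2)
      out <- two_phase_estimates(tp, frame,
                                 if (length(cal_estimators)) cal_estimators
                                 else "ratio",
                                 tolerance = tolerance, max_iter = max_iter)
      out <- out[out$estimator %in% cal_estimators, , drop = FALSE]
      if ("base" %in% estimators) {
        y_of <- function(ids) frame$y[match(ids, frame$unit_id)]
        d_r <- tp$d11[as.character(tp$s11pp)] * tp$d11pp
        d_n <- tp$d11[as.character(tp$s12rpp)] * tp$k1 * tp$d11pp * tp$k2
        out <- rbind(data.frame(
          domain = NA_integer_, estimator = "base",
          value = sum(d_r * y_of(tp$s11pp)) + sum(d_n * y_of(tp$s12rpp)),
          converged = TRUE, degenerate = length(tp$s12rpp) == 0L &&
            length(tp$s12p) > 0L,
          negative_weights = 0L), out)
      }
      out
    }
    key <- paste(est$estimator, ifelse(is.na(est$domain), "NA", est$domain))
    j <- match(key, cell_key)
    ok <- !is.na(j)
    values[s, j[ok]] <- est$value[ok]
    degen[s, j[ok]] <- est$degenerate[ok]
    negw[s, j[ok]] <- est$negative_weights[ok] > 0L
  }

  Y <- sum(truth$Ya)
  rows <- lapply(seq_len(nrow(cells)), function(jc) {
    est <- cells$estimator[jc]
    a <- if (est == "base") NA_integer_ else doms[cells$domain_idx[jc]]
    tv <- if (est == "base") Y else truth$Ya[truth$domain == a]
    v <- values[, jc]
    ok <- is.finite(v)
    ms <- if (any(ok)) smse(v[ok], tv) else NA_real_
    data.frame(
      estimator = est, domain = a,
      arb = if (any(ok)) arb(v[ok], tv) else NA_real_,
      smse = ms,
      srse = if (any(ok)) srse(ms, tv) else NA_real_,
      reps_used = sum(ok),
      degenerate = sum(degen[, jc]),
      negative_weight_rate = mean(negw[ok, jc]))
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(
    list(results = results, truth = truth,
         meta = list(mode = mode, n = n, n2r_target = n2r_target,
                     reps = reps, estimators = estimators,
                     phase1_fraction = if (mode == "two_phase") phase1_fraction else NULL,
                     n_phase2 = if (mode == "two_phase") n_phase2 else NULL,
                     n2r_phase2 = if (mode == "two_phase") n2r_phase2 else NULL,
                     seed = seed,
                     N = nrow(frame))),
    class = "domain_sim")
}

#' Format simulation results as an "SRSE (ARB)" table
#'
#' One row per estimator, one column per domain; each cell shows the
#' simulated relative standard error with the absolute relative bias in
#' parentheses, both in percent.
#'
#' @param x a `domain_sim` object.
#' @param digits decimal places per entry.
#' @return A character matrix.
#' @export
results_table <- function(x, digits = 2) {
  stopifnot(inherits(x, "domain_sim"))
  res <- x$results[x$results$estimator != "base", , drop = FALSE]
  ests <- unique(res$estimator)
  doms <- sort(unique(res$domain))
  m <- matrix("", nrow = length(ests), ncol = length(doms),
              dimnames = list(ests, paste("domain", doms)))
  fmt <- paste0("%.", digits, "f (%.", digits, "f)")
  for (i in seq_len(nrow(res))) {
    m[res$estimator[i], paste("domain", res$domain[i])] <-
      sprintf(fmt, res$srse[i], res$arb[i])
  }
  m
}

#' @export
print.domain_sim <- function(x, ...) {
  m <- x$meta
  cat("Design-based Monte Carlo study (", m$mode, "): ",
      m$reps, " replicates, N = ", m$N, ", n = ", m$n,
      ", n2r = ", m$n2r_target, "\n", sep = "")
  if (!is.null(m$seed)) cat("Master seed:", m$seed, "\n")
  cat("\nSRSE (ARB), percent:\n")
  print(results_table(x), quote = FALSE)
  base <- x$results[x$results$estimator == "base", , drop = FALSE]
  if (nrow(base)) {
    cat("\nBase Hansen-Hurwitz (population total): ARB = ",
        sprintf("%.3f", base$arb), "%, SRSE = ",
        sprintf("%.2f", base$srse), "%\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.domain_sim <- function(object, ...) {
  print(object)
  cat("\nPer-cell results:\n")
  print(object$results, row.names = FALSE)
  invisible(object$results)
}

#' Write and re-read simulation results
#'
#' Writes the per-cell results as CSV
#' (`estimator,domain,arb,smse,srse,reps_used,degenerate,negative_weight_rate`),
#' the truth table, and a JSON metadata sidecar (configuration including the
#' master seed).  Numeric values are written with 17 significant digits, so
#' the round trip is lossless.
#'
#' @param x a `domain_sim` object.
#' @param dir output directory (created if missing).
#' @return `write_results()` returns `dir` invisibly; `read_results()`
#'   returns the reconstructed `domain_sim`.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "domain_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    as.data.frame(lapply(df, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else col
    }), stringsAsFactors = FALSE)
  }
  write.csv(fmt(x$results), file.path(dir, "results.csv"),
            row.names = FALSE, quote = FALSE)
  write_domain_totals(x$truth, file.path(dir, "truth.csv"))
  jsonlite::write_json(x$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_results
#' @param dir directory previously written by `write_results()`.
#' @export
read_results <- function(dir) {
  results <- read.csv(file.path(dir, "results.csv"), stringsAsFactors = FALSE)
  results$domain <- as.integer(results$domain)
  truth <- read_domain_totals(file.path(dir, "truth.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!is.null(meta$estimators)) meta$estimators <- as.character(meta$estimators)
  structure(list(results = results, truth = truth, meta = meta),
            class = "domain_sim")
}
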