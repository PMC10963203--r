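# Finite-population data model: synthetic generation, domain summaries,
# validation, and the packaged Swedish municipality totals.

#' Specification of a synthetic finite population
#'
#' Describes a finite population partitioned into domains, with a positively
#' skewed auxiliary variable `x`, a study variable `y` approximately
#' proportional to `x`, and a fixed non-respondent stratum inside each
#' domain.  Defaults reproduce the study conditions of the packaged Swedish
#' municipality data: six domains of sizes 48/32/38/41/15/29 (203 units),
#' 30\% non-respondents per domain, lognormal `x`.
#'
#' @param domain_sizes integer vector of per-domain unit counts (all >= 1).
#' @param nonresponse_rate fraction of each domain assigned to the
#'   non-respondent stratum, in (0, 1); scalar or one value per domain.
#'   The realized count is `floor(rate * Na + 0.5)` and must be strictly
#'   between 0 and `Na`.
#' @param x_skew_shape positive `sdlog` of the lognormal law for `x`;
#'   larger values give stronger right skew.
#' @param link_slope positive slope beta in `y = beta * x * (1 + noise)`.
#' @param noise_scale non-negative relative dispersion of `y` about
#'   `link_slope * x` (standard deviation of the multiplicative noise).
#' @param target_totals optional `domain_totals` object (see
#'   [summarize_domains()]); generated `x` and `y` are rescaled per domain
#'   and stratum so realized stratum totals match `X1a/X2a/Y1a/Y2a` exactly.
#' @param seed optional integer seed making generation reproducible.
#'
#' @return An object of class `population_spec`.
#' @seealso [generate_population()]
#' @export
population_spec <- function(domain_sizes = c(48L, 32L, 38L, 41L, 15L, 29L),
                            nonresponse_rate = 0.3,
                            x_skew_shape = 1,
                            link_slope = 1.8,
                            noise_scale = 0.3,
                            target_totals = NULL,
                            seed = NULL) {
  domain_sizes <- as.integer(domain_sizes)
  L <- length(domain_sizes)
  if (L < 1L || any(domain_sizes < 1L)) {
    stop("domain_sizes must be a non-empty vector of positive integers", call. = FALSE)
  }
  if (!length(nonresponse_rate) %in% c(1L, L)) {
    stop("nonresponse_rate must be scalar or one value per domain", call. = FALSE)
  }
  rate <- rep_len(nonresponse_rate, L)
  if (any(rate <= 0) || any(rate >= 1)) {
    stop("nonresponse_rate must lie strictly in (0, 1)", call. = FALSE)
  }
  n2 <- round_half_up(rate * domain_sizes)
  if (any(n2 < 1L) || any(n2 >= domain_sizes)) {
    stop("infeasible spec: each domain needs at least one respondent and one non-respondent",
         call. = FALSE)
  }
  if (x_skew_shape <= 0) stop("x_skew_shape must be positive", call. = FALSE)
  if (link_slope <= 0) stop("link_slope must be positive", call. = FALSE)
  if (noise_scale < 0) stop("noise_scale must be non-negative", call. = FALSE)
  if (!is.null(target_totals)) {
    target_totals <- as_domain_totals(target_totals)
    if (nrow(target_totals) != L) {
      stop("target_totals must have one row per domain", call. = FALSE)
    }
  }
  structure(
    list(domain_sizes = domain_sizes,
         nonresponse_rate = rate,
         x_skew_shape = x_skew_shape,
         link_slope = link_slope,
         noise_scale = noise_scale,
         target_totals = target_totals,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Synthetic population spec:",
      length(x$domain_sizes), "domains,",
      sum(x$domain_sizes), "units\n")
  cat("  domain sizes:      ", paste(x$domain_sizes, collapse = "/"), "\n")
  cat("  non-response rate: ", paste(unique(x$nonresponse_rate), collapse = ", "), "\n")
  cat("  x skew shape:      ", x$x_skew_shape,
      "  link slope:", x$link_slope,
      "  noise scale:", x$noise_scale, "\n")
  cat("  target totals:     ", if (is.null(x$target_totals)) "none" else "supplied", "\n")
  invisible(x)
}

#' Generate a synthetic finite population
#'
#' Draws a unit-level population frame from a [population_spec()]: within each
#' domain, `x` is lognormal (right-skewed), `y = link_slope * x * (1 + eps)`
#' with `eps ~ N(0, noise_scale)` truncated so `y >= 0`, and
#' `floor(rate * Na + 0.5)` randomly chosen units form the fixed
#' non-respondent stratum.  When `target_totals` is supplied, `x` and `y` are
#' rescaled multiplicatively per domain and stratum so that realized stratum
#' totals equal `X1a/X2a/Y1a/Y2a` exactly (the rescaling preserves the shape
#' of the skewed distribution).
#'
#' The non-respondent stratum is a fixed unit attribute drawn once here, not
#' re-randomized per sampling replicate: the Hansen-Hurwitz set-up and the
#' fixed stratum counts of the reference data presuppose fixed strata.
#'
#' @param spec a [population_spec()].
#' @return A `population_frame`: a data frame with columns `unit_id`,
#'   `domain`, `y`, `x`, `stratum` (`"R"`/`"NR"`).
#' @examples
#' frame <- generate_population(population_spec(seed = 1))
#' nrow(frame)            # 203
#' table(frame$stratum)   # ~30% NR
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    L <- length(spec$domain_sizes)
    pieces <- vector("list", L)
    next_id <- 1L
    for (a in seq_len(L)) {
      Na <- spec$domain_sizes[a]
      x <- rlnorm(Na, meanlog = 0, sdlog = spec$x_skew_shape)
      eps <- if (spec$noise_scale > 0) rnorm(Na, 0, spec$noise_scale) else numeric(Na)
      y <- pmax(spec$link_slope * x * (1 + eps), 0)
      stratum <- rep("R", Na)
      n2a <- round_half_up(spec$nonresponse_rate[a] * Na)
      stratum[sample.int(Na, n2a)] <- "NR"
      if (!is.null(spec$target_totals)) {
        tt <- spec$target_totals[a, ]
        for (s in c("R", "NR")) {
          in_s <- stratum == s
          xt <- if (s == "R") tt$X1a else tt$X2a
          yt <- if (s == "R") tt$Y1a else tt$Y2a
          x[in_s] <- x[in_s] * xt / sum(x[in_s])
          y[in_s] <- y[in_s] * yt / sum(y[in_s])
        }
      }
      pieces[[a]] <- data.frame(
        unit_id = seq.int(next_id, length.out = Na),
        domain = a, y = y, x = x, stratum = stratum,
        stringsAsFactors = FALSE)
      next_id <- next_id + Na
    }
    frame <- do.call(rbind, pieces)
    rownames(frame) <- NULL
    class(frame) <- c("population_frame", "data.frame")
    frame
  })
}

as_population_frame <- function(frame) {
  req <- c("unit_id", "domain", "y", "x", "stratum")
  if (!all(req %in% names(frame))) {
    stop("population frame needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(frame$unit_id)) stop("unit_id must be unique", call. = FALSE)
  if (any(frame$x <= 0)) stop("auxiliary values x must be strictly positive", call. = FALSE)
  if (any(frame$y < 0)) stop("study values y must be non-negative", call. = FALSE)
  if (!all(frame$stratum %in% c("R", "NR"))) {
    stop("stratum must be 'R' or 'NR'", call. = FALSE)
  }
  class(frame) <- unique(c("population_frame", class(frame)))
  frame
}

#' Per-domain, per-stratum totals of a population frame
#'
#' Computes exact domain totals `Na/N1a/N2a`, `Ya/Y1a/Y2a`, `Xa/X1a/X2a`,
#' where the `1`/`2` components are the respondent and non-respondent
#' stratum shares.  These serve both as calibration targets and as the truth
#' against which Monte Carlo metrics are computed.
#'
#' @param frame a `population_frame` (see [generate_population()]).
#' @return A `domain_totals` data frame, one row per domain.
#' @export
summarize_domains <- function(frame) {
  frame <- as_population_frame(frame)
  if (nrow(frame) == 0L) stop("population frame is empty", call. = FALSE)
  doms <- sort(unique(frame$domain))
  rows <- lapply(doms, function(a) {
    in_a <- frame$domain == a
    if (!any(in_a)) stop("domain ", a, " has no units", call. = FALSE)
    r <- in_a & frame$stratum == "R"
    nr <- in_a & frame$stratum == "NR"
    data.frame(domain = a,
               Na = sum(in_a), N1a = sum(r), N2a = sum(nr),
               Ya = sum(frame$y[in_a]), Y1a = sum(frame$y[r]), Y2a = sum(frame$y[nr]),
               Xa = sum(frame$x[in_a]), X1a = sum(frame$x[r]), X2a = sum(frame$x[nr]))
  })
  as_domain_totals(do.call(rbind, rows))
}

as_domain_totals <- function(t) {
  req <- c("domain", "Na", "N1a", "N2a", "Ya", "Y1a", "Y2a", "Xa", "X1a", "X2a")
  if (!all(req %in% names(t))) {
    stop("domain totals need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  t <- as.data.frame(t)[req]
  rownames(t) <- NULL
  class(t) <- c("domain_totals", "data.frame")
  t
}

#' Domain totals of the Swedish municipality reference population
#'
#' Published domain totals for a finite population of 203 Swedish
#' municipalities grouped into six geographic domains, split into respondent
#' and non-respondent strata (about 30\% non-respondents per domain).
#' `y` is the number of municipal employees in 1984; `x` the real estate
#' value according to the 1984 assessment (millions of kronor).  Only these
#' totals are published, not the unit-level values; [generate_population()]
#' can build a synthetic population matching them via `target_totals`.
#'
#' @return A `domain_totals` data frame with six rows.
#' @examples
#' tot <- swedish_totals()
#' sum(tot$Na)   # 203
#' @export
swedish_totals <- function() {
  path <- system.file("extdata", "swedish_domain_totals.csv",
                      package = "domcalib", mustWork = TRUE)
  read_domain_totals(path)
}

#' Validate domain totals
#'
#' Checks the internal consistency of a `domain_totals` table: stratum unit
#' counts must sum exactly to the domain count, and stratum value totals must
#' sum to the domain total within `tol` (0.5 by default, the slack a printed,
#' rounded table needs; computed totals satisfy the identities exactly).
#'
#' @param t a `domain_totals` data frame.
#' @param tol absolute tolerance for the value-total identities.
#' @return A data frame of violations (`domain`, `check`, `discrepancy`);
#'   zero rows when the table is consistent.  Reports, never raises.
#' @export
validate_totals <- function(t, tol = 0.5) {
  t <- as_domain_totals(t)
  bad <- list()
  flag <- function(domain, check, discrepancy) {
    bad[[length(bad) + 1L]] <<- data.frame(domain = domain, check = check,
                                           discrepancy = discrepancy)
  }
  for (i in seq_len(nrow(t))) {
    r <- t[i, ]
    if (r$Na != r$N1a + r$N2a) flag(r$domain, "Na != N1a + N2a", r$Na - r$N1a - r$N2a)
    dy <- r$Ya - (r$Y1a + r$Y2a)
    if (abs(dy) > tol) flag(r$domain, "|Ya - (Y1a + Y2a)| > tol", dy)
    dx <- r$Xa - (r$X1a + r$X2a)
    if (abs(dx) > tol) flag(r$domain, "|Xa - (X1a + X2a)| > tol", dx)
    if (any(unlist(r[c("Na", "N1a", "N2a")]) < 0)) flag(r$domain, "negative count", NA_real_)
    if (r$Xa <= 0 || r$X1a <= 0) flag(r$domain, "non-positive auxiliary total", NA_real_)
  }
  if (length(bad) == 0L) {
    data.frame(domain = integer(0), check = character(0), discrepancy = numeric(0))
  } else {
    do.call(rbind, bad)
  }
}

#' Read or write unit-level population frames as CSV
#'
#' The dialect is `unit_id,domain,y,x,stratum` with `stratum` in `{R, NR}`,
#' UTF-8, "." as decimal separator.
#'
#' @param path file path.
#' @param frame a `population_frame`.
#' @return `read_population()` returns a `population_frame`;
#'   `write_population()` returns `path` invisibly.
#' @export
read_population <- function(path) {
  frame <- read.csv(path, stringsAsFactors = FALSE)
  as_population_frame(frame)
}

#' @rdname read_population
#' @export
write_population <- function(frame, path) {
  frame <- as_population_frame(frame)
  write.csv(as.data.frame(frame), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write domain totals as CSV
#'
#' The dialect is `domain,Na,N1a,N2a,Ya,Y1a,Y2a,Xa,X1a,X2a`.
#'
#' @param path file path.
#' @param t a `domain_totals` data frame.
#' @return `read_domain_totals()` returns a `domain_totals` data frame;
#'   `write_domain_totals()` returns `path` invisibly.
#' @export
read_domain_totals <- function(path) {
  as_domain_totals(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_domain_totals
#' @export
write_domain_totals <- function(t, path) {
  t <- as_domain_totals(t)
  out <- as.data.frame(lapply(t, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
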