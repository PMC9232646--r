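# Phenotype computations: specific growth rates from OD measurements,
# phenotype-microarray maximum curve height classification with control
# based exclusion rules, and mitotic (segregational) stability.

#' Specific growth rate between two OD readings
#'
#' `U = ln(x / x0) / t`, the per-hour specific growth rate between an
#' initial optical density `x0` and a later reading `x` taken `t`
#' hours apart.
#'
#' @param x0 Initial OD (> 0).
#' @param x Later OD (> 0).
#' @param t Elapsed time in hours (> 0).
#' @return Growth rate in 1/h.
#' @export
specific_growth_rate <- function(x0, x, t) {
  if (any(x0 <= 0) || any(x <= 0) || any(t <= 0))
    stop("x0, x and t must all be positive")
  log(x / x0) / t
}

#' Maximum specific growth rate of a growth curve
#'
#' Slides a window along the curve and takes the maximum over windows
#' of the least-squares slope of `ln(OD)` versus time — the steepest
#' sustained exponential phase.
#'
#' @param times Strictly increasing times in hours.
#' @param od OD values (> 0 required inside fitted windows).
#' @param window Points per window (default 5).
#' @return Maximum specific growth rate in 1/h.
#' @export
max_specific_growth_rate <- function(times, od, window = 5L) {
  n <- length(times)
  if (length(od) != n) stop("times and od must have equal length")
  if (n < window) stop("need at least ", window, " points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od <= 0)) stop("od must be positive for log-linear fitting")
  y <- log(od)
  best <- -Inf
  for (i in seq_len(n - window + 1L)) {
    idx <- seq(i, i + window - 1L)
    tt <- times[idx]; yy <- y[idx]
    slope <- stats::cov(tt, yy) / stats::var(tt)
    if (slope > best) best <- slope
  }
  best
}

#' Maximum curve height of a kinetic series
#'
#' The plateau statistic used to summarize phenotype-microarray
#' respiration curves: the maximum of the series after 5-point rolling
#' median smoothing (so single-point spikes do not register).
#'
#' @param values Kinetic readings (>= 5 points).
#' @param k Rolling-median window (odd, default 5).
#' @return Maximum smoothed value `A`.
#' @export
max_curve_height <- function(values, k = 5L) {
  if (length(values) < k) stop("need at least ", k, " points")
  max(stats::runmed(values, k))
}

#' Classify compounds from paired phenotype-microarray plates
#'
#' Per compound well, computes the maximum curve height `A` for the
#' test and reference strains and the `log2(A_test / A_reference)`
#' ratio. A well is excluded when either strain fails to exceed its
#' plate's negative-control height by at least `delta` units (A >=
#' A_neg + delta passes) or when a plate's positive control stays
#' below `pos_min` units. Remaining wells are `increased` when the
#' log2 ratio is >= `threshold`, `decreased` when <= `-threshold`,
#' otherwise `unchanged`.
#'
#' @param test,reference Tidy plate data frames (columns `well`,
#'   `role`, `compound`, `time`, `value`) with matching layouts, e.g.
#'   from [generate_biolog_experiment()].
#' @param delta Negative-control margin in units (default 50).
#' @param pos_min Minimum positive-control height (default 100).
#' @param threshold log2 fold-change threshold (default 1, i.e.
#'   two-fold).
#' @return A `biolog_classification` data frame: per compound `A_test`,
#'   `A_reference`, `log2_ratio` (NA when excluded), `status`.
#' @export
biolog_classify <- function(test, reference, delta = 50, pos_min = 100,
                            threshold = 1) {
  key <- function(df) df[!duplicated(df$well), c("well", "role")]
  kt <- key(test); kr <- key(reference)
  if (!identical(kt[order(kt$well), ], kr[order(kr$well), ]))
    stop("test and reference plate layouts do not match")
  heights <- function(df) {
    wells <- unique(df$well)
    vapply(wells, function(w)
      max_curve_height(df$value[df$well == w][order(df$time[df$well == w])]),
      numeric(1))
  }
  a_test <- heights(test); a_ref <- heights(reference)
  roles <- stats::setNames(kt$role, kt$well)
  neg <- names(roles)[roles == "negative"]
  pos <- names(roles)[roles == "positive"]
  if (length(neg) != 1L || length(pos) != 1L)
    stop("plates must carry exactly one negative and one positive control")
  plate_fail <- a_test[[pos]] < pos_min || a_ref[[pos]] < pos_min
  wells <- names(roles)[roles == "compound"]
  compounds <- stats::setNames(test$compound[!duplicated(test$well)],
                               test$well[!duplicated(test$well)])[wells]
  out <- do.call(rbind, lapply(wells, function(w) {
    at <- a_test[[w]]; ar <- a_ref[[w]]
    excluded <- plate_fail ||
      at < a_test[[neg]] + delta || ar < a_ref[[neg]] + delta
    lr <- if (excluded) NA_real_ else log2(at / ar)
    status <- if (excluded) "excluded"
              else if (lr >= threshold) "increased"
              else if (lr <= -threshold) "decreased"
              else "unchanged"
    data.frame(well = w, compound = compounds[[w]], A_test = at,
               A_reference = ar, log2_ratio = lr, status = status,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("biolog_classification", "data.frame")
  out
}

#' Retention statistics of a stability experiment
#'
#' Per sampled generation: replicate retention proportions, their mean
#' and sample (n - 1) standard deviation in percent, and exact
#' Clopper-Pearson 95% binomial intervals per replicate.
#'
#' @param exp A `stability_experiment` data frame (`replicate`,
#'   `generation`, `resistant`, `total`).
#' @return List with `per_generation` (generation, mean_pct, sd_pct,
#'   n_replicates) and `per_replicate` (adds proportion and CI bounds).
#' @export
retention_stats <- function(exp) {
  if (nrow(exp) == 0L) stop("need at least one replicate")
  if (any(exp$total <= 0)) stop("n_total must be positive")
  if (any(exp$resistant < 0 | exp$resistant > exp$total))
    stop("resistant counts must lie in [0, total]")
  per_rep <- exp
  per_rep$proportion <- exp$resistant / exp$total
  ci <- t(vapply(seq_len(nrow(exp)), function(i)
    stats::binom.test(exp$resistant[i], exp$total[i])$conf.int,
    numeric(2)))
  per_rep$ci_lower <- ci[, 1]
  per_rep$ci_upper <- ci[, 2]
  gens <- sort(unique(exp$generation))
  per_gen <- do.call(rbind, lapply(gens, function(g) {
    p <- per_rep$proportion[per_rep$generation == g]
    data.frame(generation = g, mean_pct = 100 * mean(p),
               sd_pct = 100 * stats::sd(p), n_replicates = length(p))
  }))
  structure(list(per_generation = per_gen, per_replicate = per_rep),
            class = "retention_stats")
}

#' @export
print.retention_stats <- function(x, ...) {
  for (i in seq_len(nrow(x$per_generation))) {
    r <- x$per_generation[i, ]
    cat(sprintf("generation %d: %.1f +/- %.1f%% retention (n = %d)\n",
                r$generation, r$mean_pct, r$sd_pct, r$n_replicates))
  }
  invisible(x)
}

#' Per-generation loss rate from observed retention
#'
#' Inverts the geometric retention model `R = (1 - p)^g`:
#' `p = 1 - R^(1/g)`.
#'
#' @param retention Retained fraction `R` in (0, 1].
#' @param generations Elapsed generations `g` (> 0).
#' @return Per-generation loss probability.
#' @export
estimate_loss_rate <- function(retention, generations) {
  if (any(generations <= 0)) stop("generations must be positive")
  if (any(retention > 1)) stop("retention must be <= 1")
  if (any(retention <= 0))
    stop("retention of 0 leaves the loss rate unidentifiable ",
         "(report as a lower bound instead)")
  1 - retention^(1 / generations)
}
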