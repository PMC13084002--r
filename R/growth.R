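#' Construct an OD600 growth curve
#'
#' @param times Minutes from stress addition (may be negative pre-stress),
#'   strictly increasing.
#' @param od Optical density at 600 nm (> 0).
#' @param strain,replicate Labels.
#' @param treated Logical: was the stressor added at t = 0?
#' @return An object of class `od_curve` (a data.frame with attributes).
#' @export
od_curve <- function(times, od, strain = "WT", replicate = "r1",
                     treated = TRUE) {
  stopifnot(length(times) == length(od), length(times) >= 2)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(od <= 0)) stop("od must be positive")
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    warning("irregular sampling interval (15-min spacing is typical)")
  structure(data.frame(time_min = times, od = od),
            strain = strain, replicate = replicate, treated = treated,
            class = c("od_curve", "data.frame"))
}

#' Fit an exponential growth rate to an OD600 window
#'
#' Ordinary least squares of `ln(OD)` against time within the closed window,
#' the standard log-linear estimate of the exponential rate. The default
#' window, 75-225 min after stress addition, skips the acute acclimation lag
#' and captures the resumed exponential phase.
#'
#' @param curve An [od_curve()].
#' @param window Length-2 numeric, closed window in minutes.
#' @return List of class `growth_rate_fit`: `rate` (per minute), `window`,
#'   `r_squared`, `n_points`.
#' @export
fit_growth_rate <- function(curve, window = c(75, 225)) {
  stopifnot(inherits(curve, "od_curve"), length(window) == 2)
  sel <- curve$time_min >= window[1] & curve$time_min <= window[2]
  if (sum(sel) < 4)
    stop("insufficient data: need >= 4 points in [", window[1], ", ",
         window[2], "] min, found ", sum(sel))
  fit <- stats::lm(log(od) ~ time_min, data = curve[sel, ])
  # noiseless synthetic curves fit perfectly; the summary warning is noise
  s <- suppressWarnings(summary(fit))
  structure(list(rate = unname(stats::coef(fit)[2]),
                 window = window,
                 r_squared = s$r.squared,
                 n_points = sum(sel)),
            class = "growth_rate_fit")
}

#' Scale mutant growth rates to their paired wild-type
#'
#' Each mutant post-stress rate is divided by the same-replicate wild-type
#' post-stress rate, then multiplied by the mean wild-type post- versus
#' pre-stress relative rate, yielding a dimensionless rate comparable across
#' days.
#'
#' @param mutant_rates Mutant post-stress rates, one per replicate.
#' @param paired_wt_post Same-day wild-type post-stress rates.
#' @param wt_pre,wt_post Wild-type pre- and post-stress rates used for the
#'   average post/pre scaling factor.
#' @return Numeric vector of scaled rates, same length as `mutant_rates`.
#' @export
scale_rates <- function(mutant_rates, paired_wt_post, wt_pre, wt_post) {
  if (length(mutant_rates) != length(paired_wt_post))
    stop("mutant_rates and paired_wt_post must be replicate-paired ",
         "(equal length)")
  if (length(wt_pre) != length(wt_post))
    stop("wt_pre and wt_post must be replicate-paired (equal length)")
  bad <- which(paired_wt_post == 0)
  if (length(bad))
    stop("zero wild-type rate in replicate(s): ",
         paste(bad, collapse = ", "))
  if (any(wt_pre == 0)) stop("zero wild-type pre-stress rate")
  (mutant_rates / paired_wt_post) * mean(wt_post / wt_pre)
}

#' Percent change in cell density over a short span
#'
#' Acclimation-lag metric: the percent change in OD from t = 0 to t = `span`
#' minutes (default 60), with linear interpolation of OD to the exact
#' endpoints. Cultures that pause growth after stress score lower than
#' cultures with the same eventual rate but no pause.
#'
#' @param curve An [od_curve()] covering `[0, span]`.
#' @param span Minutes (default 60).
#' @return Percent change, a single number.
#' @export
percent_change_lag <- function(curve, span = 60) {
  stopifnot(inherits(curve, "od_curve"), span > 0)
  if (min(curve$time_min) > 0 || max(curve$time_min) < span)
    stop("curve must cover [0, ", span, "] min")
  od0 <- stats::approx(curve$time_min, curve$od, xout = 0)$y
  od1 <- stats::approx(curve$time_min, curve$od, xout = span)$y
  100 * (od1 - od0) / od0
}

#' Ordinal viability score for one survival fraction
#'
#' Four-point visual scale used to grade colony viability at one peroxide
#' dose: complete survival scores 3, majority survival 2, minority survival
#' 1, no survivors 0. Bin edges are closed below: `f >= 0.995 -> 3`;
#' `0.5 <= f < 0.995 -> 2`; `0.1 <= f < 0.5 -> 1`; `f < 0.1 -> 0` (a plated
#' spot visually indistinguishable from complete survival is read as 100%).
#'
#' @param fraction Survival fraction(s) in \[0, 1\], relative to the
#'   no-peroxide control.
#' @return Integer score(s) in 0-3.
#' @export
score_viability <- function(fraction) {
  if (any(is.na(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("survival fraction must lie in [0, 1]")
  ifelse(fraction >= 0.995, 3L,
         ifelse(fraction >= 0.5, 2L,
                ifelse(fraction >= 0.1, 1L, 0L)))
}

#' Construct a viability panel
#'
#' Survival fractions over an ordered peroxide dose series, one row per
#' pretreatment time. Fractions are relative to the zero-dose control.
#'
#' @param pretreat_times Minutes of mild-stress pretreatment (first entry
#'   must be 0, the untreated baseline).
#' @param doses Ordered nonzero H2O2 doses (mM); 11 doses spanning 0-20 mM is
#'   the standard design (the zero dose is the reference, not scored).
#' @param survival Matrix `length(pretreat_times) x length(doses)` of
#'   survival fractions in \[0, 1\].
#' @param strain,replicate Labels.
#' @return Object of class `viability_panel`.
#' @export
viability_panel <- function(pretreat_times, doses, survival,
                            strain = "WT", replicate = "r1") {
  survival <- as.matrix(survival)
  stopifnot(nrow(survival) == length(pretreat_times),
            ncol(survival) == length(doses))
  if (is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly increasing")
  if (!any(pretreat_times == 0))
    stop("pretreat_times must include the time-0 baseline")
  if (any(is.na(survival)) || any(survival < 0) || any(survival > 1))
    stop("survival fractions must lie in [0, 1]")
  structure(list(pretreat_times = pretreat_times, doses = doses,
                 survival = survival, strain = strain,
                 replicate = replicate),
            class = "viability_panel")
}

#' Acquired-stress-resistance survival score
#'
#' For each pretreatment time, sums the ordinal [score_viability()] grade
#' over the dose series (maximum 33 for the standard 11-dose design) and
#' reports the change relative to the unstressed time-0 aliquot of the same
#' panel.
#'
#' @param panel A [viability_panel()].
#' @return Object of class `survival_score_series`: data.frame with
#'   `pretreat_time`, `score`, `delta_score`.
#' @export
survival_score <- function(panel) {
  stopifnot(inherits(panel, "viability_panel"))
  scores <- apply(panel$survival, 1L, function(row)
    sum(score_viability(row)))
  baseline <- scores[panel$pretreat_times == 0][1L]
  structure(data.frame(pretreat_time = panel$pretreat_times,
                       score = as.integer(scores),
                       delta_score = as.integer(scores - baseline)),
            strain = panel$strain, replicate = panel$replicate,
            max_score = 3L * length(panel$doses),
            class = c("survival_score_series", "data.frame"))
}

#' Replicate-aware group comparison
#'
#' Thin dispatcher over the standard tests used throughout:
#' replicate-paired t tests (two-sided, or one-sided with a declared
#' direction) and the Wilcoxon rank-sum test (exact when both samples have
#' n <= 25 and no ties).
#'
#' @param a,b Numeric samples; paired modes require equal length.
#' @param mode One of `"paired_t_two_sided"`, `"paired_t_one_sided"`,
#'   `"wilcoxon_rank_sum"`.
#' @param alternative For the one-sided paired t test: direction of the
#'   alternative for `a` relative to `b` (`"less"` or `"greater"`); must be
#'   declared explicitly.
#' @return List with `p_value`, `statistic`, `mode`.
#' @export
compare_groups <- function(a, b,
                           mode = c("paired_t_two_sided",
                                    "paired_t_one_sided",
                                    "wilcoxon_rank_sum"),
                           alternative = NULL) {
  mode <- match.arg(mode)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group")
  # zero-variance paired differences make t.test error; a uniformly zero
  # difference carries no evidence against H0
  degenerate_pair <- function() {
    d <- a - b
    if (stats::sd(d) == 0 && mean(d) == 0)
      list(p.value = 1, statistic = 0)
    else NULL
  }
  res <- switch(mode,
    paired_t_two_sided = {
      if (length(a) != length(b)) stop("paired test requires equal lengths")
      degenerate_pair() %||%
        stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
    },
    paired_t_one_sided = {
      if (length(a) != length(b)) stop("paired test requires equal lengths")
      if (is.null(alternative) ||
          !alternative %in% c("less", "greater"))
        stop("one-sided mode requires alternative = 'less' or 'greater'")
      degenerate_pair() %||%
        stats::t.test(a, b, paired = TRUE, alternative = alternative)
    },
    wilcoxon_rank_sum = {
      exact <- length(a) <= 25 && length(b) <= 25 &&
        !any(duplicated(c(a, b)))
      stats::wilcox.test(a, b, exact = exact)
    })
  list(p_value = unname(res$p.value),
       statistic = unname(res$statistic),
       mode = mode)
}

#' @export
print.growth_rate_fit <- function(x, ...) {
  cat(sprintf("Growth rate %.5g /min over [%g, %g] min (R^2 = %.4f, n = %d)\n",
              x$rate, x$window[1], x$window[2], x$r_squared, x$n_points))
  invisible(x)
}
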