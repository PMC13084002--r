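#' Competition-model parameters
#'
#' Bundle and validate the parameters of the piecewise Lotka-Volterra
#' two-strain competition model: a wild-type strain that mounts a full stress
#' response (and therefore grows more slowly in the chronic single-stress
#' condition, but survives severe secondary stress) competing against a
#' stress-response null mutant that grows faster but is killed by each
#' secondary-stress event.
#'
#' Each stress cycle of period `stress_period` (omega) opens with a severe
#' stress window of duration `(1 - growth_fraction) * stress_period` during
#' which wild-type counts are frozen and the mutant dies at rate `death_rate`,
#' followed by a growth window with logistic competition toward a shared
#' carrying capacity.
#'
#' @param r_wt Per-unit-time exponential growth rate of the wild-type.
#' @param r_null Per-unit-time growth rate of the mutant (default 1, which
#'   makes time units the mutant's inverse growth rate).
#' @param carrying_capacity Shared carrying capacity `K` (cells).
#' @param stress_period Time `omega` between successive secondary-stress
#'   onsets.
#' @param growth_fraction Fraction `phi` in (0, 1] of each cycle spent in the
#'   growth window; `1 - phi` of the cycle is severe stress.
#' @param death_rate Per-unit-time death rate `D` applied to the mutant during
#'   the stress window (wild-type death is neglected).
#' @return An object of class `competition_params`.
#' @seealso [reduce_params()], [simulate_competition()]
#' @export
competition_params <- function(r_wt, r_null = 1, carrying_capacity = 1e7,
                               stress_period, growth_fraction, death_rate) {
  stopifnot(is.numeric(r_wt), length(r_wt) == 1L, r_wt >= 0,
            is.numeric(r_null), length(r_null) == 1L, r_null >= 0,
            is.numeric(death_rate), length(death_rate) == 1L, death_rate >= 0)
  if (!(is.numeric(carrying_capacity) && carrying_capacity > 0))
    stop("carrying_capacity must be > 0")
  if (!(is.numeric(stress_period) && stress_period > 0))
    stop("stress_period must be > 0")
  if (!(is.numeric(growth_fraction) && growth_fraction > 0 &&
        growth_fraction <= 1))
    stop("growth_fraction must lie in (0, 1]")
  structure(
    list(r_wt = r_wt, r_null = r_null,
         carrying_capacity = carrying_capacity,
         stress_period = stress_period,
         growth_fraction = growth_fraction,
         death_rate = death_rate),
    class = "competition_params")
}

#' Reduce competition parameters to the dimensionless triple
#'
#' Reparametrizes the full model into three dimensionless quantities that
#' fully determine the competitive outcome: the relative fitness
#' `alpha = r_wt / r_null`, the time between secondary stresses expressed in
#' uninhibited (mutant) doubling times
#' `beta = stress_period * growth_fraction * r_null / ln 2`, and the mutant
#' mortality per stress event
#' `m = 1 - exp(-death_rate * (1 - growth_fraction) * stress_period)`.
#'
#' `beta` counts the growth window only: it is the growth time available to
#' the mutant between kill events, normalized by the mutant doubling time
#' `ln 2 / r_null`.
#'
#' @param p A [competition_params()] object.
#' @return An object of class `reduced_params` with fields `alpha`, `beta`,
#'   `death_fraction`.
#' @export
reduce_params <- function(p) {
  stopifnot(inherits(p, "competition_params"))
  if (p$r_null == 0)
    stop("relative fitness undefined: mutant growth rate r_null is 0")
  growth_time <- p$growth_fraction * p$stress_period
  stress_time <- (1 - p$growth_fraction) * p$stress_period
  reduced_params(
    alpha = p$r_wt / p$r_null,
    beta = growth_time * p$r_null / log(2),
    death_fraction = 1 - exp(-p$death_rate * stress_time))
}

#' Dimensionless competition parameters
#'
#' @param alpha Relative fitness `r_wt / r_null` (> 0).
#' @param beta Time between secondary stresses in mutant doubling-time
#'   equivalents (> 0).
#' @param death_fraction Fraction `m` of mutant cells killed per stress event,
#'   in \[0, 1).
#' @return An object of class `reduced_params`.
#' @export
reduced_params <- function(alpha, beta, death_fraction) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0))
    stop("alpha must be > 0")
  if (!(is.numeric(beta) && length(beta) == 1L && beta > 0))
    stop("beta must be > 0")
  if (!(is.numeric(death_fraction) && length(death_fraction) == 1L &&
        death_fraction >= 0 && death_fraction < 1))
    stop("death_fraction must lie in [0, 1)")
  structure(list(alpha = alpha, beta = beta,
                 death_fraction = death_fraction),
            class = "reduced_params")
}

# State III threshold: critical starting N_WT/N_Null above which wild-type
# outcompetes the mutant. Decreasing in m, increasing in beta (for alpha < 1).
# m = 0 gives +Inf when alpha < 1 (wild-type can never win without killing).
threshold_ratio <- function(alpha, beta, m) {
  if (m == 0) {
    if (alpha < 1) return(Inf)
    return(-1 / alpha)  # limit of the formula as m -> 0+ is -Inf*0 form; see below
  }
  ((1 - 1 / alpha) * beta * log(2)) / log(1 - m) - 1 / alpha
}

#' Classify the phase state of the competition
#'
#' Assigns one of three analytically derived regimes:
#' * `MUTANT_NONVIABLE` (state I): per-event killing exceeds what mutant
#'   growth between events can replace (`m > 1 - 2^-beta`); the mutant dies
#'   out regardless of competition.
#' * `WT_ALWAYS_WINS` (state II): the mutant is viable but the wild-type
#'   outcompetes it from any starting proportion
#'   (`m > 1 - exp((alpha - 1) beta ln 2)`).
#' * `RATIO_DEPENDENT` (state III): the winner depends on the starting
#'   wild-type:mutant ratio; the critical ratio is returned as
#'   `threshold_ratio`.
#'
#' @param rp A [reduced_params()] object.
#' @return An object of class `phase_state`: list with `label` and, for state
#'   III, `threshold_ratio` (the critical starting `N_WT / N_Null`; `Inf`
#'   when `m = 0` and `alpha < 1`).
#' @export
classify_state <- function(rp) {
  stopifnot(inherits(rp, "reduced_params"))
  m <- rp$death_fraction
  if (m >= 1) stop("death_fraction must be < 1")
  bound1 <- 1 - exp(-rp$beta * log(2))
  bound2 <- 1 - exp((rp$alpha - 1) * rp$beta * log(2))
  if (m > bound1) {
    st <- list(label = "MUTANT_NONVIABLE", threshold_ratio = NULL)
  } else if (m > bound2) {
    st <- list(label = "WT_ALWAYS_WINS", threshold_ratio = NULL)
  } else {
    st <- list(label = "RATIO_DEPENDENT",
               threshold_ratio = threshold_ratio(rp$alpha, rp$beta, m))
  }
  structure(st, class = "phase_state")
}

#' Minimal per-event death fraction for wild-type dominance
#'
#' Finds the smallest per-event mutant death fraction `m` at which a
#' population started at `start_ratio` (wild-type : mutant) ends in wild-type
#' dominance, i.e. the root of `threshold_ratio(m) = start_ratio`. The
#' threshold is strictly decreasing in `m`, from `+Inf` at `m = 0` down to
#' `-1` at the mutant-nonviability bound, so a unique root exists in
#' `(0, 1 - 2^-beta)` for any positive starting ratio when `alpha < 1`.
#'
#' Solved by bisection (via [stats::uniroot()]) to `|dm| < 1e-6`.
#'
#' @param alpha Relative fitness in (0, 1).
#' @param beta Doubling-time equivalents between stresses (> 0).
#' @param start_ratio Starting `N_WT / N_Null` (> 0).
#' @param tol Absolute tolerance on `m`.
#' @return The critical death fraction, a single number in (0, 1).
#' @export
critical_death_fraction <- function(alpha, beta, start_ratio, tol = 1e-6) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, start_ratio > 0)
  bound1 <- 1 - exp(-beta * log(2))
  lo <- 1e-9
  hi <- bound1 - 1e-9
  f <- function(m) threshold_ratio(alpha, beta, m) - start_ratio
  if (f(lo) < 0) return(lo)  # even negligible killing suffices
  if (f(hi) > 0)
    stop("wild-type cannot dominate at any sublethal death fraction ",
         "for this starting ratio")
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Simulate the piecewise competition model
#'
#' Integrates the two-strain model cycle by cycle. Each cycle of length
#' `omega` opens with a stress window of length `(1 - phi) omega` solved by
#' its exact linear solution (wild-type frozen, mutant exponential decay at
#' rate `D`), then a growth window of length `phi omega` with logistic
#' competition `dN_i/dt = r_i N_i (1 - (N_wt + N_null)/K)` integrated with an
#' adaptive stiff-capable solver (lsoda; relative tolerance 1e-8, absolute
#' tolerance `1e-10 K`). Phase switches are hard boundaries: the solver never
#' steps across one.
#'
#' @param p A [competition_params()] object.
#' @param init Named list or vector with starting counts `n_wt`, `n_null`
#'   (both >= 0). Default splits `0.05 K` equally.
#' @param n_cycles Number of stress cycles to simulate (>= 1).
#' @param samples_per_phase Output samples per phase window.
#' @return An object of class `competition_trajectory`: list with `states`
#'   (data.frame `t`, `n_wt`, `n_null`), `cycle_log_ratio_changes` (per-cycle
#'   change in `ln(n_wt/n_null)`), and `params`.
#' @export
simulate_competition <- function(p, init = NULL, n_cycles,
                                 samples_per_phase = 10L) {
  stopifnot(inherits(p, "competition_params"), n_cycles >= 1)
  K <- p$carrying_capacity
  if (is.null(init)) init <- c(n_wt = 0.025 * K, n_null = 0.025 * K)
  init <- unlist(init)[c("n_wt", "n_null")]
  if (any(is.na(init)) || any(init < 0))
    stop("init must supply nonnegative n_wt and n_null")

  omega <- p$stress_period
  t_stress <- (1 - p$growth_fraction) * omega
  t_growth <- p$growth_fraction * omega

  logistic <- function(t, y, parms) {
    crowd <- 1 - (y[1] + y[2]) / K
    list(c(p$r_wt * y[1] * crowd, p$r_null * y[2] * crowd))
  }

  state <- init
  t0 <- 0
  out <- list(data.frame(t = 0, n_wt = state[[1]], n_null = state[[2]]))
  dlog <- numeric(n_cycles)
  for (cyc in seq_len(n_cycles)) {
    lr0 <- log(state[[1]]) - log(state[[2]])
    # stress window: exact solution of the linear phase
    if (t_stress > 0) {
      ts <- seq(0, t_stress, length.out = samples_per_phase + 1L)[-1L]
      seg <- data.frame(t = t0 + ts,
                        n_wt = rep(state[[1]], length(ts)),
                        n_null = state[[2]] * exp(-p$death_rate * ts))
      out[[length(out) + 1L]] <- seg
      state <- c(n_wt = seg$n_wt[nrow(seg)], n_null = seg$n_null[nrow(seg)])
      t0 <- t0 + t_stress
    }
    # growth window: adaptive integration, never stepping across the switch
    ts <- seq(0, t_growth, length.out = samples_per_phase + 1L)
    sol <- deSolve::ode(y = state, times = ts, func = logistic, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10 * K)
    if (attr(sol, "istate")[1L] < 0)
      stop("ODE solver failed in growth window of cycle ", cyc)
    seg <- as.data.frame(sol[-1L, , drop = FALSE])
    names(seg) <- c("t", "n_wt", "n_null")
    seg$t <- seg$t + t0
    seg$n_wt <- pmax(seg$n_wt, 0)
    seg$n_null <- pmax(seg$n_null, 0)
    out[[length(out) + 1L]] <- seg
    state <- c(n_wt = seg$n_wt[nrow(seg)], n_null = seg$n_null[nrow(seg)])
    t0 <- t0 + t_growth
    dlog[cyc] <- (log(state[[1]]) - log(state[[2]])) - lr0
  }
  structure(list(states = do.call(rbind, out),
                 cycle_log_ratio_changes = dlog,
                 params = p),
            class = "competition_trajectory")
}

#' Decide the winner of a simulated competition
#'
#' Operationalizes "outcompetes": the mutant is extinct if its count ever
#' falls below an extinction floor; otherwise the sign of the mean per-cycle
#' change in `ln(n_wt/n_null)` over the last quarter of cycles decides the
#' winner, with `COEXIST_FROZEN` when that mean is below tolerance (e.g. both
#' strains parked at carrying capacity with no killing).
#'
#' @param traj A [simulate_competition()] trajectory spanning >= 10 cycles.
#' @param extinction_floor Mutant count below which it is declared extinct
#'   (default `1e-9 K`).
#' @param tol Tolerance on the mean per-cycle log-ratio change.
#' @return One of `"WT"`, `"MUTANT"`, `"COEXIST_FROZEN"`, `"MUTANT_EXTINCT"`.
#' @export
winner <- function(traj, extinction_floor = NULL, tol = 1e-6) {
  stopifnot(inherits(traj, "competition_trajectory"))
  n_cycles <- length(traj$cycle_log_ratio_changes)
  if (n_cycles < 10)
    stop("trajectory too short: need >= 10 cycles, got ", n_cycles)
  K <- traj$params$carrying_capacity
  if (is.null(extinction_floor)) extinction_floor <- 1e-9 * K
  if (min(traj$states$n_null) < extinction_floor) return("MUTANT_EXTINCT")
  late <- traj$cycle_log_ratio_changes[
    seq.int(ceiling(0.75 * n_cycles) + 1L, n_cycles)]
  mu <- mean(late)
  if (abs(mu) < tol) "COEXIST_FROZEN" else if (mu > 0) "WT" else "MUTANT"
}

#' Phase-state map over a (beta, m) grid
#'
#' Evaluates [classify_state()] on the full grid and, for each requested
#' starting ratio, the dominance contour `m*(beta)` from
#' [critical_death_fraction()]: the per-event death fraction above which the
#' wild-type has the competitive advantage at that population makeup.
#'
#' @param alpha Relative fitness in (0, 1).
#' @param beta_grid Ascending grid of doubling-time equivalents.
#' @param m_grid Ascending grid of per-event death fractions in \[0, 1).
#' @param ratios Starting wild-type:mutant ratios for dominance contours.
#' @return List with `grid` (long data.frame: `beta`, `m`, `state`,
#'   `threshold_ratio`) and `contours` (data.frame: `ratio`, `beta`,
#'   `m_critical`).
#' @export
phase_map <- function(alpha, beta_grid, m_grid, ratios = c(1, 5, 25)) {
  stopifnot(alpha > 0, alpha < 1,
            length(beta_grid) > 0, !is.unsorted(beta_grid),
            length(m_grid) > 0, !is.unsorted(m_grid))
  grid <- expand.grid(beta = beta_grid, m = m_grid,
                      KEEP.OUT.ATTRS = FALSE)
  states <- lapply(seq_len(nrow(grid)), function(i) {
    classify_state(reduced_params(alpha, grid$beta[i], grid$m[i]))
  })
  grid$state <- vapply(states, `[[`, "", "label")
  grid$threshold_ratio <- vapply(states, function(s) {
    if (is.null(s$threshold_ratio)) NA_real_ else s$threshold_ratio
  }, 0)
  contours <- do.call(rbind, lapply(ratios, function(r) {
    data.frame(ratio = r, beta = beta_grid,
               m_critical = vapply(beta_grid, function(b)
                 critical_death_fraction(alpha, b, r), 0))
  }))
  list(grid = grid, contours = contours)
}

#' @export
print.phase_state <- function(x, ...) {
  cat("Phase state:", x$label, "\n")
  if (!is.null(x$threshold_ratio))
    cat("  critical starting WT:mutant ratio:",
        format(x$threshold_ratio, digits = 4), "\n")
  invisible(x)
}

#' @export
print.competition_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat("Competition trajectory:", length(x$cycle_log_ratio_changes),
      "cycles,", n, "samples\n")
  cat("  final n_wt =", format(x$states$n_wt[n], digits = 4),
      " n_null =", format(x$states$n_null[n], digits = 4), "\n")
  invisible(x)
}
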