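# Sinusoidal diel light profile, OD720 simulation and instantaneous
# specific growth-rate estimation.

#' Define a sinusoidal diel light profile
#'
#' Irradiance follows a half-sine during the photoperiod and is zero in the
#' dark phase; the profile repeats with `cycle_h`. Defaults reproduce a
#' 14 h : 10 h light-dark regime peaking at 600 umol photons m-2 s-1.
#'
#' @param peak peak irradiance (umol photons m-2 s-1; default 600).
#' @param dawn_h dawn time within the cycle (h; default 0).
#' @param photoperiod_h length of the light phase (h; default 14).
#' @param cycle_h cycle length (h; default 24).
#' @return An object of class `light_profile`.
#' @export
light_profile <- function(peak = 600, dawn_h = 0, photoperiod_h = 14,
                          cycle_h = 24) {
  if (peak <= 0) stop("peak irradiance must be > 0")
  if (photoperiod_h <= 0 || photoperiod_h >= cycle_h)
    stop("need 0 < photoperiod < cycle length")
  structure(list(peak = peak, dawn_h = dawn_h,
                 photoperiod_h = photoperiod_h, cycle_h = cycle_h),
            class = "light_profile")
}

#' @export
print.light_profile <- function(x, ...) {
  cat(sprintf("<light_profile> half-sine, peak %g, %g h light : %g h dark\n",
              x$peak, x$photoperiod_h, x$cycle_h - x$photoperiod_h))
  invisible(x)
}

#' Irradiance at time t
#'
#' `peak * sin(pi * (t - dawn) / photoperiod)` while `(t - dawn) mod cycle`
#' lies in the photoperiod, zero otherwise; continuous at dawn and dusk.
#' Vectorized over `t`.
#'
#' @param profile a `light_profile`.
#' @param t time in hours (>= 0).
#' @return Irradiance in the profile's units.
#' @export
irradiance <- function(profile, t) {
  phase <- (t - profile$dawn_h) %% profile$cycle_h
  ifelse(phase <= profile$photoperiod_h,
         profile$peak * sin(pi * phase / profile$photoperiod_h),
         0)
}

#' Simulate an OD720 growth curve under a diel light profile
#'
#' Integrates `d(OD)/dt = mu(t) * OD` with `mu(t) = mu_peak *
#' irradiance(t) / peak` by the classical fixed-step fourth-order
#' Runge-Kutta scheme. Optional dusk/dawn dips multiply the growth rate by
#' a factor `< 1` for `dip_width_h` hours after dawn and before dusk,
#' mimicking the transient OD declines seen at the light transitions (their
#' mechanism is left open; this is a phenomenological option, off by
#' default).
#'
#' @param profile a `light_profile`.
#' @param mu_peak peak specific growth rate (h-1).
#' @param od0 initial OD720 (> 0; default 0.1).
#' @param dt integration/reporting step (h; default 0.05).
#' @param horizon_h total simulated time (h; default 48).
#' @param dip_depth additive depression of mu during transition windows
#'   (h-1; default 0 = no dips). Positive values can drive mu negative.
#' @param dip_width_h width of each transition window (h; default 1.5).
#' @return A `growth_series`: data.frame with columns `time_h`, `od720`.
#' @export
simulate_od <- function(profile, mu_peak, od0 = 0.1, dt = 0.05,
                        horizon_h = 48, dip_depth = 0, dip_width_h = 1.5) {
  if (mu_peak < 0) stop("mu_peak must be >= 0")
  if (od0 <= 0) stop("od0 must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  mu_of <- function(t) {
    mu <- mu_peak * irradiance(profile, t) / profile$peak
    if (dip_depth != 0) {
      phase <- (t - profile$dawn_h) %% profile$cycle_h
      in_dip <- (phase >= 0 & phase <= dip_width_h) |
        (phase >= profile$photoperiod_h - dip_width_h &
           phase <= profile$photoperiod_h)
      mu <- mu - dip_depth * as.numeric(in_dip)
    }
    mu
  }
  times <- seq(0, horizon_h, by = dt)
  # d(ln OD)/dt = mu(t) is independent of OD, so RK4 reduces to Simpson
  # quadrature of mu over each step; integrate in log space for stability
  lod <- numeric(length(times))
  lod[1] <- log(od0)
  for (i in seq_len(length(times) - 1L)) {
    t0 <- times[i]
    k1 <- mu_of(t0)
    k2 <- mu_of(t0 + dt / 2)
    k4 <- mu_of(t0 + dt)
    lod[i + 1L] <- lod[i] + dt / 6 * (k1 + 4 * k2 + k4)
  }
  structure(data.frame(time_h = times, od720 = exp(lod)),
            class = c("growth_series", "data.frame"))
}

#' Instantaneous specific growth rate from an OD series
#'
#' Estimates `mu(t) = d ln(OD) / dt` by centered finite differences on
#' `ln(OD)` (one-sided at the endpoints), after optional moving-average
#' smoothing of `ln(OD)` over `window` points (`window = 1` disables
#' smoothing).
#'
#' @param series data.frame with columns `time_h` and `od720` (all OD > 0,
#'   times strictly increasing, at least 3 points).
#' @param window odd moving-average window in points (default 3).
#' @return data.frame with columns `time_h`, `mu` (h-1).
#' @export
instantaneous_mu <- function(series, window = 3L) {
  t <- series$time_h; od <- series$od720
  if (length(t) < 3L) stop("need at least 3 time points")
  if (any(od <= 0)) stop("OD values must be > 0")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  l <- log(od)
  if (window > 1L) {
    half <- (window - 1L) %/% 2L
    l <- vapply(seq_along(l), function(i) {
      lo <- max(1L, i - half); hi <- min(length(l), i + half)
      mean(l[lo:hi])
    }, numeric(1))
  }
  n <- length(l)
  mu <- numeric(n)
  mu[1] <- (l[2] - l[1]) / (t[2] - t[1])
  mu[n] <- (l[n] - l[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    mu[i] <- (l[i + 1] - l[i - 1]) / (t[i + 1] - t[i - 1])
  }
  data.frame(time_h = t, mu = mu)
}
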