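#' Rainfall regime
#'
#' Time-dependent precipitation forcing \eqn{R(t)} for a simulation.  Three
#' modes are supported: `"constant"` (\eqn{R(t) = R_0}), `"shift"` (a step
#' change from `R0` to `R1` at `t_shift`, emulating a sudden change of
#' climate), and `"sinusoid"` (\eqn{R(t) = R_0 + A \sin(2\pi t / period)},
#' emulating a yearly dry/rainy seasonality).
#'
#' @param mode One of `"constant"`, `"shift"`, `"sinusoid"`.
#' @param R0 Baseline precipitation (mm d\eqn{^{-1}}).
#' @param R1 Post-shift precipitation (mm d\eqn{^{-1}}; `"shift"` mode only).
#' @param t_shift Time of the step change (d; `"shift"` mode only).
#' @param amplitude Seasonal amplitude A (mm d\eqn{^{-1}}; `"sinusoid"` only).
#' @param period Seasonal period (d), default 365.
#'
#' @return An object of class `rainfall_regime`.
#' @seealso [rainfall_at()]
#' @export
#' @examples
#' r <- rainfall_regime("sinusoid", R0 = 1.3, amplitude = 0.45)
#' rainfall_at(r, c(0, 91.25, 182.5))
rainfall_regime <- function(mode = c("constant", "shift", "sinusoid"),
                            R0 = 1.3, R1 = NULL, t_shift = NULL,
                            amplitude = 0, period = 365) {
  mode <- match.arg(mode)
  if (!is.numeric(R0) || length(R0) != 1L || R0 < 0)
    stop("R0 must be a single non-negative number")
  if (mode == "shift") {
    if (is.null(R1) || is.null(t_shift))
      stop("shift mode requires R1 and t_shift")
    if (R1 < 0) stop("R1 must be non-negative")
  }
  if (mode == "sinusoid") {
    if (amplitude < 0) stop("amplitude must be non-negative")
    if (amplitude > R0)
      stop("sinusoidal rainfall would be negative: amplitude > R0")
  }
  structure(
    list(mode = mode, R0 = R0, R1 = if (mode == "shift") R1 else R0,
         t_shift = if (mode == "shift") t_shift else Inf,
         amplitude = if (mode == "sinusoid") amplitude else 0,
         period = period),
    class = "rainfall_regime")
}

#' Evaluate a rainfall regime
#'
#' @param regime A [rainfall_regime()].
#' @param t Time(s) in days (vectorized).
#' @return Precipitation R(t) in mm d\eqn{^{-1}}.
#' @export
rainfall_at <- function(regime, t) {
  stopifnot(inherits(regime, "rainfall_regime"))
  switch(regime$mode,
    constant = rep_len(regime$R0, length(t)),
    shift    = ifelse(t < regime$t_shift, regime$R0, regime$R1),
    sinusoid = regime$R0 + regime$amplitude * sin(2 * pi * t / regime$period))
}

#' @export
print.rainfall_regime <- function(x, ...) {
  cat("<rainfall_regime>", x$mode, "\n")
  cat("  R0 =", x$R0, "mm/d")
  if (x$mode == "shift") cat(", R1 =", x$R1, "at t =", x$t_shift, "d")
  if (x$mode == "sinusoid") cat(", amplitude =", x$amplitude,
                                "mm/d, period =", x$period, "d")
  cat("\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Builds a validated configuration object holding every model parameter,
#' the grid geometry, the rainfall forcing, the numerical settings and the
#' feature flags.  Defaults are the standard parameterization of the model
#' (see the package vignette for the meaning, units and provenance of each
#' parameter).
#'
#' @param b Water-to-biomass conversion rate (g mm\eqn{^{-1}} m\eqn{^2}).
#' @param g_max Maximum water uptake (mm\eqn{^{-1}} m\eqn{^2} g\eqn{^{-1}}
#'   d\eqn{^{-1}}).
#' @param k1 Half-saturation constant of growth and uptake (mm\eqn{^{-1}}
#'   m\eqn{^2}).
#' @param Kp Plant size limiting factor (g).
#' @param d Biomass turnover (senescence) rate (d\eqn{^{-1}}).
#' @param l Mean life expectancy (d).
#' @param d_b Death threshold as a fraction of the running biomass maximum
#'   (dimensionless, in (0, 1]).
#' @param m Age of reproductive maturity (d).
#' @param s Biomass-to-seedlings factor (seeds g\eqn{^{-1}} d\eqn{^{-1}}).
#' @param mu_disp Mean seed dispersal distance (m).
#' @param sigma_disp Lognormal dispersal kernel shape (log-scale sd).
#' @param K_a Maximum biomass density allowing seedling establishment
#'   (g m\eqn{^{-2}}).
#' @param rain A [rainfall_regime()].
#' @param alpha Maximum infiltration rate (g\eqn{^{-1}} d\eqn{^{-1}}).
#' @param k2 Infiltration saturation constant (g).
#' @param W0 Bare-soil relative infiltration rate (dimensionless).
#' @param r_w Soil water evaporation and drainage rate (d\eqn{^{-1}}).
#'   The default 0.2 is the value of the grid-hydrology lineage this model
#'   builds on; it places the bare-soil/vegetated transition inside the
#'   0.6-1.7 mm d\eqn{^{-1}} rainfall range studied here (see the methods
#'   vignette on this calibration).
#' @param D_O Surface water diffusion coefficient (m\eqn{^2} d\eqn{^{-1}}).
#' @param D_W Soil water diffusion coefficient (m\eqn{^2} d\eqn{^{-1}}).
#' @param dx Parcel side length (m).
#' @param nx,ny Number of parcels along x and y.
#' @param dt_event Discrete event time step (d).
#' @param dt_int RK4 integration sub-step (d); must divide `dt_event`.
#' @param T_end Simulation horizon (d).
#' @param seed Integer RNG seed (or `NULL` to leave the RNG alone).
#' @param age_mortality_enabled Apply the constant age hazard 1/`l`?
#' @param age_mortality_mode `"hazard"` (constant daily hazard 1/`l`, mean
#'   lifetime `l`) or `"cutoff"` (deterministic death at age `l`).
#' @param B_init_range Range of initial plant biomass (g).
#' @param preemptive_seedling_removal Reject seedlings whose instantaneous
#'   growth rate at establishment would be non-positive (a performance
#'   shortcut known to distort pattern formation; off by default).
#' @param boundary Water-diffusion boundary condition: `"zero-flux"`
#'   (reflecting, the default; the plot is a closed hydrological unit) or
#'   `"periodic"`.
#' @param infiltration_denominator `"biomass"` (default; saturating in the
#'   parcel biomass) or `"water"` (literal soil-water denominator variant,
#'   for sensitivity checks).
#' @param coupling `"cointegrated"` (plant and water ODEs share RK4
#'   sub-steps; default) or `"split"` (plants integrate against frozen W,
#'   then water against frozen biomass).
#' @param summary_every Interval (d) between rows of the output time series.
#' @param snapshot_every Interval (d) between full state snapshots (`Inf`
#'   for none beyond first and last).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(nx = 20, ny = 20, T_end = 10)
#' cfg$Kp
sim_config <- function(b = 10, g_max = 0.05, k1 = 3, Kp = 800, d = 0.3,
                       l = 365, d_b = 0.8, m = 0, s = 0.002,
                       mu_disp = 10, sigma_disp = 1.5, K_a = 30,
                       rain = rainfall_regime("constant", R0 = 1.3),
                       alpha = 0.1, k2 = 5, W0 = 0.15, r_w = 0.2,
                       D_O = 10, D_W = 0.01,
                       dx = 4, nx = 50, ny = 50,
                       dt_event = 0.2, dt_int = 0.02, T_end = 1825,
                       seed = NULL,
                       age_mortality_enabled = TRUE,
                       age_mortality_mode = c("hazard", "cutoff"),
                       B_init_range = c(1, 2),
                       preemptive_seedling_removal = FALSE,
                       boundary = c("zero-flux", "periodic"),
                       infiltration_denominator = c("biomass", "water"),
                       coupling = c("cointegrated", "split"),
                       summary_every = 1, snapshot_every = Inf) {
  cfg <- list(
    b = b, g_max = g_max, k1 = k1, Kp = Kp, d = d, l = l, d_b = d_b,
    m = m, s = s, mu_disp = mu_disp, sigma_disp = sigma_disp, K_a = K_a,
    rain = rain, alpha = alpha, k2 = k2, W0 = W0, r_w = r_w,
    D_O = D_O, D_W = D_W, dx = dx, nx = as.integer(nx), ny = as.integer(ny),
    dt_event = dt_event, dt_int = dt_int, T_end = T_end, seed = seed,
    age_mortality_enabled = isTRUE(age_mortality_enabled),
    age_mortality_mode = match.arg(age_mortality_mode),
    B_init_range = B_init_range,
    preemptive_seedling_removal = isTRUE(preemptive_seedling_removal),
    boundary = match.arg(boundary),
    infiltration_denominator = match.arg(infiltration_denominator),
    coupling = match.arg(coupling),
    summary_every = summary_every, snapshot_every = snapshot_every)
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks rate signs, threshold ranges, time-step compatibility and
#' non-negativity of the rainfall forcing over the whole horizon.  Called by
#' [sim_config()]; exported so externally assembled or file-loaded
#' configurations can be checked too.
#'
#' @param cfg A `sim_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rates <- c("b", "g_max", "k1", "Kp", "d", "l", "s", "mu_disp",
             "sigma_disp", "K_a", "alpha", "k2", "W0", "r_w",
             "D_O", "D_W", "dx", "m")
  for (nm in rates) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative number")
  }
  if (cfg$d_b <= 0 || cfg$d_b > 1) stop("d_b must lie in (0, 1]")
  if (cfg$nx < 1L || cfg$ny < 1L) stop("grid must have at least one parcel")
  if (cfg$dt_int <= 0 || cfg$dt_event <= 0)
    stop("time steps must be positive")
  if (cfg$dt_int > cfg$dt_event) stop("dt_int must not exceed dt_event")
  nsub <- cfg$dt_event / cfg$dt_int
  if (abs(nsub - round(nsub)) > 1e-8)
    stop("dt_int must divide dt_event evenly")
  nper <- 1 / cfg$dt_event
  if (abs(nper - round(nper)) > 1e-8)
    stop("dt_event must divide evenly into whole days")
  if (length(cfg$B_init_range) != 2L ||
      any(cfg$B_init_range < 0) ||
      cfg$B_init_range[1] > cfg$B_init_range[2])
    stop("B_init_range must be an increasing non-negative pair")
  if (cfg$T_end < 0) stop("T_end must be non-negative")
  ## rainfall must stay non-negative over the horizon
  tt <- seq(0, max(cfg$T_end, 1), length.out = 512L)
  if (any(rainfall_at(cfg$rain, tt) < 0))
    stop("rainfall regime is negative somewhere in [0, T_end]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  plot: %d x %d parcels of %g m (%g x %g m)\n",
              x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx))
  cat(sprintf("  rainfall: %s (R0 = %g mm/d)\n", x$rain$mode, x$rain$R0))
  cat(sprintf("  time: T_end = %g d, dt_event = %g d, dt_int = %g d\n",
              x$T_end, x$dt_event, x$dt_int))
  cat(sprintf("  plant: b=%g g_max=%g k1=%g Kp=%g d=%g l=%g d_b=%g m=%g\n",
              x$b, x$g_max, x$k1, x$Kp, x$d, x$l, x$d_b, x$m))
  cat(sprintf("  dispersal: s=%g mu=%g sigma=%g K_a=%g\n",
              x$s, x$mu_disp, x$sigma_disp, x$K_a))
  cat(sprintf("  soil: alpha=%g k2=%g W0=%g r_w=%g D_O=%g D_W=%g\n",
              x$alpha, x$k2, x$W0, x$r_w, x$D_O, x$D_W))
  invisible(x)
}

## flat key-value serialization used by the config file interface;
## rainfall fields are prefixed rain_*
config_to_flat <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), "rain")]
  flat$rain_mode <- cfg$rain$mode
  flat$rain_R0 <- cfg$rain$R0
  if (cfg$rain$mode == "shift") {
    flat$rain_R1 <- cfg$rain$R1
    flat$rain_t_shift <- cfg$rain$t_shift
  }
  if (cfg$rain$mode == "sinusoid") {
    flat$rain_amplitude <- cfg$rain$amplitude
    flat$rain_period <- cfg$rain$period
  }
  flat
}

flat_to_config <- function(flat) {
  rain <- rainfall_regime(
    mode = flat$rain_mode %||% "constant",
    R0 = flat$rain_R0 %||% 1.3,
    R1 = flat$rain_R1, t_shift = flat$rain_t_shift,
    amplitude = flat$rain_amplitude %||% 0,
    period = flat$rain_period %||% 365)
  flat <- flat[!grepl("^rain_", names(flat))]
  flat$rain <- rain
  do.call(sim_config, flat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a configuration file
#'
#' Configurations are stored as a flat YAML key-value file whose keys mirror
#' the [sim_config()] arguments (rainfall fields are prefixed `rain_`).
#'
#' @param path File path.
#' @param cfg A `sim_config`.
#' @return `read_config()` returns a validated `sim_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  flat_to_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write config files")
  flat <- config_to_flat(cfg)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}
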