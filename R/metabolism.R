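#' Instantaneous plant growth rate
#'
#' Right-hand side of the per-plant biomass ODE: water-limited logistic
#' growth minus constant turnover,
#' \deqn{\frac{dB}{dt} = B\,b\,g_{max}\left(1 - \frac{B}{K_p}\right)
#'   \frac{W}{W + k_1} - B\,d.}
#' Growth is Michaelis-Menten in the soil water of the plant's own parcel
#' (plants do not root beyond their parcel) and capped by the size limit
#' \eqn{K_p}; with no water the plant loses biomass at the turnover rate.
#'
#' @param B Plant biomass (g); vectorized.
#' @param W_local Soil water on the plant's parcel (mm); vectorized.
#' @param cfg A [sim_config()].
#' @return dB/dt (g d\eqn{^{-1}}).
#' @export
#' @examples
#' growth_rate(1, 3, sim_config())   # -0.0503125 at the default parameters
growth_rate <- function(B, W_local, cfg) {
  B * cfg$b * cfg$g_max * (1 - B / cfg$Kp) * W_local / (W_local + cfg$k1) -
    B * cfg$d
}

#' Per-plant water demand
#'
#' Soil-water depth drawn from the plant's parcel,
#' \eqn{g_{max} \frac{W}{W + k_1} B / dx^2}.  Linear in biomass, so the
#' demands of a parcel's plants sum exactly to the parcel uptake term of
#' the water dynamics ([uptake_field()]).  Note the asymmetry with
#' [growth_rate()]: water is drawn in proportion to raw biomass even when
#' growth is size-capped by \eqn{K_p}.
#'
#' @param B Plant biomass (g); vectorized.
#' @param W_local Soil water on the plant's parcel (mm); vectorized.
#' @param cfg A [sim_config()].
#' @return Water demand (mm d\eqn{^{-1}}).
#' @export
plant_water_demand <- function(B, W_local, cfg) {
  cfg$g_max * W_local / (W_local + cfg$k1) * B / cfg$dx^2
}

#' Advance plant biomasses over one event step (frozen soil water)
#'
#' Integrates each plant's biomass ODE by classical RK4 sub-steps of size
#' `cfg$dt_int`, holding the soil water of its parcel fixed.  This is the
#' "split" coupling metabolism half-step; the full simulation loop normally
#' co-integrates plants and water (see [run_simulation()]).  Running
#' biomass maxima are updated; no plant is created or destroyed.
#'
#' @param pop A [new_population()] table.
#' @param grid A `soil_grid`.
#' @param cfg A [sim_config()].
#' @param dt Step length (d); defaults to `cfg$dt_event`.
#' @return The advanced population.
#' @export
metabolism_step <- function(pop, grid, cfg, dt = cfg$dt_event) {
  if (!nrow(pop) || dt == 0) return(pop)
  Wloc <- grid$W[parcel_index(pop$x, pop$y, cfg)]
  B <- pop$B
  nsub <- max(1L, as.integer(round(dt / cfg$dt_int)))
  h <- dt / nsub
  for (i in seq_len(nsub)) {
    k1 <- growth_rate(B, Wloc, cfg)
    k2 <- growth_rate(B + h / 2 * k1, Wloc, cfg)
    k3 <- growth_rate(B + h / 2 * k2, Wloc, cfg)
    k4 <- growth_rate(B + h * k3, Wloc, cfg)
    B <- B + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    B[B < 0] <- 0
  }
  if (anyNA(B)) stop("plant biomass integration became unstable (NaN)")
  pop$B <- B
  pop$Bmax <- pmax(pop$Bmax, B)
  pop
}
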