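#' Infiltration flux
#'
#' Surface-to-soil water flux per parcel.  Vegetation enters the water
#' dynamics as biomass *density* \eqn{P = \Sigma B / dx^2} (g m\eqn{^{-2}};
#' the scale on which the infiltration constants are calibrated).
#' Infiltration saturates with the vegetation standing on the parcel: bare
#' soil infiltrates at the reduced rate \eqn{\alpha O W_0} while densely
#' vegetated soil approaches the maximum \eqn{\alpha O} — the positive
#' feedback that concentrates water under vegetation and drives pattern
#' formation.  The default form is
#' \deqn{\alpha O \frac{P + k_2 W_0}{P + k_2}.}
#' The `"water"` denominator variant (\eqn{P + k_2} replaced by
#' \eqn{W + k_2}) is available for sensitivity analysis via
#' `cfg$infiltration_denominator`; it requires `W`.
#'
#' @param O Surface water (mm); scalar, vector or matrix.
#' @param Bsum Total plant biomass on the parcel (g); same shape as `O`.
#' @param cfg A [sim_config()].
#' @param W Soil water (mm); only used by the `"water"` variant.
#' @return Infiltration flux (mm d\eqn{^{-1}}), same shape as `O`.
#' @export
#' @examples
#' cfg <- sim_config()
#' infiltration(20, 0, cfg)    # bare soil: 0.1 * 20 * 0.15 = 0.3
infiltration <- function(O, Bsum, cfg, W = NULL) {
  P <- Bsum / cfg$dx^2
  if (cfg$infiltration_denominator == "biomass") {
    cfg$alpha * O * (P + cfg$k2 * cfg$W0) / (P + cfg$k2)
  } else {
    if (is.null(W))
      stop("the 'water' infiltration variant needs the soil water field W")
    cfg$alpha * O * (P + cfg$k2 * cfg$W0) / (W + cfg$k2)
  }
}

#' Plant water uptake per parcel
#'
#' Water drawn from a parcel's soil by the plants standing on it,
#' \eqn{g_{max} \frac{W}{W + k_1} P} with \eqn{P = \Sigma B / dx^2} the
#' parcel's biomass density (g m\eqn{^{-2}}): Michaelis-Menten in soil
#' water and linear in biomass (plants on a parcel share the same water
#' density and each draws in proportion to its biomass).
#'
#' @param W Soil water (mm); scalar, vector or matrix.
#' @param Bsum Total plant biomass on the parcel (g); same shape as `W`.
#' @param cfg A [sim_config()].
#' @return Uptake flux (mm d\eqn{^{-1}}), same shape as `W`.
#' @export
#' @examples
#' uptake_field(3, 160, sim_config())  # 0.05 * 0.5 * 160/16 = 0.25
uptake_field <- function(W, Bsum, cfg) {
  cfg$g_max * W / (W + cfg$k1) * Bsum / cfg$dx^2
}

#' Discrete Laplacian (5-point stencil)
#'
#' \eqn{(\mathrm{up} + \mathrm{down} + \mathrm{left} + \mathrm{right} -
#' 4\,\mathrm{center}) / dx^2} with either reflecting (`"zero-flux"`) ghost
#' cells — under which pure diffusion conserves the field total — or
#' periodic wrapping.
#'
#' @param field Numeric matrix.
#' @param dx Grid spacing (m).
#' @param boundary `"zero-flux"` or `"periodic"`.
#' @return Matrix of the same shape.
#' @export
#' @examples
#' laplacian(matrix(c(0, 1, 0), 1, 3), dx = 1)  # 1 -2 1
laplacian <- function(field, dx, boundary = c("zero-flux", "periodic")) {
  boundary <- match.arg(boundary)
  if (!is.matrix(field)) stop("field must be a rectangular matrix")
  n <- nrow(field); m <- ncol(field)
  if (boundary == "zero-flux") {
    up    <- field[c(1L, seq_len(n - 1L)), , drop = FALSE]
    down  <- field[c(seq_len(n)[-1L], n), , drop = FALSE]
    left  <- field[, c(1L, seq_len(m - 1L)), drop = FALSE]
    right <- field[, c(seq_len(m)[-1L], m), drop = FALSE]
  } else {
    up    <- field[c(n, seq_len(n - 1L)), , drop = FALSE]
    down  <- field[c(seq_len(n)[-1L], 1L), , drop = FALSE]
    left  <- field[, c(m, seq_len(m - 1L)), drop = FALSE]
    right <- field[, c(seq_len(m)[-1L], 1L), drop = FALSE]
  }
  (up + down + left + right - 4 * field) / dx^2
}

## Right-hand side of the water dynamics for a frozen biomass field.
water_rhs <- function(O, W, Bsum, R_t, cfg) {
  inf <- infiltration(O, Bsum, cfg, W = W)
  upt <- uptake_field(W, Bsum, cfg)
  list(
    dO = R_t - inf + cfg$D_O * laplacian(O, cfg$dx, cfg$boundary),
    dW = inf - upt - cfg$r_w * W + cfg$D_W * laplacian(W, cfg$dx, cfg$boundary))
}

#' Advance the water fields over one event step (frozen biomass)
#'
#' Integrates the surface/soil water dynamics by classical RK4 sub-steps of
#' size `cfg$dt_int`, holding the per-parcel biomass `Bsum` fixed.  This is
#' the "split" coupling water half-step; the full simulation loop normally
#' co-integrates plants and water (see [run_simulation()]).  Both fields are
#' clamped non-negative after each sub-step.
#'
#' @param grid A [bare_soil_grid()] `soil_grid`.
#' @param Bsum Per-parcel biomass matrix (g), frozen over the step.
#' @param cfg A [sim_config()].
#' @param dt Step length (d); defaults to `cfg$dt_event`.
#' @param t0 Start time (d), used to evaluate the rainfall forcing.
#' @return The advanced `soil_grid`.
#' @export
water_step <- function(grid, Bsum, cfg, dt = cfg$dt_event, t0 = 0) {
  stopifnot(inherits(grid, "soil_grid"))
  O <- grid$O; W <- grid$W
  nsub <- max(1L, as.integer(round(dt / cfg$dt_int)))
  h <- dt / nsub
  t <- t0
  for (i in seq_len(nsub)) {
    k1 <- water_rhs(O, W, Bsum, rainfall_at(cfg$rain, t), cfg)
    k2 <- water_rhs(O + h / 2 * k1$dO, W + h / 2 * k1$dW, Bsum,
                    rainfall_at(cfg$rain, t + h / 2), cfg)
    k3 <- water_rhs(O + h / 2 * k2$dO, W + h / 2 * k2$dW, Bsum,
                    rainfall_at(cfg$rain, t + h / 2), cfg)
    k4 <- water_rhs(O + h * k3$dO, W + h * k3$dW, Bsum,
                    rainfall_at(cfg$rain, t + h), cfg)
    O <- O + h / 6 * (k1$dO + 2 * k2$dO + 2 * k3$dO + k4$dO)
    W <- W + h / 6 * (k1$dW + 2 * k2$dW + 2 * k3$dW + k4$dW)
    O[O < 0] <- 0
    W[W < 0] <- 0
    t <- t + h
  }
  if (anyNA(O) || anyNA(W))
    stop("water integration became unstable (NaN); reduce dt_int")
  new_soil_grid(O, W, grid$dx)
}
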