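## Independent reference implementations used as oracles.  These are
## deliberately written from the model equations, not from the package's
## integration code paths: plain explicit Euler at a fine step, with their
## own stencil built from padded arrays.

## Laplacian with reflecting (zero-flux) ghost cells, via explicit padding.
oracle_laplacian <- function(f, dx) {
  n <- nrow(f); m <- ncol(f)
  pad <- matrix(0, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- f
  pad[1, 2:(m + 1)] <- f[1, ]
  pad[n + 2, 2:(m + 1)] <- f[n, ]
  pad[2:(n + 1), 1] <- f[, 1]
  pad[2:(n + 1), m + 2] <- f[, m]
  (pad[1:n, 2:(m + 1)] + pad[3:(n + 2), 2:(m + 1)] +
   pad[2:(n + 1), 1:m] + pad[2:(n + 1), 3:(m + 2)] - 4 * f) / dx^2
}

## Explicit-Euler integration of the water dynamics with frozen per-parcel
## biomass (raw grams; converted to g/m2 density inside, as in the model).
oracle_water_euler <- function(O, W, Bsum, p, R, t_total, h) {
  P <- Bsum / p$dx^2
  nstep <- round(t_total / h)
  for (i in seq_len(nstep)) {
    inf <- p$alpha * O * (P + p$k2 * p$W0) / (P + p$k2)
    upt <- p$g_max * W / (W + p$k1) * P
    dO <- R - inf + p$D_O * oracle_laplacian(O, p$dx)
    dW <- inf - upt - p$r_w * W + p$D_W * oracle_laplacian(W, p$dx)
    O <- pmax(O + h * dO, 0)
    W <- pmax(W + h * dW, 0)
  }
  list(O = O, W = W)
}

## Explicit-Euler integration of the single-plant biomass equation at
## constant soil water.
oracle_plant_euler <- function(B, W, p, t_total, h) {
  nstep <- round(t_total / h)
  for (i in seq_len(nstep)) {
    dB <- B * p$b * p$g_max * (1 - B / p$Kp) * W / (W + p$k1) - B * p$d
    B <- max(B + h * dB, 0)
  }
  B
}

## Default model parameters as a plain list for the oracles.
oracle_params <- function(cfg = sim_config()) {
  cfg[c("alpha", "k2", "W0", "r_w", "D_O", "D_W", "dx",
        "g_max", "k1", "b", "Kp", "d")]
}

## Small standard scenario shared by scheduler-level tests: coarse grid,
## modest population, short horizon.
small_scenario <- function(R = 1.1, T_end = 120, rng_seed = 99, nx = 15,
                           ..., snapshot_every = Inf) {
  cfg <- sim_config(nx = nx, ny = nx,
                    rain = rainfall_regime("constant", R0 = R),
                    T_end = T_end, seed = rng_seed, summary_every = 5,
                    snapshot_every = snapshot_every, ...)
  set.seed(rng_seed)
  pop0 <- init_population(cfg, "aggregated", 30,
                          n_patches = min(3, ceiling(0.01 * nx * nx)))
  list(cfg = cfg, pop0 = pop0)
}
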