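#' Soil grid at bare-soil equilibrium
#'
#' Builds the grid of soil parcels with both water stocks at their bare-soil
#' steady state: surface water \eqn{O = R_0 / (\alpha W_0)} and soil water
#' \eqn{W = R_0 / r_w}, where \eqn{R_0} is the rainfall at \eqn{t = 0}.
#' With no plants and constant rainfall this state is a fixed point of the
#' water dynamics, so simulations start from hydrological equilibrium.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `soil_grid`: a list with matrices `O` and `W`
#'   (dimension `nx` by `ny`, row index along x) and the parcel side `dx`.
#' @export
#' @examples
#' g <- bare_soil_grid(sim_config(rain = rainfall_regime("constant", R0 = 0.3),
#'                                r_w = 0.1, nx = 10, ny = 10))
#' g$O[1, 1]  # 0.3 / (0.1 * 0.15) = 20
#' g$W[1, 1]  # 0.3 / 0.1 = 3
bare_soil_grid <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  R0 <- rainfall_at(cfg$rain, 0)
  if (R0 > 0 && (cfg$alpha == 0 || cfg$W0 == 0 || cfg$r_w == 0))
    stop("bare-soil equilibrium undefined: positive rainfall with zero ",
         "infiltration (alpha, W0) or loss (r_w) rate")
  O0 <- if (R0 == 0) 0 else R0 / (cfg$alpha * cfg$W0)
  W0 <- if (R0 == 0) 0 else R0 / cfg$r_w
  new_soil_grid(matrix(O0, cfg$nx, cfg$ny), matrix(W0, cfg$nx, cfg$ny),
                cfg$dx)
}

new_soil_grid <- function(O, W, dx) {
  stopifnot(is.matrix(O), is.matrix(W), all(dim(O) == dim(W)), dx > 0)
  structure(list(O = O, W = W, dx = dx), class = "soil_grid")
}

#' @export
print.soil_grid <- function(x, ...) {
  cat(sprintf("<soil_grid> %d x %d parcels of %g m\n",
              nrow(x$O), ncol(x$O), x$dx))
  cat(sprintf("  O: [%.4g, %.4g] mm   W: [%.4g, %.4g] mm\n",
              min(x$O), max(x$O), min(x$W), max(x$W)))
  invisible(x)
}

#' Plant population table
#'
#' Populations are plain data frames with one row per living plant and
#' columns `id` (stable integer identifier), `x`, `y` (continuous position
#' in m, origin at the lower-left corner), `age` (d), `B` (current biomass,
#' g) and `Bmax` (largest biomass reached so far, g).
#'
#' @param id,x,y,age,B,Bmax Equal-length column vectors.
#' @return A `data.frame` with class `population` prepended.
#' @export
new_population <- function(id = integer(), x = numeric(), y = numeric(),
                           age = numeric(), B = numeric(), Bmax = B) {
  df <- data.frame(id = as.integer(id), x = x, y = y, age = age,
                   B = B, Bmax = Bmax)
  class(df) <- c("population", "data.frame")
  df
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d plants, total biomass %.4g g\n",
              nrow(x), sum(x$B)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L), ...)
  if (nrow(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Linear parcel index of plant positions
#'
#' Maps continuous coordinates to 1-based linear indices into the grid
#' matrices (parcel `ix = floor(x/dx) + 1`, column-major over an
#' `nx` by `ny` matrix).  Positions exactly on the upper boundary are
#' clamped into the last parcel.
#'
#' @param x,y Coordinates (m).
#' @param cfg A [sim_config()].
#' @return Integer vector of linear parcel indices.
#' @export
parcel_index <- function(x, y, cfg) {
  ix <- pmin.int(cfg$nx, floor(x / cfg$dx) + 1L)
  iy <- pmin.int(cfg$ny, floor(y / cfg$dx) + 1L)
  as.integer(ix + (iy - 1L) * cfg$nx)
}

#' Per-parcel total plant biomass
#'
#' @param pop A [new_population()] table.
#' @param cfg A [sim_config()].
#' @return An `nx` by `ny` matrix of summed biomass (g).
#' @export
parcel_biomass <- function(pop, cfg) {
  Bsum <- numeric(cfg$nx * cfg$ny)
  if (nrow(pop)) {
    idx <- parcel_index(pop$x, pop$y, cfg)
    agg <- rowsum(pop$B, idx)
    Bsum[as.integer(rownames(agg))] <- agg[, 1L]
  }
  matrix(Bsum, cfg$nx, cfg$ny)
}

#' Initial plant population
#'
#' Instantiates the founding population in one of two spatial modes.
#' `"random"` scatters plants uniformly over the plot.  `"aggregated"`
#' groups them inside patches that together cover 1\% of the parcels:
#' `ceiling(0.01 * nx * ny)` parcels are partitioned among `n_patches`
#' contiguous patches grown from uniformly chosen seed parcels, and plants
#' are assigned round-robin among patches (uniform position within a
#' uniformly chosen parcel of their patch).
#'
#' Initial biomass is drawn uniformly from `cfg$B_init_range` (default 1-2 g)
#' and initial age uniformly from the integers 1 to `cfg$l`, avoiding
#' artificial synchrony in the founding cohort.
#'
#' @param cfg A [sim_config()].
#' @param mode `"aggregated"` or `"random"`.
#' @param n_plants Number of founding plants.
#' @param n_patches Number of patches (aggregated mode); defaults to the
#'   number of covered parcels, i.e. single-parcel patches.
#' @return A [new_population()] table.
#' @export
#' @examples
#' cfg <- sim_config(nx = 20, ny = 20, seed = 1)
#' set.seed(1)
#' pop <- init_population(cfg, "aggregated", n_plants = 40, n_patches = 4)
#' nrow(pop)
init_population <- function(cfg, mode = c("random", "aggregated"),
                            n_plants, n_patches = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_plants >= 0)
  if (n_plants == 0) return(new_population())
  Lx <- cfg$nx * cfg$dx
  Ly <- cfg$ny * cfg$dx
  if (Lx <= 0 || Ly <= 0) stop("cannot place plants on a zero-area plot")

  if (mode == "random") {
    x <- runif(n_plants, 0, Lx)
    y <- runif(n_plants, 0, Ly)
  } else {
    n_cover <- ceiling(0.01 * cfg$nx * cfg$ny)
    if (is.null(n_patches)) n_patches <- n_cover
    if (n_patches < 1 || n_patches > n_cover)
      stop("n_patches must lie in [1, ceiling(0.01 * nx * ny)] = [1, ",
           n_cover, "]")
    patches <- grow_patches(cfg$nx, cfg$ny, n_patches, n_cover)
    ## plants round-robin among patches
    pat <- rep_len(seq_len(n_patches), n_plants)
    cell <- vapply(pat, function(k) {
      p <- patches[[k]]
      p[sample.int(length(p), 1L)]
    }, integer(1))
    ix <- (cell - 1L) %% cfg$nx
    iy <- (cell - 1L) %/% cfg$nx
    x <- (ix + runif(n_plants)) * cfg$dx
    y <- (iy + runif(n_plants)) * cfg$dx
  }
  B <- runif(n_plants, cfg$B_init_range[1], cfg$B_init_range[2])
  age <- sample.int(max(1L, as.integer(cfg$l)), n_plants, replace = TRUE)
  new_population(id = seq_len(n_plants), x = x, y = y, age = as.numeric(age),
                 B = B, Bmax = B)
}

## Partition n_cover parcels into n_patches contiguous blocks: seed parcels
## chosen uniformly without replacement, then round-robin growth by random
## free 4-neighbors until each patch reaches its quota.
grow_patches <- function(nx, ny, n_patches, n_cover) {
  ncell <- nx * ny
  seeds <- sample.int(ncell, n_patches)
  quota <- rep(n_cover %/% n_patches, n_patches)
  extra <- n_cover %% n_patches
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  taken <- logical(ncell)
  taken[seeds] <- TRUE
  patches <- as.list(seeds)
  neighbors4 <- function(cell) {
    ix <- (cell - 1L) %% nx
    iy <- (cell - 1L) %/% nx
    nb <- c(if (ix > 0L) cell - 1L, if (ix < nx - 1L) cell + 1L,
            if (iy > 0L) cell - nx, if (iy < ny - 1L) cell + nx)
    nb
  }
  repeat {
    grew <- FALSE
    for (k in seq_len(n_patches)) {
      if (length(patches[[k]]) >= quota[k]) next
      free <- unique(unlist(lapply(patches[[k]], neighbors4)))
      free <- free[!taken[free]]
      if (!length(free)) next
      pick <- free[sample.int(length(free), 1L)]
      taken[pick] <- TRUE
      patches[[k]] <- c(patches[[k]], pick)
      grew <- TRUE
    }
    if (!grew || all(lengths(patches) >= quota)) break
  }
  patches
}
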