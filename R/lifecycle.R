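#' Lognormal seed dispersal kernel
#'
#' Distance kernel for isotropic seed dispersal.  `mu_disp` is the
#' distribution *mean* (not the log-scale location): the lognormal location
#' parameter is \eqn{\ln\mu - \sigma^2/2}, so the empirical mean of sampled
#' distances converges to `mu_disp` while the median is
#' \eqn{\mu e^{-\sigma^2/2}} — a leptokurtic, short-range-biased kernel
#' typical of arid-land vegetation (atelechory).
#'
#' @param mu_disp Mean dispersal distance (m).
#' @param sigma_disp Log-scale standard deviation (dimensionless).
#' @return An object of class `dispersal_kernel` with `meanlog` and `sdlog`.
#' @export
#' @examples
#' k <- dispersal_kernel(10, 1.5)
#' exp(k$meanlog)  # median distance ~ 3.25 m
dispersal_kernel <- function(mu_disp, sigma_disp) {
  stopifnot(mu_disp > 0, sigma_disp >= 0)
  structure(list(mu_disp = mu_disp, sigma_disp = sigma_disp,
                 meanlog = log(mu_disp) - sigma_disp^2 / 2,
                 sdlog = sigma_disp),
            class = "dispersal_kernel")
}

#' Expected number of seeds per event step
#'
#' A mature plant's expected seed output over one event step,
#' \eqn{E = B\,s\,f(m)\,\Delta t} with maturity factor \eqn{f(m) = l/m} for
#' \eqn{m > 0} and \eqn{f(0) = 1}.  The factor \eqn{l/m} keeps expected
#' lifetime fecundity roughly constant as maturity is delayed; at the
#' default \eqn{m = 0} the seed rate is simply \eqn{B s}.  When realized,
#' \eqn{E \ge 1} means \eqn{\lfloor E \rfloor} seeds plus one more with
#' probability \eqn{E - \lfloor E \rfloor}; \eqn{E < 1} is a Bernoulli
#' probability.
#'
#' @param B Plant biomass (g); vectorized.
#' @param cfg A [sim_config()].
#' @param dt_event Event step (d); defaults to `cfg$dt_event`.
#' @return Expected seed count per step (vectorized).
#' @export
expected_seeds <- function(B, cfg, dt_event = cfg$dt_event) {
  f_m <- if (cfg$m > 0) cfg$l / cfg$m else 1
  B * cfg$s * f_m * dt_event
}

## realize integer seed counts from expected values
sample_seed_counts <- function(E) {
  base <- floor(E)
  frac <- E - base
  as.integer(base) + rbinom(length(E), 1L, frac)
}

#' Sample seed landing positions
#'
#' Disperses `n` seeds from one origin: direction uniform on
#' \eqn{[0, 2\pi)}, distance from the lognormal kernel.  Landing positions
#' outside the plot are lost (absorbing boundary — no wrapping, no
#' re-draw), so the plot leaks seeds at its edges.
#'
#' @param origin Numeric length-2 vector `c(x, y)` (m), inside the plot.
#' @param kernel A [dispersal_kernel()].
#' @param plot_bounds Numeric length-2 vector `c(Lx, Ly)` (m).
#' @param n Number of seeds.
#' @return A `data.frame` with columns `x`, `y` and logical `lost`
#'   (positions of lost seeds are still reported).
#' @export
sample_dispersal <- function(origin, kernel, plot_bounds, n = 1L) {
  stopifnot(inherits(kernel, "dispersal_kernel"),
            origin[1] >= 0, origin[1] < plot_bounds[1],
            origin[2] >= 0, origin[2] < plot_bounds[2])
  theta <- runif(n, 0, 2 * pi)
  dist <- rlnorm(n, kernel$meanlog, kernel$sdlog)
  x <- origin[1] + dist * cos(theta)
  y <- origin[2] + dist * sin(theta)
  lost <- x < 0 | x >= plot_bounds[1] | y < 0 | y >= plot_bounds[2]
  data.frame(x = x, y = y, lost = lost)
}

#' Attempt seedling establishment at a point
#'
#' A seedling takes root with biomass 1 g and age 0 unless the biomass
#' density of the target parcel (`Bsum / dx^2`) already exceeds the
#' establishment cap `K_a`.  With `cfg$preemptive_seedling_removal` on, a
#' seedling is additionally rejected when its instantaneous growth rate in
#' the parcel's current soil water is non-positive — a performance shortcut
#' that distorts pattern formation and is therefore off by default.
#'
#' @param position Numeric length-2 vector `c(x, y)` (m), inside the plot.
#' @param pop A [new_population()] table (for the parcel biomass).
#' @param grid A `soil_grid`.
#' @param cfg A [sim_config()].
#' @return A one-row population table (the established seedling, `id = NA`)
#'   or `NULL` if establishment is rejected.
#' @export
try_establish <- function(position, pop, grid, cfg) {
  p <- parcel_index(position[1], position[2], cfg)
  Bsum <- parcel_biomass(pop, cfg)[p]
  if (Bsum / cfg$dx^2 > cfg$K_a) return(NULL)
  if (cfg$preemptive_seedling_removal &&
      growth_rate(1, grid$W[p], cfg) <= 0) return(NULL)
  new_population(id = NA_integer_, x = position[1], y = position[2],
                 age = 0, B = 1, Bmax = 1)
}

#' Water-stress death probability
#'
#' Daily probability of stress-induced death: zero while the relative
#' biomass \eqn{B/B_{max}} is at or above the threshold `d_b`; once below
#' it, \eqn{p = 1 - B / (d_b B_{max})} (equivalently one minus biomass
#' over the death threshold \eqn{d_b B_{max}}), reaching 1 as
#' \eqn{B \to 0}.  With `dt_event` given, the daily probability is
#' converted to the event step by complement exponentiation.
#'
#' @param B,Bmax Current and running-maximum biomass (g); vectorized.
#' @param cfg A [sim_config()].
#' @param dt_event Step length (d); `1` gives the daily probability.
#' @return Death probability in \eqn{[0, 1]}.
#' @export
#' @examples
#' death_probability(0.4, 1, sim_config())  # 1 - 0.4/0.8 = 0.5
death_probability <- function(B, Bmax, cfg, dt_event = 1) {
  p_day <- pmax(0, pmin(1, 1 - B / (cfg$d_b * Bmax)))
  p_day[B / Bmax >= cfg$d_b] <- 0
  1 - (1 - p_day)^dt_event
}

#' Stochastic death over one event step
#'
#' Two independent hazards act on each plant.  *Water stress*: once the
#' relative biomass \eqn{B/B_{max}} falls below the threshold `d_b`, the
#' daily death probability is \eqn{p = 1 - B/(d_b\,B_{max})} (zero exactly
#' at the threshold, one as \eqn{B \to 0}).  *Age*: when enabled, a
#' constant daily hazard \eqn{1/l} (exponential lifetime with mean `l`), or
#' a hard cutoff at age `l` in `"cutoff"` mode.  Daily probabilities are
#' converted to the event step by complement exponentiation,
#' \eqn{p_{step} = 1 - (1 - p_{day})^{\Delta t}}, which keeps them in
#' \eqn{[0, 1]} for any step size.
#'
#' @param pop A [new_population()] table.
#' @param cfg A [sim_config()].
#' @param dt_event Event step (d); defaults to `cfg$dt_event`.
#' @return The surviving population, with attributes `n_death_stress` and
#'   `n_death_age` counting removals.
#' @export
death_step <- function(pop, cfg, dt_event = cfg$dt_event) {
  n <- nrow(pop)
  if (!n) {
    attr(pop, "n_death_stress") <- 0L
    attr(pop, "n_death_age") <- 0L
    return(pop)
  }
  p_stress <- death_probability(pop$B, pop$Bmax, cfg, dt_event)
  die_stress <- runif(n) < p_stress
  die_age <- rep(FALSE, n)
  if (cfg$age_mortality_enabled) {
    if (cfg$age_mortality_mode == "hazard") {
      p_age <- 1 - (1 - 1 / cfg$l)^dt_event
      die_age <- runif(n) < p_age
    } else {
      die_age <- pop$age >= cfg$l
    }
  }
  die_age <- die_age & !die_stress
  keep <- !(die_stress | die_age)
  out <- pop[keep, , drop = FALSE]
  attr(out, "n_death_stress") <- sum(die_stress)
  attr(out, "n_death_age") <- sum(die_age)
  out
}

#' One full round of discrete lifecycle events
#'
#' Applies, in order: seed production and dispersal by mature plants with
#' establishment under the density cap, then stochastic death, then age
#' increment; newborns are appended with age 0.  Seeds landing in the same
#' parcel establish in randomized order, each established seedling adding
#' its 1 g to the parcel's density before the next is checked.
#'
#' @param pop A [new_population()] table (after the metabolism update).
#' @param grid A `soil_grid` (current soil water, for the preemptive flag).
#' @param cfg A [sim_config()].
#' @param next_id First unused plant id.
#' @return A list with elements `pop` (updated population), `next_id`, and
#'   `events` (named counts: `births`, `deaths_stress`, `deaths_age`,
#'   `seeds_lost`, `blocked`).
#' @export
lifecycle_step <- function(pop, grid, cfg, next_id = 1L) {
  v <- list(id = pop$id, x = pop$x, y = pop$y, age = pop$age,
            B = pop$B, Bmax = pop$Bmax)
  res <- lifecycle_step_vec(v, grid$W, cfg, next_id)
  out <- new_population(id = res$v$id, x = res$v$x, y = res$v$y,
                        age = res$v$age, B = res$v$B, Bmax = res$v$Bmax)
  list(pop = out, next_id = res$next_id, events = res$events)
}

## Vector-form lifecycle kernel used by the simulation loop: `v` is a plain
## list of equal-length column vectors (id, x, y, age, B, Bmax), `Wfield`
## the soil-water matrix.  Avoids data.frame overhead in the per-step path.
lifecycle_step_vec <- function(v, Wfield, cfg, next_id) {
  ev <- c(births = 0L, deaths_stress = 0L, deaths_age = 0L,
          seeds_lost = 0L, blocked = 0L)
  n <- length(v$B)
  nb <- 0L
  if (n) {
    ## --- seed production and dispersal
    E <- expected_seeds(v$B, cfg)
    E[v$age < cfg$m] <- 0
    nseed <- sample_seed_counts(E)
    tot <- sum(nseed)
    if (tot > 0L) {
      src <- rep.int(seq_len(n), nseed)
      theta <- runif(tot, 0, 2 * pi)
      dist <- rlnorm(tot, log(cfg$mu_disp) - cfg$sigma_disp^2 / 2,
                     cfg$sigma_disp)
      sx <- v$x[src] + dist * cos(theta)
      sy <- v$y[src] + dist * sin(theta)
      Lx <- cfg$nx * cfg$dx; Ly <- cfg$ny * cfg$dx
      inside <- sx >= 0 & sx < Lx & sy >= 0 & sy < Ly
      ev["seeds_lost"] <- sum(!inside)
      sx <- sx[inside]; sy <- sy[inside]
      ncand <- length(sx)
      if (ncand) {
        ## randomized order, then sequential density cap per parcel:
        ## the k-th candidate in a parcel establishes iff
        ## (Bsum + (k-1) * 1 g) / dx^2 <= K_a
        ord <- sample.int(ncand)
        sx <- sx[ord]; sy <- sy[ord]
        pidx <- parcel_index(sx, sy, cfg)
        Bsum <- numeric(cfg$nx * cfg$ny)
        agg <- rowsum(v$B, parcel_index(v$x, v$y, cfg))
        Bsum[as.integer(rownames(agg))] <- agg[, 1L]
        rank_in <- seq_len(ncand)
        if (ncand > 1L) {
          o <- order(pidx)
          r <- sequence(rle(pidx[o])$lengths)
          rank_in[o] <- r
        }
        cap_ok <- (Bsum[pidx] + (rank_in - 1)) / cfg$dx^2 <= cfg$K_a
        if (cfg$preemptive_seedling_removal) {
          cap_ok <- cap_ok & (growth_rate(1, Wfield[pidx], cfg) > 0)
        }
        ev["blocked"] <- sum(!cap_ok)
        nb <- sum(cap_ok)
        if (nb) {
          bx <- sx[cap_ok]; by <- sy[cap_ok]
        }
      }
    }
    ## --- death, then aging of the established plants
    p_stress <- death_probability(v$B, v$Bmax, cfg, cfg$dt_event)
    die_stress <- runif(n) < p_stress
    die_age <- rep(FALSE, n)
    if (cfg$age_mortality_enabled) {
      if (cfg$age_mortality_mode == "hazard") {
        die_age <- runif(n) < (1 - (1 - 1 / cfg$l)^cfg$dt_event)
      } else {
        die_age <- v$age >= cfg$l
      }
    }
    die_age <- die_age & !die_stress
    keep <- !(die_stress | die_age)
    ev["deaths_stress"] <- sum(die_stress)
    ev["deaths_age"] <- sum(die_age)
    if (!all(keep)) v <- lapply(v, `[`, keep)
    v$age <- v$age + cfg$dt_event
  }
  if (nb) {
    ev["births"] <- nb
    v <- list(id = c(v$id, seq.int(next_id, length.out = nb)),
              x = c(v$x, bx), y = c(v$y, by),
              age = c(v$age, rep.int(0, nb)),
              B = c(v$B, rep.int(1, nb)), Bmax = c(v$Bmax, rep.int(1, nb)))
    next_id <- next_id + nb
  }
  list(v = v, next_id = next_id, events = ev)
}
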