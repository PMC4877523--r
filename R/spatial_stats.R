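#' Quadrat counts of living plants
#'
#' Tiles the plot exhaustively with non-overlapping square quadrats and
#' counts the plants in each.  Every living plant is counted exactly once,
#' so the counts always sum to the population size regardless of quadrat
#' size.
#'
#' @param pop A [new_population()] table.
#' @param quadrat_size Quadrat side (m); must divide both plot sides.
#' @param cfg A [sim_config()] (for the plot geometry).
#' @return An object of class `quadrat_counts`: list with integer vector
#'   `counts` (one entry per quadrat) and `quadrat_size`.
#' @export
#' @examples
#' cfg <- sim_config(nx = 10, ny = 10)
#' pop <- new_population(id = 1:2, x = c(1, 30), y = c(1, 30),
#'                       age = c(0, 0), B = c(1, 1))
#' sum(quadrat_counts(pop, 8, cfg)$counts)  # 2
quadrat_counts <- function(pop, quadrat_size, cfg) {
  Lx <- cfg$nx * cfg$dx
  Ly <- cfg$ny * cfg$dx
  qx <- Lx / quadrat_size
  qy <- Ly / quadrat_size
  if (abs(qx - round(qx)) > 1e-9 || abs(qy - round(qy)) > 1e-9)
    stop("quadrat_size ", quadrat_size, " does not divide the plot sides (",
         Lx, " x ", Ly, "); nearest divisor of the x side: ",
         Lx / round(qx))
  qx <- as.integer(round(qx)); qy <- as.integer(round(qy))
  counts <- integer(qx * qy)
  if (nrow(pop)) {
    ix <- pmin.int(qx, floor(pop$x / quadrat_size) + 1L)
    iy <- pmin.int(qy, floor(pop$y / quadrat_size) + 1L)
    tab <- tabulate(ix + (iy - 1L) * qx, nbins = qx * qy)
    counts <- as.integer(tab)
  }
  structure(list(counts = counts, quadrat_size = quadrat_size),
            class = "quadrat_counts")
}

count_vector <- function(counts) {
  if (inherits(counts, "quadrat_counts")) counts$counts else counts
}

#' Lloyd's index of patchiness (IP)
#'
#' Mean crowding over mean: \eqn{IP = 1 + (s^2 - \bar m)/\bar m^2}, with
#' \eqn{\bar m} the mean and \eqn{s^2} the sample (n-1) variance of the
#' quadrat counts.  Equals 1 for a Poisson (spatially random) pattern,
#' exceeds 1 for clumped patterns, and is independent of density under
#' random thinning.
#'
#' @param counts A [quadrat_counts()] object or a numeric count vector.
#' @return IP (dimensionless).
#' @export
#' @examples
#' index_of_patchiness(c(8, 0, 8, 0))  # about 2.083
index_of_patchiness <- function(counts) {
  x <- count_vector(counts)
  m <- mean(x)
  if (!is.finite(m) || m <= 0)
    stop("index of patchiness undefined: mean quadrat count is zero")
  1 + (var(x) - m) / m^2
}

#' David-Moore index of cluster size (ICS)
#'
#' Variance-to-mean ratio of the quadrat counts minus one:
#' \eqn{ICS = s^2/\bar m - 1}.  Zero for a Poisson (random) pattern;
#' positive values measure the mean number of *other* individuals sharing a
#' clump with a randomly chosen individual (absolute clumping).
#'
#' @param counts A [quadrat_counts()] object or a numeric count vector.
#' @return ICS (dimensionless).
#' @export
#' @examples
#' index_of_cluster_size(c(8, 0, 8, 0))  # about 4.33
index_of_cluster_size <- function(counts) {
  x <- count_vector(counts)
  m <- mean(x)
  if (!is.finite(m) || m <= 0)
    stop("index of cluster size undefined: mean quadrat count is zero")
  var(x) / m - 1
}

#' Population structure summaries
#'
#' Age and biomass histograms (1-day and 1-gram bins, relative
#' frequencies), means, seedling fraction (age under 30 days, i.e. plants
#' less than a month old) and plant density.
#'
#' @param pop A [new_population()] table.
#' @param cfg A [sim_config()] (for the plot area).
#' @return A list with `age_hist` and `biomass_hist` (data frames with
#'   `mid` and `freq`), `mean_age`, `mean_biomass`, `seedling_fraction`,
#'   `n_plants` and `plant_density` (m\eqn{^{-2}}).  An empty population
#'   yields `n_plants = 0` with `NA` summaries (flagged by `empty = TRUE`),
#'   not an error.
#' @export
structure_summaries <- function(pop, cfg) {
  area <- cfg$nx * cfg$ny * cfg$dx^2
  n <- nrow(pop)
  if (!n) {
    return(list(empty = TRUE, n_plants = 0L, plant_density = 0,
                mean_age = NA_real_, mean_biomass = NA_real_,
                seedling_fraction = NA_real_,
                age_hist = data.frame(mid = numeric(), freq = numeric()),
                biomass_hist = data.frame(mid = numeric(), freq = numeric())))
  }
  hist1 <- function(v) {
    lo <- floor(min(v)); hi <- floor(max(v))
    bins <- lo:hi
    f <- tabulate(floor(v) - lo + 1L, nbins = length(bins)) / length(v)
    data.frame(mid = bins + 0.5, freq = f)
  }
  list(empty = FALSE, n_plants = n, plant_density = n / area,
       mean_age = mean(pop$age), mean_biomass = mean(pop$B),
       seedling_fraction = mean(pop$age < 30),
       age_hist = hist1(pop$age), biomass_hist = hist1(pop$B))
}

#' Mortality by age / biomass class
#'
#' Given the population before a disturbance and the (id-stable) population
#' at a later assessment time, computes the fraction of each pre-disturbance
#' class that has died, for classes of pre-disturbance age and biomass.
#'
#' @param pre_pop Population at the reference (pre-disturbance) time.
#' @param post_pop Population at the assessment time (descended from
#'   `pre_pop` by simulation, ids stable).
#' @param age_breaks,biomass_breaks Numeric break vectors handed to
#'   [cut()]; classes are left-closed (`[a, b)`).
#' @return A list with data frames `by_age` and `by_biomass` (columns
#'   `class`, `n`, `dead`, `mortality`); empty classes report `NA`
#'   mortality.
#' @export
#' @examples
#' pre <- new_population(id = 1:3, x = 1:3, y = 1:3,
#'                       age = c(2, 40, 400), B = c(0.5, 6, 20))
#' post <- pre[2, ]
#' mortality_by_class(pre, post, c(0, 7, 45, Inf), c(0, 1, 15, Inf))$by_biomass
mortality_by_class <- function(pre_pop, post_pop,
                               age_breaks = c(0, 1, 7, 14, 30, 45, 90, 180,
                                              365, Inf),
                               biomass_breaks = c(0, 1, 5, 15, 30, 60, 120,
                                                  Inf)) {
  dead <- !(pre_pop$id %in% post_pop$id)
  one <- function(values, breaks) {
    cls <- cut(values, breaks = breaks, right = FALSE)
    n <- as.integer(table(cls))
    nd <- vapply(levels(cls), function(lv) sum(dead[cls == lv]),
                 integer(1), USE.NAMES = FALSE)
    data.frame(class = levels(cls), n = n, dead = nd,
               mortality = ifelse(n > 0, nd / n, NA_real_))
  }
  list(by_age = one(pre_pop$age, age_breaks),
       by_biomass = one(pre_pop$B, biomass_breaks))
}

#' Spatial autocorrelation of parcel occupancy
#'
#' Moran-style correlogram of the binary occupied/empty state of parcels,
#' at integer parcel lags along the grid axes: the Pearson correlation
#' between the occupancy field and itself shifted by the lag (both axis
#' directions pooled).  Positive short-lag and negative mid-lag values are
#' the signature of periodic (spot/labyrinth) vegetation patterns.
#'
#' @param occ Logical or 0/1 matrix of parcel occupancy (e.g.
#'   `parcel_biomass(pop, cfg) > 0`).
#' @param lags Integer vector of lags (in parcels).
#' @return Data frame with columns `lag` and `correlation`.
#' @export
occupancy_autocorrelation <- function(occ, lags = 1:15) {
  occ <- matrix(as.numeric(occ), nrow(occ), ncol(occ))
  n <- nrow(occ); m <- ncol(occ)
  cor_at <- function(k) {
    pairs_x <- if (k < n)
      cbind(as.vector(occ[seq_len(n - k), ]),
            as.vector(occ[seq_len(n - k) + k, ])) else NULL
    pairs_y <- if (k < m)
      cbind(as.vector(occ[, seq_len(m - k)]),
            as.vector(occ[, seq_len(m - k) + k])) else NULL
    p <- rbind(pairs_x, pairs_y)
    if (is.null(p) || stats::sd(p[, 1]) == 0 || stats::sd(p[, 2]) == 0)
      return(NA_real_)
    stats::cor(p[, 1], p[, 2])
  }
  data.frame(lag = lags,
             correlation = vapply(lags, cor_at, numeric(1)))
}
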