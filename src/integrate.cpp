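#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hybrid simulation core.
//
// Continuous block: coupled RK4 integration of the water fields and the
// per-plant biomass ODEs.  Plants and parcels form one continuous system:
// the per-parcel biomass density (g m^-2) entering the infiltration and
// uptake terms is refreshed from the stage biomasses at every RK4 stage.
//
// Discrete block (.run_hybrid only): seed production and lognormal
// dispersal, establishment under the density cap, stochastic death
// (biomass-threshold stress + age hazard), aging.  All randomness comes
// from R's RNG (the exported wrappers install an RNGScope), so runs are
// reproducible from set.seed().
//
// Fields are nx*ny column-major with x as the row index.  The grid loop
// is split into interior cells (fixed stencil offsets) and boundary cells
// (precomputed neighbor indices: reflecting ghost cells for zero-flux,
// wrapping for periodic).  Negative state values arising from a sub-step
// are clamped to zero and counted.

struct Model {
  int nx, ny, ncell;
  double alpha, k2, W0, r_w, D_O, D_W, inv_dx2, inv_area;
  double g_max, k1, b, Kp, d;
  bool infil_water;
  // rainfall forcing
  int rain_mode;  // 0 constant, 1 shift, 2 sinusoid
  double R0, R1, t_shift, amplitude, period;
  std::vector<double> Bsum;
  std::vector<int> bcell, bup, bdown, bleft, bright;

  Model(int nx_, int ny_, bool periodic)
    : nx(nx_), ny(ny_), ncell(nx_ * ny_), Bsum(nx_ * ny_) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        if (ix > 0 && ix < nx - 1 && iy > 0 && iy < ny - 1) continue;
        int c = ix + iy * nx;
        int ixm = ix - 1, ixp = ix + 1, iym = iy - 1, iyp = iy + 1;
        if (periodic) {
          ixm = (ix + nx - 1) % nx; ixp = (ix + 1) % nx;
          iym = (iy + ny - 1) % ny; iyp = (iy + 1) % ny;
        } else {
          if (ixm < 0) ixm = ix; if (ixp >= nx) ixp = ix;
          if (iym < 0) iym = iy; if (iyp >= ny) iyp = iy;
        }
        bcell.push_back(c);
        bup.push_back(ixm + iy * nx);
        bdown.push_back(ixp + iy * nx);
        bleft.push_back(ix + iym * nx);
        bright.push_back(ix + iyp * nx);
      }
    }
  }

  double rainfall(double t) const {
    switch (rain_mode) {
      case 1: return t < t_shift ? R0 : R1;
      case 2: return R0 + amplitude * std::sin(2.0 * M_PI * t / period);
      default: return R0;
    }
  }

  inline void cell_flux(const double *O, const double *W, const double *Bs,
                        int c, double lapO, double lapW, double R,
                        double *dO, double *dW) const {
    double denom = (infil_water ? W[c] : Bs[c]) + k2;
    double inf = alpha * O[c] * (Bs[c] + k2 * W0) / denom;
    double upt = g_max * W[c] / (W[c] + k1) * Bs[c];
    dO[c] = R - inf + D_O * lapO;
    dW[c] = inf - upt - r_w * W[c] + D_W * lapW;
  }

  void rhs(const std::vector<double> &Ov, const std::vector<double> &Wv,
           const std::vector<double> &Bv, const std::vector<int> &pidx,
           double R, std::vector<double> &dOv, std::vector<double> &dWv,
           std::vector<double> &dBv) {
    const int np = (int)Bv.size();
    const double *O = Ov.data(), *W = Wv.data(), *B = Bv.data();
    double *dO = dOv.data(), *dW = dWv.data(), *dB = dBv.data();
    double *Bs = Bsum.data();
    std::fill(Bsum.begin(), Bsum.end(), 0.0);
    for (int i = 0; i < np; ++i) Bs[pidx[i]] += B[i] * inv_area;
    for (int iy = 1; iy < ny - 1; ++iy) {
      const int row = iy * nx;
      for (int ix = 1; ix < nx - 1; ++ix) {
        const int c = ix + row;
        double lapO = (O[c - 1] + O[c + 1] + O[c - nx] + O[c + nx]
                       - 4.0 * O[c]) * inv_dx2;
        double lapW = (W[c - 1] + W[c + 1] + W[c - nx] + W[c + nx]
                       - 4.0 * W[c]) * inv_dx2;
        cell_flux(O, W, Bs, c, lapO, lapW, R, dO, dW);
      }
    }
    for (size_t j = 0; j < bcell.size(); ++j) {
      const int c = bcell[j];
      double lapO = (O[bup[j]] + O[bdown[j]] + O[bleft[j]] + O[bright[j]]
                     - 4.0 * O[c]) * inv_dx2;
      double lapW = (W[bup[j]] + W[bdown[j]] + W[bleft[j]] + W[bright[j]]
                     - 4.0 * W[c]) * inv_dx2;
      cell_flux(O, W, Bs, c, lapO, lapW, R, dO, dW);
    }
    const double bg = b * g_max, invKp = 1.0 / Kp;
    for (int i = 0; i < np; ++i) {
      double wl = W[pidx[i]];
      dB[i] = B[i] * (bg * (1.0 - B[i] * invKp) * wl / (wl + k1) - d);
    }
  }

  // advance (O, W, B) over nsub RK4 sub-steps of size h from time t;
  // returns the number of negativity clamps applied
  long integrate_event(std::vector<double> &O, std::vector<double> &W,
                       std::vector<double> &B, const std::vector<int> &pidx,
                       double t, double h, int nsub) {
    const int np = (int)B.size();
    std::vector<double> k1O(ncell), k1W(ncell), k2O(ncell), k2W(ncell),
        k3O(ncell), k3W(ncell), k4O(ncell), k4W(ncell), tO(ncell),
        tW(ncell);
    std::vector<double> k1B(np), k2B(np), k3B(np), k4B(np), tB(np);
    long clamps = 0;
    for (int s = 0; s < nsub; ++s) {
      double ts = t + s * h;
      double Ra = rainfall(ts), Rm = rainfall(ts + 0.5 * h),
             Rb = rainfall(ts + h);
      rhs(O, W, B, pidx, Ra, k1O, k1W, k1B);
      for (int c = 0; c < ncell; ++c) {
        tO[c] = O[c] + 0.5 * h * k1O[c];
        tW[c] = W[c] + 0.5 * h * k1W[c];
      }
      for (int i = 0; i < np; ++i) tB[i] = B[i] + 0.5 * h * k1B[i];
      rhs(tO, tW, tB, pidx, Rm, k2O, k2W, k2B);
      for (int c = 0; c < ncell; ++c) {
        tO[c] = O[c] + 0.5 * h * k2O[c];
        tW[c] = W[c] + 0.5 * h * k2W[c];
      }
      for (int i = 0; i < np; ++i) tB[i] = B[i] + 0.5 * h * k2B[i];
      rhs(tO, tW, tB, pidx, Rm, k3O, k3W, k3B);
      for (int c = 0; c < ncell; ++c) {
        tO[c] = O[c] + h * k3O[c];
        tW[c] = W[c] + h * k3W[c];
      }
      for (int i = 0; i < np; ++i) tB[i] = B[i] + h * k3B[i];
      rhs(tO, tW, tB, pidx, Rb, k4O, k4W, k4B);
      const double w = h / 6.0;
      for (int c = 0; c < ncell; ++c) {
        O[c] += w * (k1O[c] + 2.0 * k2O[c] + 2.0 * k3O[c] + k4O[c]);
        W[c] += w * (k1W[c] + 2.0 * k2W[c] + 2.0 * k3W[c] + k4W[c]);
        if (O[c] < 0) { O[c] = 0; ++clamps; }
        if (W[c] < 0) { W[c] = 0; ++clamps; }
      }
      for (int i = 0; i < np; ++i) {
        B[i] += w * (k1B[i] + 2.0 * k2B[i] + 2.0 * k3B[i] + k4B[i]);
        if (B[i] < 0) { B[i] = 0; ++clamps; }
      }
    }
    for (int c = 0; c < ncell; ++c)
      if (R_IsNaN(O[c]) || R_IsNaN(W[c]))
        stop("water integration became unstable (NaN); reduce dt_int");
    for (int i = 0; i < np; ++i)
      if (R_IsNaN(B[i]))
        stop("plant biomass integration became unstable (NaN); reduce dt_int");
    return clamps;
  }
};

static void fill_params(Model &m, const List &par) {
  double dx = as<double>(par["dx"]);
  m.inv_dx2 = 1.0 / (dx * dx);
  m.inv_area = 1.0 / (dx * dx);
  m.alpha = as<double>(par["alpha"]);
  m.k2 = as<double>(par["k2"]);
  m.W0 = as<double>(par["W0"]);
  m.r_w = as<double>(par["r_w"]);
  m.D_O = as<double>(par["D_O"]);
  m.D_W = as<double>(par["D_W"]);
  m.g_max = as<double>(par["g_max"]);
  m.k1 = as<double>(par["k1"]);
  m.b = as<double>(par["b"]);
  m.Kp = as<double>(par["Kp"]);
  m.d = as<double>(par["d"]);
  m.infil_water =
    as<std::string>(par["infiltration_denominator"]) == "water";
}

// One event-step's worth of coupled RK4 integration with a fixed
// population (no lifecycle events): the continuous block in isolation.
// Rstage is ignored for rainfall if par carries rain fields; instead the
// scalar rain values for the stage times are taken from Rstage (length
// 2*nsub + 1, rain at t0 + j*h/2).
// [[Rcpp::export(name = ".rk4_coupled")]]
List rk4_coupled(NumericMatrix O_in, NumericMatrix W_in, NumericVector B_in,
                 IntegerVector pidx1, NumericVector Rstage, List par,
                 double h, int nsub) {
  const int nx = O_in.nrow(), ny = O_in.ncol();
  if (nx < 2 || ny < 2) stop("grid must be at least 2 x 2 parcels");
  Model m(nx, ny, as<std::string>(par["boundary"]) == "periodic");
  fill_params(m, par);
  // encode the piecewise rainfall stages through a lookup: emulate with
  // constant-mode sub-steps by running one sub-step at a time
  std::vector<double> O(O_in.begin(), O_in.end());
  std::vector<double> W(W_in.begin(), W_in.end());
  std::vector<double> B(B_in.begin(), B_in.end());
  std::vector<int> pidx(B.size());
  for (size_t i = 0; i < B.size(); ++i) pidx[i] = pidx1[i] - 1;
  long clamps = 0;
  m.rain_mode = 0;
  for (int s = 0; s < nsub; ++s) {
    // stage rains: start, midpoint, end of this sub-step
    double Ra = Rstage[2 * s], Rm = Rstage[2 * s + 1],
           Rb = Rstage[2 * s + 2];
    // use sinusoid-free path: temporary shift mode emulation is
    // unnecessary; a 3-point linear forcing is close enough only if the
    // three values are used exactly, so integrate one sub-step with a
    // local lambda-like trick: set mode to piecewise via R1/t_shift.
    // Simplest exact approach: constant rain per stage triple.
    if (Ra == Rb && Ra == Rm) {
      m.R0 = Ra;
      clamps += m.integrate_event(O, W, B, pidx, 0.0, h, 1);
    } else {
      // exact stage values for time-varying rain: replicate the RK4
      // update with explicit stage rains
      m.R0 = Ra;  // not used below; kept for clarity
      const int ncell = m.ncell, np = (int)B.size();
      std::vector<double> k1O(ncell), k1W(ncell), k2O(ncell), k2W(ncell),
          k3O(ncell), k3W(ncell), k4O(ncell), k4W(ncell), tO(ncell),
          tW(ncell);
      std::vector<double> k1B(np), k2B(np), k3B(np), k4B(np), tB(np);
      m.rhs(O, W, B, pidx, Ra, k1O, k1W, k1B);
      for (int c = 0; c < ncell; ++c) {
        tO[c] = O[c] + 0.5 * h * k1O[c];
        tW[c] = W[c] + 0.5 * h * k1W[c];
      }
      for (int i = 0; i < np; ++i) tB[i] = B[i] + 0.5 * h * k1B[i];
      m.rhs(tO, tW, tB, pidx, Rm, k2O, k2W, k2B);
      for (int c = 0; c < ncell; ++c) {
        tO[c] = O[c] + 0.5 * h * k2O[c];
        tW[c] = W[c] + 0.5 * h * k2W[c];
      }
      for (int i = 0; i < np; ++i) tB[i] = B[i] + 0.5 * h * k2B[i];
      m.rhs(tO, tW, tB, pidx, Rm, k3O, k3W, k3B);
      for (int c = 0; c < ncell; ++c) {
        tO[c] = O[c] + h * k3O[c];
        tW[c] = W[c] + h * k3W[c];
      }
      for (int i = 0; i < np; ++i) tB[i] = B[i] + h * k3B[i];
      m.rhs(tO, tW, tB, pidx, Rb, k4O, k4W, k4B);
      const double w = h / 6.0;
      for (int c = 0; c < ncell; ++c) {
        O[c] += w * (k1O[c] + 2.0 * k2O[c] + 2.0 * k3O[c] + k4O[c]);
        W[c] += w * (k1W[c] + 2.0 * k2W[c] + 2.0 * k3W[c] + k4W[c]);
        if (O[c] < 0) { O[c] = 0; ++clamps; }
        if (W[c] < 0) { W[c] = 0; ++clamps; }
      }
      for (int i = 0; i < np; ++i) {
        B[i] += w * (k1B[i] + 2.0 * k2B[i] + 2.0 * k3B[i] + k4B[i]);
        if (B[i] < 0) { B[i] = 0; ++clamps; }
      }
    }
  }
  NumericMatrix Oo(nx, ny), Wo(nx, ny);
  std::copy(O.begin(), O.end(), Oo.begin());
  std::copy(W.begin(), W.end(), Wo.begin());
  return List::create(_["O"] = Oo, _["W"] = Wo,
                      _["B"] = NumericVector(B.begin(), B.end()),
                      _["n_clamps"] = (double)clamps);
}

// Full hybrid loop over n_steps event steps: continuous block, then the
// discrete lifecycle events, then series bookkeeping.  Returns the final
// state plus the recorded series rows.
// [[Rcpp::export(name = ".run_hybrid")]]
List run_hybrid(NumericMatrix O_in, NumericMatrix W_in, List pop, List par,
                double t0, int n_steps, int next_id, int record_every,
                int step_offset) {
  const int nx = as<int>(par["nx"]), ny = as<int>(par["ny"]);
  if (nx < 2 || ny < 2) stop("grid must be at least 2 x 2 parcels");
  Model m(nx, ny, as<std::string>(par["boundary"]) == "periodic");
  fill_params(m, par);
  m.rain_mode = as<int>(par["rain_mode"]);
  m.R0 = as<double>(par["rain_R0"]);
  m.R1 = as<double>(par["rain_R1"]);
  m.t_shift = as<double>(par["rain_t_shift"]);
  m.amplitude = as<double>(par["rain_amplitude"]);
  m.period = as<double>(par["rain_period"]);

  const double dt_event = as<double>(par["dt_event"]);
  const double dt_int = as<double>(par["dt_int"]);
  const int nsub = (int)std::lround(dt_event / dt_int);
  const double h = dt_event / nsub;
  const double dx = as<double>(par["dx"]);
  const double Lx = nx * dx, Ly = ny * dx;
  const double s_fec = as<double>(par["s"]);
  const double l_life = as<double>(par["l"]);
  const double mat_age = as<double>(par["m"]);
  const double f_m = mat_age > 0 ? l_life / mat_age : 1.0;
  const double mu_disp = as<double>(par["mu_disp"]);
  const double sigma_disp = as<double>(par["sigma_disp"]);
  const double meanlog = std::log(mu_disp) - sigma_disp * sigma_disp / 2.0;
  const double K_a = as<double>(par["K_a"]);
  const double d_b = as<double>(par["d_b"]);
  const bool age_mort = as<bool>(par["age_mortality_enabled"]);
  const bool age_cutoff =
    as<std::string>(par["age_mortality_mode"]) == "cutoff";
  const bool preemptive = as<bool>(par["preemptive_seedling_removal"]);
  const double p_age_step =
    1.0 - std::pow(1.0 - 1.0 / l_life, dt_event);

  // population state
  IntegerVector id0 = pop["id"];
  NumericVector x0 = pop["x"], y0 = pop["y"], age0 = pop["age"],
                B0 = pop["B"], Bmax0 = pop["Bmax"];
  std::vector<int> id(id0.begin(), id0.end());
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      age(age0.begin(), age0.end()), B(B0.begin(), B0.end()),
      Bmax(Bmax0.begin(), Bmax0.end());
  std::vector<double> O(O_in.begin(), O_in.end());
  std::vector<double> W(W_in.begin(), W_in.end());
  std::vector<int> pidx(B.size());
  auto parcel_of = [&](double px, double py) {
    int ix = (int)(px / dx); if (ix >= nx) ix = nx - 1;
    int iy = (int)(py / dx); if (iy >= ny) iy = ny - 1;
    return ix + iy * nx;
  };
  for (size_t i = 0; i < B.size(); ++i) pidx[i] = parcel_of(x[i], y[i]);

  long clamps = 0;
  long ev_births = 0, ev_dstress = 0, ev_dage = 0, ev_lost = 0,
       ev_blocked = 0;
  int n_rec = n_steps / record_every + 2;
  NumericMatrix series(n_rec, 6);  // time, n, totB, sumAge, nSeedling, --
  int k_rec = 0;

  std::vector<double> Bsum_g(m.ncell);
  std::vector<double> cx, cy;  // seed candidates
  std::vector<int> cslot;

  for (int step = 1; step <= n_steps; ++step) {
    double t = t0 + (step - 1) * dt_event;
    // (1) continuous block
    clamps += m.integrate_event(O, W, B, pidx, t, h, nsub);
    const int n = (int)B.size();
    for (int i = 0; i < n; ++i) if (B[i] > Bmax[i]) Bmax[i] = B[i];

    // (2) discrete lifecycle events
    // seed production and dispersal
    cx.clear(); cy.clear();
    for (int i = 0; i < n; ++i) {
      if (age[i] < mat_age) continue;
      double E = B[i] * s_fec * f_m * dt_event;
      int nsd = (int)std::floor(E);
      if (unif_rand() < E - nsd) ++nsd;
      for (int k = 0; k < nsd; ++k) {
        double theta = 2.0 * M_PI * unif_rand();
        double dist = R::rlnorm(meanlog, sigma_disp);
        double sx = x[i] + dist * std::cos(theta);
        double sy = y[i] + dist * std::sin(theta);
        if (sx < 0 || sx >= Lx || sy < 0 || sy >= Ly) { ++ev_lost; }
        else { cx.push_back(sx); cy.push_back(sy); }
      }
    }
    int ncand = (int)cx.size();
    int nborn = 0;
    std::vector<double> bx, by;
    if (ncand) {
      // Fisher-Yates shuffle for randomized establishment order
      for (int j = ncand - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(cx[j], cx[k]);
        std::swap(cy[j], cy[k]);
      }
      std::fill(Bsum_g.begin(), Bsum_g.end(), 0.0);
      for (int i = 0; i < n; ++i) Bsum_g[pidx[i]] += B[i];
      const double cap = K_a * dx * dx;  // grams per parcel
      for (int j = 0; j < ncand; ++j) {
        int p = parcel_of(cx[j], cy[j]);
        bool ok = Bsum_g[p] <= cap;
        if (ok && preemptive) {
          double wl = W[p];
          double gr = m.b * m.g_max * (1.0 - 1.0 / m.Kp) * wl / (wl + m.k1)
                      - m.d;
          ok = gr > 0;
        }
        if (ok) {
          bx.push_back(cx[j]); by.push_back(cy[j]);
          Bsum_g[p] += 1.0;
          ++nborn;
        } else ++ev_blocked;
      }
    }
    // stochastic death (stress takes precedence in the accounting),
    // then aging of the established plants
    int keep = 0;
    for (int i = 0; i < n; ++i) {
      bool die = false;
      double ratio = B[i] / Bmax[i];
      double u = unif_rand();
      if (ratio < d_b) {
        double p_day = 1.0 - B[i] / (d_b * Bmax[i]);
        if (p_day > 1.0) p_day = 1.0;
        double ps = 1.0 - std::pow(1.0 - p_day, dt_event);
        if (u < ps) { die = true; ++ev_dstress; }
      }
      if (age_mort && !die) {
        if (age_cutoff) {
          if (age[i] >= l_life) { die = true; ++ev_dage; }
        } else {
          if (unif_rand() < p_age_step) { die = true; ++ev_dage; }
        }
      } else if (age_mort && !age_cutoff) {
        unif_rand();  // keep one draw per plant per hazard
      }
      if (!die) {
        if (keep != i) {
          id[keep] = id[i]; x[keep] = x[i]; y[keep] = y[i];
          age[keep] = age[i]; B[keep] = B[i]; Bmax[keep] = Bmax[i];
          pidx[keep] = pidx[i];
        }
        age[keep] += dt_event;
        ++keep;
      }
    }
    id.resize(keep); x.resize(keep); y.resize(keep); age.resize(keep);
    B.resize(keep); Bmax.resize(keep); pidx.resize(keep);
    for (int j = 0; j < nborn; ++j) {
      id.push_back(next_id++);
      x.push_back(bx[j]); y.push_back(by[j]);
      age.push_back(0.0); B.push_back(1.0); Bmax.push_back(1.0);
      pidx.push_back(parcel_of(bx[j], by[j]));
    }
    ev_births += nborn;

    // (3) series bookkeeping
    if ((step_offset + step) % record_every == 0) {
      double totB = 0, sumAge = 0; int nsdl = 0;
      for (size_t i = 0; i < B.size(); ++i) {
        totB += B[i]; sumAge += age[i];
        if (age[i] < 30.0) ++nsdl;
      }
      series(k_rec, 0) = t0 + step * dt_event;
      series(k_rec, 1) = (double)B.size();
      series(k_rec, 2) = totB;
      series(k_rec, 3) = sumAge;
      series(k_rec, 4) = (double)nsdl;
      ++k_rec;
    }
  }

  NumericMatrix Oo(nx, ny), Wo(nx, ny);
  std::copy(O.begin(), O.end(), Oo.begin());
  std::copy(W.begin(), W.end(), Wo.begin());
  return List::create(
    _["O"] = Oo, _["W"] = Wo,
    _["pop"] = List::create(
      _["id"] = IntegerVector(id.begin(), id.end()),
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["age"] = NumericVector(age.begin(), age.end()),
      _["B"] = NumericVector(B.begin(), B.end()),
      _["Bmax"] = NumericVector(Bmax.begin(), Bmax.end())),
    _["next_id"] = next_id,
    _["events"] = NumericVector::create(
      _["births"] = (double)ev_births,
      _["deaths_stress"] = (double)ev_dstress,
      _["deaths_age"] = (double)ev_dage,
      _["seeds_lost"] = (double)ev_lost,
      _["blocked"] = (double)ev_blocked),
    _["n_clamps"] = (double)clamps,
    _["series"] = series, _["k_rec"] = k_rec);
}
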