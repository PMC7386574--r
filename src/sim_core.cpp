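// Daily loop of the individual-based grassland simulator.
//
// Semantics mirror the exported R building blocks exactly (geometry.R,
// physiology.R, demography.R, soil.R); the loop is compiled because
// calibration experiments run the simulator thousands of times.
//
// Individuals of one species that emerged on the same day stay bit-identical
// forever: every within-day update is deterministic given community state,
// and the only stochastic process acting on an existing plant is whether it
// dies. The loop therefore tracks emergence cohorts as states with a count.
// Intrinsic mortality becomes binomial thinning and crowding decrements the
// count of a state chosen with probability proportional to its count — both
// distributionally identical to per-individual draws, at a fraction of the
// cost.
//
// All randomness goes through R's RNG (RNGScope), so set.seed() in R governs
// reproducibility of seed rain, mortality and crowding.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// trait matrix column indices (one row per species)
enum {
  T_HMAX, T_HW, T_FS, T_FO, T_SLA, T_SR, T_SEEDRAIN, T_TMETA, T_TEM,
  T_GERM, T_HMIN_CM, T_AGEREP_D, T_LLS, T_RLS, T_MSEED, T_MBASIC_D,
  T_PMAX, T_ALPHA, T_K, T_M, T_WUE, T_CNG, T_CNS, T_ALLOC, T_RM, T_RG,
  T_NCOL
};

// config vector indices
enum {
  C_PATCH, C_T0, C_T1, C_ODM, C_PETSHARE, C_WCAP, C_WINIT, C_NINIT,
  C_MINRATE, C_NDEP, C_SEEDDUR, C_FALL, C_STARV, C_CROWDBIAS, C_NCONF
};

struct Cohort { int sp; int due; double count; };

// one state = `cnt` identical individuals
struct Plants {
  std::vector<int> sp;
  std::vector<double> cnt, age, h, w, sg, ss, rt;
  size_t n() const { return sp.size(); }
  void push(int s, double c, double a, double hh, double ww,
            double g, double se, double r) {
    sp.push_back(s); cnt.push_back(c); age.push_back(a);
    h.push_back(hh); w.push_back(ww);
    sg.push_back(g); ss.push_back(se); rt.push_back(r);
  }
  void erase_at(size_t i) {            // swap-with-last removal
    size_t last = n() - 1;
    sp[i] = sp[last]; cnt[i] = cnt[last]; age[i] = age[last];
    h[i] = h[last]; w[i] = w[last];
    sg[i] = sg[last]; ss[i] = ss[last]; rt[i] = rt[last];
    sp.pop_back(); cnt.pop_back(); age.pop_back(); h.pop_back();
    w.pop_back(); sg.pop_back(); ss.pop_back(); rt.pop_back();
  }
};

static inline double cyl_mass(double fs, double w, double h) {
  return fs * (M_PI / 4.0) * w * w * h;
}

// geometry update: isometric growth path, h_max cap, post-mowing height
// regrowth at fixed width (see update_dimensions() in R)
static inline void update_dims(double B, double hw, double fs, double hmax,
                               double &h, double &w) {
  if (B <= 0) { h = 0; w = 0; return; }
  double h_need = (w > 0) ? B / (fs * (M_PI / 4.0) * w * w) : R_PosInf;
  if (h_need >= hw * w) {
    w = std::cbrt(4.0 * B / (M_PI * fs * hw));
    h = hw * w;
    if (h > hmax) {
      h = hmax;
      w = std::sqrt(4.0 * B / (M_PI * fs * hmax));
    }
  } else if (h_need > hmax) {
    h = hmax;
    w = std::sqrt(4.0 * B / (M_PI * fs * hmax));
  } else {
    h = h_need;
  }
}

// closed-form whole-plant gross photosynthesis per m^2 covered ground
static inline double p_area_rate(double I, double lai, double pmax,
                                 double alpha, double k, double m) {
  double aki = alpha * k * I;
  double pm1 = pmax * (1.0 - m);
  return (pmax / k) * std::log((aki + pm1) / (aki * std::exp(-k * lai) + pm1));
}

// [[Rcpp::export]]
List sim_core(NumericMatrix traits, NumericMatrix climate, IntegerVector doy,
              IntegerVector mow_day, NumericVector mow_height,
              IntegerVector census_day, NumericVector config,
              Nullable<NumericMatrix> init_plants) {
  RNGScope rngscope;
  const int nsp = traits.nrow();
  const int ndays = climate.nrow();
  const double patch = config[C_PATCH];
  const double patch_m2 = patch / 1e4;
  const double T0 = config[C_T0], T1 = config[C_T1];
  const double odm = config[C_ODM];
  const double pet_share = config[C_PETSHARE];
  const double wcap = config[C_WCAP];
  const double minrate = config[C_MINRATE];
  const double ndep = config[C_NDEP];
  const double seed_dur = config[C_SEEDDUR];
  const double fall_rate = config[C_FALL];
  const double starv = config[C_STARV];
  const bool crowd_inverse = config[C_CROWDBIAS] > 0.5;

  Plants P;
  if (init_plants.isNotNull()) {
    NumericMatrix ip(init_plants);
    for (int i = 0; i < ip.nrow(); ++i)
      P.push((int)ip(i, 0), 1.0, ip(i, 1), ip(i, 2), ip(i, 3),
             ip(i, 4), ip(i, 5), ip(i, 6));
  }
  std::vector<Cohort> cohorts;

  // soil state
  double water = config[C_WINIT], mineralN = config[C_NINIT];
  double la_mass = 0, la_N = 0, lb_mass = 0, lb_N = 0;
  double f_water = 1.0, f_nitrogen = 1.0;   // previous day's supply ratios

  // cumulative bookkeeping
  double cum_gpp = 0, cum_resp = 0, cum_litter = 0, cum_harvest = 0,
         cum_recruit = 0, cum_precip = 0, cum_evap = 0, cum_wsupply = 0,
         cum_drain = 0, cum_litterN = 0, cum_dep = 0, cum_nsupply = 0;
  double discarded_seeds = 0;

  const int ncens = census_day.size();
  NumericMatrix cen_agb(ncens, nsp), cen_cover(ncens, nsp),
                cen_lai(ncens, nsp), cen_hsp(ncens, nsp);
  NumericMatrix cen_comm(ncens, 4);   // agb, cover, lai, height
  NumericVector harvest_events(mow_day.size());

  const int NLOG = 27;
  NumericMatrix daily(ndays, NLOG);

  // per-day mow/census lookups (days are 1-based indices into climate)
  std::vector<int> mow_at(ndays + 1, -1), cens_at(ndays + 1, -1);
  for (int i = 0; i < mow_day.size(); ++i) {
    int d = mow_day[i];
    if (d >= 1 && d <= ndays) mow_at[d] = i;
  }
  for (int i = 0; i < ncens; ++i) {
    int d = census_day[i];
    if (d >= 1 && d <= ndays) cens_at[d] = i;
  }

  // per-species trait cache (hot-loop reads)
  std::vector<double> sp_hmax(nsp), sp_hw(nsp), sp_fs(nsp), sp_fo(nsp),
      sp_sla(nsp), sp_sr(nsp), sp_lls(nsp), sp_rls(nsp), sp_mseed(nsp),
      sp_mbasic(nsp), sp_agerep(nsp), sp_pmax(nsp), sp_alpha(nsp),
      sp_k(nsp), sp_m(nsp), sp_wue(nsp), sp_cng(nsp), sp_cns(nsp),
      sp_alloc(nsp), sp_rm(nsp), sp_rg(nsp);
  for (int s = 0; s < nsp; ++s) {
    sp_hmax[s] = traits(s, T_HMAX); sp_hw[s] = traits(s, T_HW);
    sp_fs[s] = traits(s, T_FS); sp_fo[s] = traits(s, T_FO);
    sp_sla[s] = traits(s, T_SLA); sp_sr[s] = traits(s, T_SR);
    sp_lls[s] = traits(s, T_LLS); sp_rls[s] = traits(s, T_RLS);
    sp_mseed[s] = traits(s, T_MSEED); sp_mbasic[s] = traits(s, T_MBASIC_D);
    sp_agerep[s] = traits(s, T_AGEREP_D);
    sp_pmax[s] = traits(s, T_PMAX); sp_alpha[s] = traits(s, T_ALPHA);
    sp_k[s] = traits(s, T_K); sp_m[s] = traits(s, T_M);
    sp_wue[s] = traits(s, T_WUE); sp_cng[s] = traits(s, T_CNG);
    sp_cns[s] = traits(s, T_CNS); sp_alloc[s] = traits(s, T_ALLOC);
    sp_rm[s] = traits(s, T_RM); sp_rg[s] = traits(s, T_RG);
  }

  // scratch buffers
  struct HA { double h; double a; };
  std::vector<HA> ha;
  std::vector<double> suffA, suffAH, kabove;

  for (int d = 1; d <= ndays; ++d) {
    const double tmean = climate(d - 1, 0);
    const double par = climate(d - 1, 1);
    const double dl = climate(d - 1, 2);
    const double precip = climate(d - 1, 3);
    const double pet = climate(d - 1, 4);
    const int jd = doy[d - 1];

    // (1) seed rain -----------------------------------------------------
    for (int s = 0; s < nsp; ++s) {
      double tmeta = traits(s, T_TMETA);
      if (jd >= tmeta && jd < tmeta + seed_dur) {
        double lam = traits(s, T_SEEDRAIN) * traits(s, T_GERM) * patch_m2;
        double cnt = R::rpois(lam);
        if (cnt > 0) {
          Cohort c; c.sp = s; c.due = d + (int)traits(s, T_TEM); c.count = cnt;
          cohorts.push_back(c);
        }
      }
    }

    // (2) emergence under the space budget -------------------------------
    // cohorts due today are processed in random order so that no species has
    // a positional priority on the free space
    double used = 0;
    for (size_t i = 0; i < P.n(); ++i)
      used += P.cnt[i] * sp_fo[P.sp[i]] * (M_PI / 4.0) * P.w[i] * P.w[i];
    std::vector<size_t> due;
    for (size_t ci = 0; ci < cohorts.size(); ++ci)
      if (cohorts[ci].due == d) due.push_back(ci);
    for (size_t i = due.size(); i > 1; --i) {
      size_t j = (size_t)std::floor(unif_rand() * i);
      if (j >= i) j = i - 1;
      std::swap(due[i - 1], due[j]);
    }
    for (size_t di = 0; di < due.size(); ++di) {
      size_t ci = due[di];
      int s = cohorts[ci].sp;
      double h0 = traits(s, T_HMIN_CM);
      double w0 = h0 / traits(s, T_HW);
      double sg0 = cyl_mass(traits(s, T_FS), w0, h0);
      double rt0 = sg0 / traits(s, T_SR);
      double a0 = traits(s, T_FO) * (M_PI / 4.0) * w0 * w0;
      double room = std::floor((patch - used) / a0);
      double fit = std::max(0.0, std::min(cohorts[ci].count, room));
      if (fit > 0)
        P.push(s, fit, 0.0, h0, w0, sg0, 0.0, rt0);
      used += fit * a0;
      cum_recruit += fit * (sg0 + rt0);
      discarded_seeds += cohorts[ci].count - fit;
      cohorts[ci].count = -1.0;   // processed: swept out below
    }
    if (!due.empty())
      cohorts.erase(std::remove_if(cohorts.begin(), cohorts.end(),
                                   [](const Cohort &c) { return c.count < 0; }),
                    cohorts.end());

    const size_t n0 = P.n();

    // (3) canopy light profile ------------------------------------------
    double f_temp_day = (tmean - T0) / (T1 - T0);
    f_temp_day = std::min(1.0, std::max(0.0, f_temp_day));
    const double I0 = (par > 0 && dl > 0) ? par * 1e6 / (dl * 3600.0) : 0.0;
    kabove.assign(n0, 0.0);
    // gross production is zeroed by f_temp on frozen days; skip the canopy
    // profile (and the per-plant light math below) entirely then
    if (n0 > 0 && I0 > 0 && f_temp_day > 0) {
      ha.resize(n0);
      for (size_t i = 0; i < n0; ++i) {
        int s = P.sp[i];
        ha[i].h = P.h[i];
        ha[i].a = (P.h[i] > 0)
                    ? P.cnt[i] * sp_k[s] * sp_sla[s] * P.sg[i] /
                        (patch * P.h[i])
                    : 0.0;
      }
      std::sort(ha.begin(), ha.end(),
                [](const HA &x, const HA &y) { return x.h < y.h; });
      suffA.assign(n0 + 1, 0.0);
      suffAH.assign(n0 + 1, 0.0);
      for (int i = (int)n0 - 1; i >= 0; --i) {
        suffA[i] = suffA[i + 1] + ha[i].a;
        suffAH[i] = suffAH[i + 1] + ha[i].a * ha[i].h;
      }
      for (size_t i = 0; i < n0; ++i) {
        double hi = P.h[i];
        size_t pos = std::upper_bound(ha.begin(), ha.end(), hi,
                       [](double v, const HA &x) { return v < x.h; }) -
                     ha.begin();
        kabove[i] = suffAH[pos] - hi * suffA[pos];
      }
    }

    // (4) limitation factors (water/N lagged one day) --------------------
    const double f_temp = f_temp_day;
    const double flim = f_temp * f_water * f_nitrogen;

    // (5) carbon update per state (each of its cnt individuals alike) -----
    double day_gpp = 0, day_resp = 0, wdemand = 0, ndemand = 0;
    double dpot_w = 0, dpot_n = 0;   // temperature-limited potential demands
    double li_am = 0, li_aN = 0, li_bm = 0, li_bN = 0;  // today's litter
    for (size_t i = 0; i < n0; ++i) {
      int s = P.sp[i];
      const double pmax = sp_pmax[s], alpha = sp_alpha[s],
                   kk = sp_k[s], mm = sp_m[s];
      const double c = P.cnt[i];
      double cover = (M_PI / 4.0) * P.w[i] * P.w[i];
      double la = sp_sla[s] * P.sg[i];
      double gpp = 0;
      if (cover > 0 && la > 0 && I0 > 0 && f_temp > 0) {
        double Itop = I0 * std::exp(-kabove[i]);
        if (Itop > 0) {
          double lai_ind = la / cover;
          gpp = p_area_rate(Itop, lai_ind, pmax, alpha, kk, mm) *
                (cover / 1e4) * dl * 3600.0 * 44e-6 * odm;
        }
      }
      double gpp_lim = gpp * flim;
      double Rm = sp_rm[s] * (P.sg[i] + P.rt[i]);
      double npp = 0, resp;
      bool alive = true;
      if (gpp_lim >= Rm) {
        double surplus = gpp_lim - Rm;
        npp = (1.0 - sp_rg[s]) * surplus;
        resp = Rm + sp_rg[s] * surplus;
        P.sg[i] += sp_alloc[s] * npp;
        P.rt[i] += (1.0 - sp_alloc[s]) * npp;
      } else {
        double deficit = Rm - gpp_lim;
        double live = P.sg[i] + P.rt[i];
        if (deficit >= live) {
          resp = gpp_lim + live;
          li_am += c * P.ss[i];
          li_aN += c * P.ss[i] / sp_cns[s];
          P.sg[i] = 0; P.rt[i] = 0; P.ss[i] = 0;
          alive = false;
        } else {
          resp = Rm;
          double f = 1.0 - deficit / live;
          P.sg[i] *= f; P.rt[i] *= f;
        }
      }
      if (alive) {
        double sen = P.sg[i] / sp_lls[s];
        P.sg[i] -= sen; P.ss[i] += sen;
        double fall = P.ss[i] * fall_rate;
        P.ss[i] -= fall;
        double rloss = P.rt[i] / sp_rls[s];
        P.rt[i] -= rloss;
        li_am += c * fall;        li_aN += c * fall / sp_cns[s];
        li_bm += c * rloss;       li_bN += c * rloss / sp_cns[s];
        P.age[i] += 1.0;
        update_dims(P.sg[i] + P.ss[i], sp_hw[s], sp_fs[s],
                    sp_hmax[s], P.h[i], P.w[i]);
      } else {
        P.h[i] = 0; P.w[i] = 0;
        P.sg[i] = -1;             // flag: removed by the mortality sweep below
      }
      day_gpp += c * gpp_lim;
      day_resp += c * resp;
      wdemand += c * gpp_lim / sp_wue[s];
      ndemand += c * npp / sp_cng[s];
      // potential (soil-unlimited) demands drive tomorrow's supply ratios;
      // using them instead of the realized demand keeps the feedback map
      // contractive (no period-2 on/off oscillation when the bucket empties)
      double gpp_pot = gpp * f_temp;
      dpot_w += c * gpp_pot / sp_wue[s];
      dpot_n += c * (1.0 - sp_rg[s]) * std::max(0.0, gpp_pot - Rm) /
                sp_cng[s];
    }

    // (6) intrinsic + starvation mortality -------------------------------
    // deaths within a state are binomial thinning: individuals are identical
    // and die independently with the same daily probability
    for (size_t i = 0; i < P.n(); ) {
      int s = P.sp[i];
      double deaths = 0;
      if (P.sg[i] < 0) {          // starved outright during carbon update
        P.sg[i] = 0;
        deaths = P.cnt[i];        // pools already zero; litter already booked
        P.cnt[i] = 0;
      } else if (P.sg[i] < starv) {   // deterministic starvation floor
        deaths = P.cnt[i];
        P.cnt[i] = 0;
        double shoot = P.sg[i] + P.ss[i];
        li_am += deaths * shoot;      li_aN += deaths * shoot / sp_cns[s];
        li_bm += deaths * P.rt[i];    li_bN += deaths * P.rt[i] / sp_cns[s];
      } else {
        double p = (P.age[i] < sp_agerep[s]) ? sp_mseed[s] : sp_mbasic[s];
        deaths = R::rbinom(P.cnt[i], p);
        if (deaths > 0) {
          P.cnt[i] -= deaths;
          double shoot = P.sg[i] + P.ss[i];
          li_am += deaths * shoot;    li_aN += deaths * shoot / sp_cns[s];
          li_bm += deaths * P.rt[i];  li_bN += deaths * P.rt[i] / sp_cns[s];
        }
      }
      if (P.cnt[i] <= 0) P.erase_at(i); else ++i;
    }

    // (7) crowding (self-thinning) ---------------------------------------
    // one individual at a time: a state is hit with probability proportional
    // to its count (uniform rule) or count / size (inverse-size rule)
    {
      double total = 0, n_ind = 0, wsum = 0;
      std::vector<double> area(P.n());
      for (size_t i = 0; i < P.n(); ++i) {
        area[i] = sp_fo[P.sp[i]] * (M_PI / 4.0) * P.w[i] * P.w[i];
        total += P.cnt[i] * area[i];
        n_ind += P.cnt[i];
        if (crowd_inverse)
          wsum += P.cnt[i] / std::max(P.sg[i] + P.ss[i], 1e-9);
      }
      while (total > patch && P.n() > 0) {
        size_t v = P.n() - 1;
        if (!crowd_inverse) {
          double u = unif_rand() * n_ind, acc = 0;
          for (size_t i = 0; i < P.n(); ++i) {
            acc += P.cnt[i];
            if (u <= acc) { v = i; break; }
          }
        } else {
          double u = unif_rand() * wsum, acc = 0;
          for (size_t i = 0; i < P.n(); ++i) {
            acc += P.cnt[i] / std::max(P.sg[i] + P.ss[i], 1e-9);
            if (u <= acc) { v = i; break; }
          }
        }
        int s = P.sp[v];
        double shoot = P.sg[v] + P.ss[v];
        li_am += shoot;            li_aN += shoot / sp_cns[s];
        li_bm += P.rt[v];          li_bN += P.rt[v] / sp_cns[s];
        total -= area[v];
        n_ind -= 1.0;
        if (crowd_inverse)
          wsum -= 1.0 / std::max(P.sg[v] + P.ss[v], 1e-9);
        P.cnt[v] -= 1.0;
        if (P.cnt[v] <= 0) {
          area[v] = area[P.n() - 1];
          area.pop_back();
          P.erase_at(v);
        }
      }
    }

    // (8) soil water -----------------------------------------------------
    double evap = std::min(pet_share * pet, water + precip);
    double avail = water + precip - evap;
    double wsupply = std::min(wdemand, avail);
    double woffer = std::min(dpot_w, avail);
    double w2 = avail - wsupply;
    double drain = std::max(0.0, w2 - wcap);
    water = w2 - drain;

    // (9) soil nitrogen ---------------------------------------------------
    la_mass += li_am; la_N += li_aN; lb_mass += li_bm; lb_N += li_bN;
    double mineralized = minrate * (la_N + lb_N);
    la_mass *= (1 - minrate); la_N *= (1 - minrate);
    lb_mass *= (1 - minrate); lb_N *= (1 - minrate);
    mineralN += mineralized + ndep;
    double nsupply = std::min(ndemand, mineralN);
    double noffer = std::min(dpot_n, mineralN);
    mineralN -= nsupply;

    f_water = (dpot_w > 1e-12) ? std::min(1.0, woffer / dpot_w) : 1.0;
    f_nitrogen = (dpot_n > 1e-12) ? std::min(1.0, noffer / dpot_n) : 1.0;

    // (10) mowing ----------------------------------------------------------
    if (mow_at[d] >= 0) {
      double cut = mow_height[mow_at[d]];
      double harv = 0;
      for (size_t i = 0; i < P.n(); ++i) {
        if (P.h[i] > cut) {
          double frac = cut / P.h[i];
          double shoot = P.sg[i] + P.ss[i];
          harv += P.cnt[i] * shoot * (1.0 - frac);
          P.sg[i] *= frac; P.ss[i] *= frac;
          P.h[i] = cut;
        }
      }
      harvest_events[mow_at[d]] = harv;
      cum_harvest += harv;
    }

    // cumulative bookkeeping ----------------------------------------------
    cum_gpp += day_gpp; cum_resp += day_resp;
    cum_litter += li_am + li_bm;
    cum_litterN += li_aN + li_bN;
    cum_precip += precip; cum_evap += evap; cum_wsupply += wsupply;
    cum_drain += drain; cum_dep += ndep; cum_nsupply += nsupply;

    // (11) census ----------------------------------------------------------
    if (cens_at[d] >= 0) {
      int ci = cens_at[d];
      double c_agb = 0, c_cov = 0, c_lai = 0, c_h = 0;
      for (int s = 0; s < nsp; ++s) {
        double agb = 0, cov = 0, lai = 0, hmax_s = 0;
        for (size_t i = 0; i < P.n(); ++i) {
          if (P.sp[i] != s) continue;
          agb += P.cnt[i] * (P.sg[i] + P.ss[i]);
          cov += P.cnt[i] * sp_fo[s] * (M_PI / 4.0) * P.w[i] * P.w[i];
          lai += P.cnt[i] * sp_sla[s] * P.sg[i];
          if (P.h[i] > hmax_s) hmax_s = P.h[i];
        }
        cen_agb(ci, s) = agb / patch_m2;
        cen_cover(ci, s) = 100.0 * cov / patch;
        cen_lai(ci, s) = lai / patch;
        cen_hsp(ci, s) = hmax_s;
        c_agb += agb / patch_m2; c_cov += 100.0 * cov / patch;
        c_lai += lai / patch;
        if (hmax_s > c_h) c_h = hmax_s;
      }
      cen_comm(ci, 0) = c_agb; cen_comm(ci, 1) = c_cov;
      cen_comm(ci, 2) = c_lai; cen_comm(ci, 3) = c_h;
    }

    // (12) daily log --------------------------------------------------------
    double living = 0, excl = 0, hmax_all = 0, agb_tot = 0, n_ind = 0;
    for (size_t i = 0; i < P.n(); ++i) {
      living += P.cnt[i] * (P.sg[i] + P.ss[i] + P.rt[i]);
      agb_tot += P.cnt[i] * (P.sg[i] + P.ss[i]);
      excl += P.cnt[i] * sp_fo[P.sp[i]] * (M_PI / 4.0) * P.w[i] * P.w[i];
      n_ind += P.cnt[i];
      if (P.h[i] > hmax_all) hmax_all = P.h[i];
    }
    int col = 0;
    daily(d - 1, col++) = n_ind;
    daily(d - 1, col++) = excl;
    daily(d - 1, col++) = hmax_all;
    daily(d - 1, col++) = living;
    daily(d - 1, col++) = cum_gpp;
    daily(d - 1, col++) = cum_resp;
    daily(d - 1, col++) = cum_litter;
    daily(d - 1, col++) = cum_harvest;
    daily(d - 1, col++) = cum_recruit;
    daily(d - 1, col++) = water;
    daily(d - 1, col++) = mineralN;
    daily(d - 1, col++) = la_mass;
    daily(d - 1, col++) = la_N;
    daily(d - 1, col++) = lb_mass;
    daily(d - 1, col++) = lb_N;
    daily(d - 1, col++) = cum_precip;
    daily(d - 1, col++) = cum_evap;
    daily(d - 1, col++) = cum_wsupply;
    daily(d - 1, col++) = cum_drain;
    daily(d - 1, col++) = cum_litterN;
    daily(d - 1, col++) = cum_dep;
    daily(d - 1, col++) = cum_nsupply;
    daily(d - 1, col++) = f_water;
    daily(d - 1, col++) = f_nitrogen;
    daily(d - 1, col++) = wdemand;
    daily(d - 1, col++) = ndemand;
    daily(d - 1, col++) = agb_tot;
  }

  // final plant table: one row per state with its individual count
  NumericMatrix fin(P.n(), 8);
  for (size_t i = 0; i < P.n(); ++i) {
    fin(i, 0) = P.sp[i]; fin(i, 1) = P.age[i]; fin(i, 2) = P.h[i];
    fin(i, 3) = P.w[i]; fin(i, 4) = P.sg[i]; fin(i, 5) = P.ss[i];
    fin(i, 6) = P.rt[i]; fin(i, 7) = P.cnt[i];
  }

  return List::create(
    _["census_agb"] = cen_agb, _["census_cover"] = cen_cover,
    _["census_lai"] = cen_lai, _["census_height_sp"] = cen_hsp,
    _["census_community"] = cen_comm,
    _["daily"] = daily,
    _["harvest_events"] = harvest_events,
    _["discarded_seeds"] = discarded_seeds,
    _["final_plants"] = fin);
}
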