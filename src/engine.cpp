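// Exact stochastic simulation of CheR / CheB-P adaptation kinetics on a
// receptor lattice.  Event channels:
//   bulk enzyme -> free tether (uniform over free tethers; tether sites in
//     excess so the propensity is per-enzyme, not per-site);
//   bulk enzyme -> free modification site, weighted by (1-a) of the target
//     complex for CheR and by a for CheB-P;
//   tethered enzyme -> modification site of its own dimer or any assistance
//     neighbor (neighbor part disabled when neighbor_binding = false, M2),
//     same activity weighting;
//   modification-site-bound enzyme -> tether of its own dimer or neighbors
//     (brachiation hand-over-hand move);
//   tether release (scaled by tether_unbind_scale, M3) and modification-site
//     release; catalysis (CheR +1 methyl if < methyl_max, CheB-P -1 if > 0),
//     with the modification-site bond released on catalysis;
//   bulk CheB <-> CheB-P conversion driven by mean lattice activity.
// Only bulk CheB participates in (de)phosphorylation and only CheB-P can
// bind the lattice.  Activities are equilibrium MWC probabilities per
// 6-dimer complex, cached and refreshed on methylation/ligand changes;
// cached aggregates are rebuilt from scratch periodically to kill drift.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Species {
  double ktb;    // bulk -> tether
  double ktu;    // tether unbind (already scaled for M3)
  double kmbb;   // bulk -> modsite, per unit weight, aggregate over lattice
  double kml;    // tethered -> modsite, per target dimer per unit weight
  double ktl;    // modsite-bound -> tether, per free target tether
  double kmu;    // modsite unbind
  double kcat;   // catalysis
};

struct Enzyme {
  int species;   // 0 = CheR, 1 = CheB
  int phos;      // CheB only; CheR always 1 (irrelevant)
  int teth;      // dimer index or -1
  int mod;       // dimer index or -1
  // processivity bookkeeping
  int residence;       // residence counter (increments on localization)
  double loc_since;
  double loc_time;
  int unique_visits;
};

struct Engine {
  // geometry
  int n, ncx;
  std::vector<std::vector<int>> nbr;   // neighbors
  std::vector<int> cxof;               // dimer -> complex
  std::vector<std::vector<int>> cxd;   // complex -> 6 dimers
  // MWC
  double Nmwc, eps_m, m_half, K_off, K_on;
  double L;                            // current ligand (uM)
  // rates / flags
  Species sp[2];
  double a_p, d_p;
  bool neighbor_binding, tethering, release_on_catalysis;
  int methyl_max;
  // state
  std::vector<int> methyl;             // per dimer 0..methyl_max
  std::vector<int> teth_occ, mod_occ;  // enzyme id or -1
  std::vector<Enzyme> enz;
  std::vector<int> mcx;                // complex methylation totals
  std::vector<double> acx;             // complex activities
  int nR, nB;
  // caches
  double sum_a;                        // sum of complex activities
  double W_R, W_B;                     // sum over free modsites of (1-a), a
  int n_free_teth;
  std::vector<double> eprop;           // per-enzyme propensity
  double esum;
  // processivity stamps
  std::vector<int> stamp;              // enz * n + dimer -> residence id
  // logs
  bool log_contacts;
  std::vector<double> log_t;
  std::vector<int> log_e, log_d, log_k;  // kind 0 contact, 1 localize, 2 delocalize
  std::vector<double> evcount;         // per channel family

  double act_of(int mtot) const {
    double F = eps_m * (m_half - mtot) +
      Nmwc * std::log((1.0 + L / K_off) / (1.0 + L / K_on));
    return 1.0 / (1.0 + std::exp(F));
  }
  double weight(int species, int d) const {
    double a = acx[cxof[d]];
    return species == 0 ? (1.0 - a) : a;
  }
  bool localized(const Enzyme& e) const { return e.teth >= 0 || e.mod >= 0; }

  int n_bulk(int species, int phos_req) const {
    int k = 0;
    for (const auto& e : enz)
      if (e.species == species && !localized(e) && e.phos == phos_req) ++k;
    return k;
  }

  // cached bulk counts, maintained incrementally
  int nbulkR, nbulkBp, nbulkB0;

  void rebuild_bulk_counts() {
    nbulkR = n_bulk(0, 1);
    nbulkBp = n_bulk(1, 1);
    nbulkB0 = n_bulk(1, 0);
  }

  void rebuild_activity() {
    sum_a = 0.0;
    for (int c = 0; c < ncx; ++c) {
      mcx[c] = 0;
      for (int d : cxd[c]) mcx[c] += methyl[d];
      acx[c] = act_of(mcx[c]);
      sum_a += acx[c];
    }
    W_R = W_B = 0.0;
    n_free_teth = 0;
    for (int d = 0; d < n; ++d) {
      if (mod_occ[d] < 0) { W_R += 1.0 - acx[cxof[d]]; W_B += acx[cxof[d]]; }
      if (teth_occ[d] < 0) ++n_free_teth;
    }
  }

  // propensity of one enzyme's private channels
  double enzyme_prop(int ei) const {
    const Enzyme& e = enz[ei];
    if (!localized(e)) return 0.0;
    const Species& s = sp[e.species];
    double p = 0.0;
    if (e.teth >= 0 && e.mod < 0) {
      p += s.ktu;
      p += local_mod_prop(ei);
    } else if (e.mod >= 0 && e.teth < 0) {
      p += s.kmu;
      p += cat_prop(ei);
      p += local_teth_prop(ei);
    } else {  // both
      p += s.ktu + s.kmu + cat_prop(ei);
    }
    return p;
  }
  double cat_prop(int ei) const {
    const Enzyme& e = enz[ei];
    const Species& s = sp[e.species];
    int m = methyl[e.mod];
    if (e.species == 0) return m < methyl_max ? s.kcat : 0.0;
    return m > 0 ? s.kcat : 0.0;
  }
  double local_mod_prop(int ei) const {
    const Enzyme& e = enz[ei];
    const Species& s = sp[e.species];
    double p = 0.0;
    int home = e.teth;
    if (mod_occ[home] < 0) p += s.kml * weight(e.species, home);
    if (neighbor_binding)
      for (int d : nbr[home])
        if (mod_occ[d] < 0) p += s.kml * weight(e.species, d);
    return p;
  }
  double local_teth_prop(int ei) const {
    const Enzyme& e = enz[ei];
    const Species& s = sp[e.species];
    double p = 0.0;
    int home = e.mod;
    if (teth_occ[home] < 0) p += s.ktl;
    if (neighbor_binding)
      for (int d : nbr[home])
        if (teth_occ[d] < 0) p += s.ktl;
    return p;
  }

  void set_eprop(int ei) {
    double np = enzyme_prop(ei);
    esum += np - eprop[ei];
    eprop[ei] = np;
  }
  void rebuild_eprops() {
    esum = 0.0;
    for (size_t i = 0; i < enz.size(); ++i) {
      eprop[i] = enzyme_prop((int)i);
      esum += eprop[i];
    }
  }

  // refresh enzymes whose channels reference dimer d (occupants of d and of
  // its neighbors; with neighbor binding off only occupants of d itself can
  // target it, but its own occupants always need a refresh)
  void touch_dimer(int d) {
    refresh_occupants(d);
    if (neighbor_binding)
      for (int d2 : nbr[d]) refresh_occupants(d2);
  }
  void refresh_occupants(int d) {
    if (teth_occ[d] >= 0) set_eprop(teth_occ[d]);
    if (mod_occ[d] >= 0 && mod_occ[d] != teth_occ[d]) set_eprop(mod_occ[d]);
  }

  // processivity: enzyme ei now occupies a site on dimer d
  void mark_contact(int ei, int d, double t, int kind) {
    Enzyme& e = enz[ei];
    if (stamp[(size_t)ei * n + d] != e.residence) {
      stamp[(size_t)ei * n + d] = e.residence;
      e.unique_visits += 1;
      if (log_contacts) {
        log_t.push_back(t); log_e.push_back(ei); log_d.push_back(d);
        log_k.push_back(kind);
      }
    }
  }
  void localize(int ei, double t) {
    Enzyme& e = enz[ei];
    e.residence += 1;
    e.loc_since = t;
    if (e.species == 0) --nbulkR; else --nbulkBp;
    if (log_contacts) {
      log_t.push_back(t); log_e.push_back(ei); log_d.push_back(-1);
      log_k.push_back(1);
    }
  }
  void delocalize(int ei, double t) {
    Enzyme& e = enz[ei];
    e.loc_time += t - e.loc_since;
    if (e.species == 0) ++nbulkR; else ++nbulkBp;
    if (log_contacts) {
      log_t.push_back(t); log_e.push_back(ei); log_d.push_back(-1);
      log_k.push_back(2);
    }
  }

  // ---- site occupancy transitions (maintain caches) ----
  void occupy_teth(int ei, int d) {
    teth_occ[d] = ei; enz[ei].teth = d; --n_free_teth;
  }
  void vacate_teth(int ei) {
    int d = enz[ei].teth;
    teth_occ[d] = -1; enz[ei].teth = -1; ++n_free_teth;
  }
  void occupy_mod(int ei, int d) {
    mod_occ[d] = ei; enz[ei].mod = d;
    W_R -= 1.0 - acx[cxof[d]]; W_B -= acx[cxof[d]];
  }
  void vacate_mod(int ei) {
    int d = enz[ei].mod;
    mod_occ[d] = -1; enz[ei].mod = -1;
    W_R += 1.0 - acx[cxof[d]]; W_B += acx[cxof[d]];
  }

  void apply_methyl(int d, int delta, double t) {
    methyl[d] += delta;
    int c = cxof[d];
    double a_old = acx[c];
    mcx[c] += delta;
    acx[c] = act_of(mcx[c]);
    double da = acx[c] - a_old;
    sum_a += da;
    int nfree = 0;
    for (int dd : cxd[c]) if (mod_occ[dd] < 0) ++nfree;
    W_R -= da * nfree;
    W_B += da * nfree;
    // activity-weighted channels of enzymes that can reach complex c
    for (int dd : cxd[c]) touch_dimer(dd);
    (void)t;
  }

  void set_ligand(double Lnew) {
    L = Lnew;
    rebuild_activity();
    rebuild_eprops();
  }

  // pick a uniformly random free tether; exact because the target is
  // uniform over free tethers and the propensity does not depend on which
  void pick_free_teth(int& d) {
    for (int tries = 0; tries < 100000; ++tries) {
      int cand = (int)(unif_rand() * n);
      if (cand >= n) cand = n - 1;
      if (teth_occ[cand] < 0) { d = cand; return; }
    }
    stop("no free tether site found");
  }
  // weighted free modsite: rejection against weight in [0,1]
  int pick_weighted_mod(int species) {
    for (int tries = 0; tries < 200000; ++tries) {
      int cand = (int)(unif_rand() * n);
      if (cand >= n) cand = n - 1;
      if (mod_occ[cand] >= 0) continue;
      if (unif_rand() < weight(species, cand)) return cand;
    }
    // exact fallback: cumulative scan
    double W = species == 0 ? W_R : W_B;
    double u = unif_rand() * W, acc = 0.0;
    int last_free = -1;
    for (int d = 0; d < n; ++d) {
      if (mod_occ[d] < 0) {
        last_free = d;
        acc += weight(species, d);
        if (acc >= u) return d;
      }
    }
    if (last_free >= 0) return last_free;  // roundoff at u ~ W
    stop("weighted modification-site selection failed");
  }
  int pick_bulk(int species, int phos_req) {
    int k = 0;
    for (size_t i = 0; i < enz.size(); ++i) {
      const Enzyme& e = enz[i];
      if (e.species == species && !localized(e) && e.phos == phos_req) ++k;
    }
    if (k == 0) stop("internal: empty bulk pool drawn");
    int pick = (int)(unif_rand() * k);
    if (pick >= k) pick = k - 1;
    int seen = 0;
    for (size_t i = 0; i < enz.size(); ++i) {
      const Enzyme& e = enz[i];
      if (e.species == species && !localized(e) && e.phos == phos_req) {
        if (seen == pick) return (int)i;
        ++seen;
      }
    }
    stop("internal: bulk pool scan failed");
  }

  void audit() const {
    int nfree = 0;
    for (int d = 0; d < n; ++d) {
      if (methyl[d] < 0 || methyl[d] > methyl_max)
        stop("audit: methylation out of range");
      if (teth_occ[d] >= 0 && enz[teth_occ[d]].teth != d)
        stop("audit: tether occupancy inconsistent");
      if (mod_occ[d] >= 0 && enz[mod_occ[d]].mod != d)
        stop("audit: modsite occupancy inconsistent");
      if (teth_occ[d] < 0) ++nfree;
    }
    if (nfree != n_free_teth) stop("audit: free tether count drifted");
    int locR = 0, locB = 0, bR = 0, bBp = 0, bB0 = 0;
    for (const auto& e : enz) {
      if (e.teth >= 0 && e.mod >= 0 && e.mod != e.teth) {
        // a doubly bound enzyme reaches only its assistance neighborhood
        bool ok = false;
        if (neighbor_binding)
          for (int d2 : nbr[e.teth]) if (d2 == e.mod) { ok = true; break; }
        if (!ok) stop("audit: doubly bound enzyme spans non-neighbors");
      }
      if (e.species == 1 && e.phos == 0 && localized(e))
        stop("audit: unphosphorylated CheB bound to the lattice");
      if (localized(e)) { if (e.species == 0) ++locR; else ++locB; }
      else if (e.species == 0) ++bR;
      else if (e.phos == 1) ++bBp;
      else ++bB0;
    }
    if (locR + bR != nR || locB + bBp + bB0 != nB)
      stop("audit: enzyme conservation violated");
    if (bR != nbulkR || bBp != nbulkBp || bB0 != nbulkB0)
      stop("audit: bulk pool counters drifted");
  }
};

}  // namespace

// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(List geom, List rates, List mwc, List init,
             NumericMatrix lgrid, double duration, double record_dt,
             bool log_contacts, int rebuild_every = 65536) {
  Engine E;
  // ---- geometry ----
  E.n = as<int>(geom["n_dimers"]);
  E.ncx = as<int>(geom["n_complexes"]);
  IntegerMatrix nbm = geom["neighbors0"];   // n x 6, -1 padded, 0-based
  E.nbr.assign(E.n, {});
  for (int d = 0; d < E.n; ++d)
    for (int j = 0; j < nbm.ncol(); ++j)
      if (nbm(d, j) >= 0) E.nbr[d].push_back(nbm(d, j));
  IntegerVector cxof = geom["complex_of0"];
  E.cxof.assign(cxof.begin(), cxof.end());
  IntegerMatrix cxm = geom["complexes0"];
  E.cxd.assign(E.ncx, {});
  for (int c = 0; c < E.ncx; ++c)
    for (int j = 0; j < 6; ++j) E.cxd[c].push_back(cxm(c, j));
  // ---- MWC ----
  E.Nmwc = as<double>(mwc["N"]); E.eps_m = as<double>(mwc["eps_m"]);
  E.m_half = as<double>(mwc["m_half"]);
  E.K_off = as<double>(mwc["K_off"]); E.K_on = as<double>(mwc["K_on"]);
  // ---- rates ----
  double scale = as<double>(rates["tether_unbind_scale"]);
  const char* nmr[2] = {"r", "b"};
  for (int s = 0; s < 2; ++s) {
    std::string suf = std::string("_") + nmr[s];
    E.sp[s].ktb = as<double>(rates[std::string("k_t_bind") + suf]);
    E.sp[s].ktu = as<double>(rates[std::string("k_t_unbind") + suf]) * scale;
    E.sp[s].kmbb = as<double>(rates[std::string("k_m_bind_bulk") + suf]);
    E.sp[s].kml = as<double>(rates[std::string("k_m_bind_local") + suf]);
    E.sp[s].ktl = as<double>(rates[std::string("k_t_bind_local") + suf]);
    E.sp[s].kmu = as<double>(rates[std::string("k_m_unbind") + suf]);
    E.sp[s].kcat = as<double>(rates[std::string("k_cat") + suf]);
  }
  E.a_p = as<double>(rates["a_p"]); E.d_p = as<double>(rates["d_p"]);
  E.neighbor_binding = as<bool>(rates["neighbor_binding"]);
  E.tethering = as<bool>(rates["tethering"]);
  E.release_on_catalysis = as<bool>(rates["release_on_catalysis"]);
  E.methyl_max = as<int>(rates["methyl_max"]);
  if (!E.tethering) { E.sp[0].ktb = E.sp[1].ktb = 0.0; }
  // ---- state ----
  IntegerVector methyl0 = init["methyl"];
  if ((int)methyl0.size() != E.n) stop("init methylation has wrong length");
  E.methyl.assign(methyl0.begin(), methyl0.end());
  IntegerVector esp = init["species"], eph = init["phos"],
    ete = init["teth0"], emo = init["mod0"];
  int nEnz = esp.size();
  E.enz.resize(nEnz);
  E.teth_occ.assign(E.n, -1); E.mod_occ.assign(E.n, -1);
  E.nR = E.nB = 0;
  for (int i = 0; i < nEnz; ++i) {
    Enzyme& e = E.enz[i];
    e.species = esp[i]; e.phos = eph[i]; e.teth = ete[i]; e.mod = emo[i];
    e.residence = 0; e.loc_since = 0.0; e.loc_time = 0.0; e.unique_visits = 0;
    if (e.species == 0) { ++E.nR; e.phos = 1; } else ++E.nB;
    if (e.teth >= 0) {
      if (E.teth_occ[e.teth] >= 0) stop("init: tether doubly occupied");
      E.teth_occ[e.teth] = i;
    }
    if (e.mod >= 0) {
      if (E.mod_occ[e.mod] >= 0) stop("init: modsite doubly occupied");
      E.mod_occ[e.mod] = i;
    }
  }
  E.mcx.assign(E.ncx, 0); E.acx.assign(E.ncx, 0.0);
  E.L = lgrid(0, 1);
  E.rebuild_activity();
  E.rebuild_bulk_counts();
  E.eprop.assign(nEnz, 0.0);
  E.rebuild_eprops();
  E.stamp.assign((size_t)nEnz * E.n, -1);
  E.log_contacts = log_contacts;
  E.evcount.assign(12, 0.0);
  // residences that begin localized count from t = 0
  for (int i = 0; i < nEnz; ++i)
    if (E.localized(E.enz[i])) {
      E.enz[i].residence = 1; E.enz[i].loc_since = 0.0;
      if (E.enz[i].teth >= 0) E.mark_contact(i, E.enz[i].teth, 0.0, 0);
      if (E.enz[i].mod >= 0) E.mark_contact(i, E.enz[i].mod, 0.0, 0);
    }
  E.audit();

  // ---- recording ----
  int nrec = (int)std::floor(duration / record_dt + 1e-9) + 1;
  std::vector<double> rec_t(nrec), rec_a(nrec), rec_m(nrec);
  std::vector<int> rec_locR(nrec), rec_locB(nrec), rec_locB_act(nrec),
    rec_bulkBp(nrec), rec_bulkB(nrec);
  int irec = 0;
  int igrid = 0;  // current ligand segment
  auto record_row = [&](double t) {
    rec_t[irec] = t;
    rec_a[irec] = E.sum_a / E.ncx;
    long mt = 0; for (int d = 0; d < E.n; ++d) mt += E.methyl[d];
    rec_m[irec] = (double)mt / E.ncx;
    int lr = 0, lb = 0, inert = 0;
    for (const auto& e : E.enz) {
      if (!E.localized(e)) continue;
      if (e.species == 0) { ++lr; continue; }
      ++lb;
      // inert CheB-P: every dimer reachable from its bound sites fully
      // demethylated
      bool any = false;
      int homes[2] = {e.teth, e.mod};
      for (int hh = 0; hh < 2 && !any; ++hh) {
        int h = homes[hh];
        if (h < 0) continue;
        if (E.methyl[h] > 0) any = true;
        if (E.neighbor_binding)
          for (int d2 : E.nbr[h]) if (E.methyl[d2] > 0) { any = true; break; }
      }
      if (!any) ++inert;
    }
    rec_locR[irec] = lr; rec_locB[irec] = lb; rec_locB_act[irec] = lb - inert;
    rec_bulkBp[irec] = E.nbulkBp; rec_bulkB[irec] = E.nbulkB0;
    ++irec;
  };
  record_row(0.0);

  double t = 0.0;
  double next_rec = record_dt;
  long long events = 0;
  while (t < duration - 1e-12) {
    // next breakpoint: record time or ligand-grid change
    double next_break = std::min(next_rec, duration);
    double lig_t = R_PosInf;
    if (igrid + 1 < lgrid.nrow()) lig_t = lgrid(igrid + 1, 0);
    if (lig_t < next_break) next_break = lig_t;

    double g[6];
    g[0] = (E.n_free_teth > 0) ? E.sp[0].ktb * E.nbulkR : 0.0;
    g[1] = (E.n_free_teth > 0) ? E.sp[1].ktb * E.nbulkBp : 0.0;
    g[2] = E.sp[0].kmbb * E.nbulkR * (E.W_R / E.n);
    g[3] = E.sp[1].kmbb * E.nbulkBp * (E.W_B / E.n);
    g[4] = E.a_p * (E.sum_a / E.ncx) * E.nbulkB0;
    g[5] = E.d_p * E.nbulkBp;
    double gsum = g[0] + g[1] + g[2] + g[3] + g[4] + g[5];
    double total = gsum + E.esum;
    if (!std::isfinite(total) || total < 0)
      stop("propensity sum non-finite at t = %f", t);

    double tau = (total > 0) ? exp_rand() / total : R_PosInf;
    if (t + tau >= next_break) {
      t = next_break;
      if (igrid + 1 < lgrid.nrow() && std::abs(t - lig_t) < 1e-12) {
        ++igrid;
        E.set_ligand(lgrid(igrid, 1));
      }
      while (next_rec <= t + 1e-12 && irec < nrec) {
        record_row(next_rec);
        next_rec += record_dt;
      }
      continue;
    }
    t += tau;
    ++events;
    if (events % rebuild_every == 0) {
      E.rebuild_activity();
      E.rebuild_eprops();
      E.rebuild_bulk_counts();
    }

    double u = unif_rand() * total;
    if (u < gsum) {
      int ch = 0;
      while (ch < 5 && u >= g[ch]) { u -= g[ch]; ++ch; }
      E.evcount[ch] += 1;
      if (ch == 0 || ch == 1) {           // bulk -> tether
        int speciesw = ch;
        int ei = E.pick_bulk(speciesw, 1);
        int d; E.pick_free_teth(d);
        E.localize(ei, t);
        E.occupy_teth(ei, d);
        E.mark_contact(ei, d, t, 0);
        E.touch_dimer(d);
      } else if (ch == 2 || ch == 3) {    // bulk -> modsite
        int speciesw = ch - 2;
        int ei = E.pick_bulk(speciesw, 1);
        int d = E.pick_weighted_mod(speciesw);
        E.localize(ei, t);
        E.occupy_mod(ei, d);
        E.mark_contact(ei, d, t, 0);
        E.touch_dimer(d);
      } else if (ch == 4) {               // phosphorylation
        int ei = E.pick_bulk(1, 0);
        E.enz[ei].phos = 1; --E.nbulkB0; ++E.nbulkBp;
      } else {                            // dephosphorylation
        int ei = E.pick_bulk(1, 1);
        E.enz[ei].phos = 0; ++E.nbulkB0; --E.nbulkBp;
      }
    } else {
      u -= gsum;
      // locate enzyme
      int ei = -1;
      for (int i = 0; i < nEnz; ++i) {
        if (u < E.eprop[i]) { ei = i; break; }
        u -= E.eprop[i];
      }
      if (ei < 0) {  // float roundoff: take last enzyme with positive prop
        for (int i = nEnz - 1; i >= 0; --i)
          if (E.eprop[i] > 0) { ei = i; break; }
        if (ei < 0) stop("enzyme selection failed");
      }
      Enzyme& e = E.enz[ei];
      const Species& s = E.sp[e.species];
      if (e.teth >= 0 && e.mod < 0) {
        if (u < s.ktu) {                          // tether release -> bulk
          E.evcount[6] += 1;
          int d = e.teth;
          E.vacate_teth(ei);
          E.delocalize(ei, t);
          E.set_eprop(ei);
          E.touch_dimer(d);
        } else {                                  // bind local modsite
          u -= s.ktu;
          E.evcount[7] += 1;
          int home = e.teth, target = -1;
          if (E.mod_occ[home] < 0) {
            double w = s.kml * E.weight(e.species, home);
            if (u < w) target = home; else u -= w;
          }
          if (target < 0 && E.neighbor_binding) {
            for (int d : E.nbr[home]) {
              if (E.mod_occ[d] < 0) {
                double w = s.kml * E.weight(e.species, d);
                if (u < w) { target = d; break; }
                u -= w;
              }
            }
          }
          if (target < 0) stop("stale local modsite channel");
          E.occupy_mod(ei, target);
          if (target != home) E.mark_contact(ei, target, t, 0);
          E.touch_dimer(target);
        }
      } else if (e.mod >= 0 && e.teth < 0) {
        if (u < s.kmu) {                          // modsite release -> bulk
          E.evcount[8] += 1;
          int d = e.mod;
          E.vacate_mod(ei);
          E.delocalize(ei, t);
          E.set_eprop(ei);
          E.touch_dimer(d);
        } else if (u < s.kmu + E.cat_prop(ei)) {  // catalysis
          E.evcount[9] += 1;
          int d = e.mod;
          if (E.release_on_catalysis) {
            E.vacate_mod(ei);
            E.delocalize(ei, t);
            E.set_eprop(ei);
          }
          E.apply_methyl(d, e.species == 0 ? 1 : -1, t);
          E.touch_dimer(d);
        } else {                                  // bind local tether
          u -= s.kmu + E.cat_prop(ei);
          E.evcount[10] += 1;
          int home = e.mod, target = -1;
          if (E.teth_occ[home] < 0) {
            if (u < s.ktl) target = home; else u -= s.ktl;
          }
          if (target < 0 && E.neighbor_binding) {
            for (int d : E.nbr[home]) {
              if (E.teth_occ[d] < 0) {
                if (u < s.ktl) { target = d; break; }
                u -= s.ktl;
              }
            }
          }
          if (target < 0) stop("stale local tether channel");
          E.occupy_teth(ei, target);
          if (target != home) E.mark_contact(ei, target, t, 0);
          E.touch_dimer(target);
        }
      } else {  // both bound
        if (u < s.ktu) {                          // tether release, keep mod
          E.evcount[6] += 1;
          int d = e.teth;
          E.vacate_teth(ei);
          E.set_eprop(ei);
          E.touch_dimer(d);
        } else if (u < s.ktu + s.kmu) {           // modsite release, keep teth
          E.evcount[8] += 1;
          int d = e.mod;
          E.vacate_mod(ei);
          E.set_eprop(ei);
          E.touch_dimer(d);
        } else {                                  // catalysis, release modsite
          E.evcount[9] += 1;
          int d = e.mod;
          if (E.release_on_catalysis) {
            E.vacate_mod(ei);
            E.set_eprop(ei);
          }
          E.apply_methyl(d, e.species == 0 ? 1 : -1, t);
          E.touch_dimer(d);
        }
      }
    }
  }
  while (irec < nrec) { record_row(next_rec); next_rec += record_dt; }
  // close residence clocks
  for (auto& e : E.enz)
    if (E.localized(e)) e.loc_time += duration - e.loc_since;
  E.audit();

  DataFrame trace = DataFrame::create(
    _["time"] = rec_t, _["a_mean"] = rec_a, _["m_mean"] = rec_m,
    _["loc_cheR"] = rec_locR, _["loc_cheBp"] = rec_locB,
    _["loc_cheBp_active"] = rec_locB_act,
    _["bulk_cheBp"] = rec_bulkBp, _["bulk_cheB"] = rec_bulkB);
  // per-species processivity summary
  double visits[2] = {0, 0}, loct[2] = {0, 0};
  IntegerVector f_teth(nEnz), f_mod(nEnz), f_phos(nEnz), f_species(nEnz);
  for (int i = 0; i < nEnz; ++i) {
    const Enzyme& e = E.enz[i];
    visits[e.species] += e.unique_visits;
    loct[e.species] += e.loc_time;
    f_teth[i] = e.teth; f_mod[i] = e.mod;
    f_phos[i] = e.species == 0 ? 1 : e.phos;
    f_species[i] = e.species;
  }
  List proc = List::create(
    _["visits_cheR"] = visits[0], _["visits_cheB"] = visits[1],
    _["loc_time_cheR"] = loct[0], _["loc_time_cheB"] = loct[1]);
  List fin = List::create(
    _["methyl"] = IntegerVector(E.methyl.begin(), E.methyl.end()),
    _["species"] = f_species, _["phos"] = f_phos,
    _["teth0"] = f_teth, _["mod0"] = f_mod);
  CharacterVector evnames = CharacterVector::create(
    "bulk_tether_bind_R", "bulk_tether_bind_B", "bulk_mod_bind_R",
    "bulk_mod_bind_B", "phosphorylation", "dephosphorylation",
    "tether_unbind", "local_mod_bind", "mod_unbind", "catalysis",
    "local_tether_bind", "unused");
  NumericVector evc(E.evcount.begin(), E.evcount.end());
  evc.names() = evnames;
  List out = List::create(
    _["trace"] = trace, _["processivity"] = proc, _["final_state"] = fin,
    _["event_counts"] = evc, _["n_events"] = (double)events);
  if (log_contacts) {
    out["contacts"] = DataFrame::create(
      _["time"] = NumericVector(E.log_t.begin(), E.log_t.end()),
      _["enzyme"] = IntegerVector(E.log_e.begin(), E.log_e.end()),
      _["dimer"] = IntegerVector(E.log_d.begin(), E.log_d.end()),
      _["kind"] = IntegerVector(E.log_k.begin(), E.log_k.end()));
  }
  return out;
}
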