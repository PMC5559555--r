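// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
#include "model.h"

using namespace Rcpp;
using sqt::NMC;
using sqt::NRC;
using sqt::NHOST;

static sqt::Geno genoFromList(const List& g) {
  sqt::Geno G;
  G.npop = as<int>(g["npop"]);
  if (G.npop < 0 || G.npop > 2) stop("npop must be 0, 1 or 2");
  G.gks = as<double>(g["gks"]);
  G.block = as<double>(g["block"]);
  if (G.npop > 0) {
    NumericMatrix A = g["a"], B = g["b"];
    NumericVector sc = g["scale"], w = g["w"];
    for (int p = 0; p < G.npop; ++p) {
      for (int k = 0; k < NRC; ++k) {
        G.pop[p].a[k] = A(k, p);
        G.pop[p].b[k] = B(k, p);
      }
      G.pop[p].scale = sc[p];
      G.w[p] = w[p];
    }
  }
  return G;
}

static void fillPop(sqt::IKsPop& P, const NumericVector& a, const NumericVector& b) {
  if (a.size() != NRC || b.size() != NRC)
    stop("rate coefficient vectors must have length 8");
  for (int k = 0; k < NRC; ++k) { P.a[k] = a[k]; P.b[k] = b[k]; }
  P.scale = 1.0;
}

// ---------------------------------------------------------------------------
// Markov chain primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix mcGeneratorCpp(double V, NumericVector a, NumericVector b) {
  if (!std::isfinite(V)) stop("membrane potential must be finite");
  sqt::IKsPop P; fillPop(P, a, b);
  double r[NRC]; sqt::mcRates(P, V, r);
  NumericMatrix Q(NMC, NMC);
  const std::vector<sqt::MCEdge>& E = sqt::mcEdges();
  for (size_t k = 0; k < E.size(); ++k) {
    double rate = E[k].mult * r[E[k].rc];
    Q(E[k].to, E[k].from) += rate;
    Q(E[k].from, E[k].from) -= rate;
  }
  return Q;
}

// [[Rcpp::export]]
NumericVector mcSteadyStateCpp(double V, NumericVector a, NumericVector b) {
  if (!std::isfinite(V)) stop("membrane potential must be finite");
  sqt::IKsPop P; fillPop(P, a, b);
  double r[NRC]; sqt::mcRates(P, V, r);
  arma::mat Q(NMC, NMC, arma::fill::zeros);
  const std::vector<sqt::MCEdge>& E = sqt::mcEdges();
  for (size_t k = 0; k < E.size(); ++k) {
    double rate = E[k].mult * r[E[k].rc];
    Q(E[k].to, E[k].from) += rate;
    Q(E[k].from, E[k].from) -= rate;
  }
  // replace last balance equation with the normalisation constraint
  arma::mat A = Q;
  A.row(NMC - 1).ones();
  arma::vec rhs(NMC, arma::fill::zeros);
  rhs(NMC - 1) = 1.0;
  arma::vec p;
  bool ok = arma::solve(p, A, rhs);
  if (!ok) stop("steady-state solve failed at V = %f mV (rank deficient)", V);
  double mn = p.min();
  if (mn < -1e-9) stop("steady-state solve produced negative occupancy at V = %f mV", V);
  p.clamp(0.0, arma::datum::inf);
  p /= arma::accu(p);
  return wrap(p);
}

// [[Rcpp::export]]
NumericVector mcAdvanceCpp(NumericVector p0, double V, double dt,
                           NumericVector a, NumericVector b,
                           double maxSub = 0.02) {
  if (!std::isfinite(V)) stop("membrane potential must be finite");
  if (dt < 0) stop("dt must be non-negative");
  if (p0.size() != NMC) stop("occupancy vector must have length 17");
  sqt::IKsPop P; fillPop(P, a, b);
  double r[NRC]; sqt::mcRates(P, V, r);
  NumericVector p = clone(p0);
  if (dt > 0) sqt::mcAdvance(REAL(p), r, dt, maxSub);
  return p;
}

// Piecewise-constant voltage-clamp propagation via the exact matrix
// exponential per segment, sampled on a uniform grid.
// segments: two-column matrix (voltage mV, duration ms).
// [[Rcpp::export]]
List mcClampCpp(NumericVector a, NumericVector b, NumericMatrix segments,
                double sampleDt, NumericVector p0, bool keepStates = false) {
  sqt::IKsPop P; fillPop(P, a, b);
  if (p0.size() != NMC) stop("occupancy vector must have length 17");
  int nseg = segments.nrow();
  int ntot = 0;
  for (int s = 0; s < nseg; ++s) {
    double dur = segments(s, 1);
    if (dur <= 0) stop("segment durations must be positive");
    ntot += (int)std::floor(dur / sampleDt + 0.5);
  }
  NumericVector time(ntot + 1), volt(ntot + 1), open(ntot + 1);
  NumericMatrix occ;
  if (keepStates) occ = NumericMatrix(NMC, ntot + 1);
  arma::vec p(NMC);
  for (int i = 0; i < NMC; ++i) p(i) = p0[i];
  int idx = 0;
  double t = 0.0;
  time[0] = 0.0; volt[0] = segments(0, 0);
  open[0] = p(sqt::ST_O1) + p(sqt::ST_O2);
  if (keepStates) for (int i = 0; i < NMC; ++i) occ(i, 0) = p(i);
  for (int s = 0; s < nseg; ++s) {
    double V = segments(s, 0);
    if (!std::isfinite(V)) stop("membrane potential must be finite");
    double r[NRC]; sqt::mcRates(P, V, r);
    arma::mat Q(NMC, NMC, arma::fill::zeros);
    const std::vector<sqt::MCEdge>& E = sqt::mcEdges();
    for (size_t k = 0; k < E.size(); ++k) {
      double rate = E[k].mult * r[E[k].rc];
      Q(E[k].to, E[k].from) += rate;
      Q(E[k].from, E[k].from) -= rate;
    }
    arma::mat Prop = arma::expmat(Q * sampleDt);
    int nk = (int)std::floor(segments(s, 1) / sampleDt + 0.5);
    for (int k = 0; k < nk; ++k) {
      p = Prop * p;
      t += sampleDt;
      ++idx;
      time[idx] = t; volt[idx] = V;
      open[idx] = p(sqt::ST_O1) + p(sqt::ST_O2);
      if (keepStates) for (int i = 0; i < NMC; ++i) occ(i, idx) = p(i);
    }
  }
  List out = List::create(_["time"] = time, _["voltage"] = volt,
                          _["open"] = open, _["final"] = wrap(p));
  if (keepStates) out["occupancy"] = occ;
  return out;
}

// Open probability under an arbitrary sampled voltage command (AP clamp).
// [[Rcpp::export]]
NumericVector mcApClampCpp(NumericVector a, NumericVector b,
                           NumericVector time, NumericVector vm,
                           NumericVector p0, double maxSub = 0.02) {
  sqt::IKsPop P; fillPop(P, a, b);
  int n = time.size();
  if (vm.size() != n) stop("time and voltage vectors must have equal length");
  if (p0.size() != NMC) stop("occupancy vector must have length 17");
  NumericVector open(n);
  double p[NMC];
  for (int i = 0; i < NMC; ++i) p[i] = p0[i];
  open[0] = p[sqt::ST_O1] + p[sqt::ST_O2];
  for (int k = 1; k < n; ++k) {
    double dt = time[k] - time[k - 1];
    if (dt <= 0) stop("time grid must be strictly increasing");
    double r[NRC]; sqt::mcRates(P, vm[k - 1], r);
    sqt::mcAdvance(p, r, dt, maxSub);
    open[k] = p[sqt::ST_O1] + p[sqt::ST_O2];
  }
  return open;
}

// ---------------------------------------------------------------------------
// Single cell
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cellInitStateCpp(List geno) {
  sqt::Geno G = genoFromList(geno);
  NumericVector st(sqt::stateLen(G));
  sqt::initState(REAL(st), G);
  return st;
}

static double stimAt(double t, const NumericVector& stimTimes,
                     double stimAmp, double stimDur) {
  for (int i = 0; i < stimTimes.size(); ++i) {
    double dt = t - stimTimes[i];
    if (dt >= 0 && dt < stimDur) return stimAmp;
    if (stimTimes[i] > t) break;   // stimTimes sorted
  }
  return 0.0;
}

// Simulate one cell for `duration` ms with stimuli at `stimTimes`
// (sorted, ms). Records V and IKs every sampleDt; optional full-state
// snapshots at given times (ms).
// [[Rcpp::export]]
List cellSimulateCpp(NumericVector state, List geno, int celltype,
                     double duration, NumericVector stimTimes,
                     double stimAmp, double stimDur, double dt,
                     double sampleDt,
                     Nullable<NumericVector> snapshotTimes = R_NilValue) {
  sqt::Geno G = genoFromList(geno);
  int slen = sqt::stateLen(G);
  if (state.size() != slen) stop("state vector has wrong length");
  if (dt <= 0 || sampleDt < dt) stop("need dt > 0 and sampleDt >= dt");
  sqt::Tables tb;
  tb.build(dt, celltype, G);
  NumericVector st = clone(state);
  double* S = REAL(st);

  NumericVector snapT;
  if (snapshotTimes.isNotNull()) snapT = NumericVector(snapshotTimes);
  int nsnap = snapT.size(), isnap = 0;
  NumericMatrix snaps(slen, std::max(nsnap, 1));

  long nstep = (long)std::floor(duration / dt + 0.5);
  int sampleEvery = (int)std::floor(sampleDt / dt + 0.5);
  int nsamp = (int)(nstep / sampleEvery) + 1;
  NumericVector time(nsamp), vm(nsamp), iks(nsamp);
  sqt::Revs rv;
  sqt::computeRevs(S, rv);
  double iksNow = 0.0;
  int idx = 0;
  time[0] = 0.0; vm[0] = S[0];
  {
    // record IKs at t=0 without stepping: evaluate via a zero-dt pass
    double open = 0.0;
    if (G.npop == 0) open = -1;
    if (G.npop > 0) {
      for (int p = 0; p < G.npop; ++p) {
        const double* mc = S + NHOST + NMC * p;
        open += G.w[p] * G.pop[p].scale * (mc[sqt::ST_O1] + mc[sqt::ST_O2]);
      }
      iks[0] = G.gks * (1.0 - G.block) * sqt::GksFactorOf(celltype) * open *
               (S[0] - rv.Eks);
    } else {
      iks[0] = sqt::GksNativeOf(celltype) * (1.0 - G.block) * S[18] * S[18] *
               (S[0] - rv.Eks);
    }
  }
  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    if ((k % 25) == 0) sqt::computeRevs(S, rv);
    double istim = stimAt(t, stimTimes, stimAmp, stimDur);
    double dV = sqt::cellStep(S, G, celltype, dt, istim, tb, rv, &iksNow);
    S[0] += dV;
    if (!std::isfinite(S[0]) || std::fabs(S[0]) > 200.0)
      stop("numerical instability: |V| out of range at t = %f ms", t);
    while (isnap < nsnap && snapT[isnap] <= t + dt * 0.5) {
      for (int i = 0; i < slen; ++i) snaps(i, isnap) = S[i];
      ++isnap;
    }
    if (((k + 1) % sampleEvery) == 0) {
      ++idx;
      time[idx] = (k + 1) * dt;
      vm[idx] = S[0];
      iks[idx] = iksNow;
    }
  }
  List out = List::create(_["time"] = time, _["vm"] = vm, _["iks"] = iks,
                          _["state"] = st);
  if (nsnap > 0) out["snapshots"] = snaps;
  return out;
}

// ---------------------------------------------------------------------------
// 1D monodomain strand
// ---------------------------------------------------------------------------

// states: statelen x ncell matrix; celltypes: 0/1/2 per node.
// stims: list of list(sites = 0-based integer vector, start, amp, dur).
// [[Rcpp::export]]
List strandSimulateCpp(NumericMatrix states, IntegerVector celltypes,
                       List geno, double D, double dx, double dt,
                       double duration, List stims, double sampleDt,
                       Nullable<NumericVector> snapshotTimes = R_NilValue,
                       bool keepVmap = true) {
  sqt::Geno G = genoFromList(geno);
  int slen = sqt::stateLen(G);
  int ncell = states.ncol();
  if (states.nrow() != slen) stop("state matrix has wrong row count");
  if (celltypes.size() != ncell) stop("celltypes length mismatch");
  if (dt <= 0 || sampleDt < dt) stop("need dt > 0 and sampleDt >= dt");
  double dco = D * dt / (dx * dx);
  if (dco > 0.5) stop("explicit diffusion unstable: D*dt/dx^2 = %f > 0.5", dco);

  // one table set per cell type present
  sqt::Tables tabs[3];
  bool have[3] = {false, false, false};
  for (int c = 0; c < ncell; ++c) {
    int ct = celltypes[c];
    if (ct < 0 || ct > 2) stop("celltype must be 0, 1 or 2");
    if (!have[ct]) { tabs[ct].build(dt, ct, G); have[ct] = true; }
  }

  int nstim = stims.size();
  std::vector<std::vector<int> > ssites(nstim);
  std::vector<double> sstart(nstim), samp(nstim), sdur(nstim);
  for (int q = 0; q < nstim; ++q) {
    List s = stims[q];
    IntegerVector si = s["sites"];
    ssites[q].assign(si.begin(), si.end());
    sstart[q] = as<double>(s["start"]);
    samp[q] = as<double>(s["amp"]);
    sdur[q] = as<double>(s["dur"]);
  }

  std::vector<double> S(states.begin(), states.end());
  std::vector<sqt::Revs> rv(ncell);
  for (int c = 0; c < ncell; ++c) sqt::computeRevs(&S[(size_t)c * slen], rv[c]);
  std::vector<double> vold(ncell), istim(ncell, 0.0);

  long nstep = (long)std::floor(duration / dt + 0.5);
  int sampleEvery = (int)std::floor(sampleDt / dt + 0.5);
  int nsamp = (int)(nstep / sampleEvery) + 1;
  NumericMatrix vmap(keepVmap ? ncell : 1, keepVmap ? nsamp : 1);
  NumericVector time(nsamp);
  if (keepVmap) for (int c = 0; c < ncell; ++c) vmap(c, 0) = S[(size_t)c * slen];
  time[0] = 0.0;

  NumericVector snapT;
  if (snapshotTimes.isNotNull()) snapT = NumericVector(snapshotTimes);
  int nsnap = snapT.size(), isnap = 0;
  List snaps(std::max(nsnap, 1));

  int idx = 0;
  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    // stimulus currents
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int q = 0; q < nstim; ++q) {
      double rel = t - sstart[q];
      if (rel >= 0 && rel < sdur[q])
        for (size_t m = 0; m < ssites[q].size(); ++m)
          istim[ssites[q][m]] += samp[q];
    }
    bool doRevs = (k % 25) == 0;
    for (int c = 0; c < ncell; ++c) vold[c] = S[(size_t)c * slen];
    for (int c = 0; c < ncell; ++c) {
      double* st = &S[(size_t)c * slen];
      if (doRevs) sqt::computeRevs(st, rv[c]);
      double dV = sqt::cellStep(st, G, celltypes[c], dt, istim[c],
                                tabs[celltypes[c]], rv[c], (double*)0);
      double vl = (c == 0) ? vold[1] : vold[c - 1];
      double vr = (c == ncell - 1) ? vold[ncell - 2] : vold[c + 1];
      st[0] += dV + dco * (vl - 2.0 * vold[c] + vr);
      if (!std::isfinite(st[0]) || std::fabs(st[0]) > 200.0)
        stop("numerical instability at node %d, t = %f ms", c, t);
    }
    while (isnap < nsnap && snapT[isnap] <= t + dt * 0.5) {
      NumericMatrix sm(slen, ncell);
      std::copy(S.begin(), S.end(), sm.begin());
      snaps[isnap] = sm;
      ++isnap;
    }
    if (((k + 1) % sampleEvery) == 0) {
      ++idx;
      time[idx] = (k + 1) * dt;
      if (keepVmap)
        for (int c = 0; c < ncell; ++c) vmap(c, idx) = S[(size_t)c * slen];
    }
  }
  NumericMatrix fin(slen, ncell);
  std::copy(S.begin(), S.end(), fin.begin());
  List out = List::create(_["time"] = time, _["states"] = fin);
  if (keepVmap) out["vmap"] = vmap;
  if (nsnap > 0) out["snapshots"] = snaps;
  return out;
}

// ---------------------------------------------------------------------------
// 2D monodomain sheet (isotropic, no-flux boundaries)
// ---------------------------------------------------------------------------

// celltypes: per-node (length nx*ny, node index = y*nx + x).
// initStates: list of state vectors indexed by celltype + 1 (entries for
// absent types may be NULL).
// S1: columns x < s1Width at t = 0. S2: rectangle [x0,x1] x [y0,y1];
// s2Time < 0 selects the adaptive rule (fire when every node in the S2
// region has repolarised below s2Vtrig after the S1 wave passed).
// [[Rcpp::export]]
List sheetSimulateCpp(int nx, int ny, IntegerVector celltypes, List initStates,
                      List geno, double D, double dx, double dt,
                      double duration, int s1Width, double stimAmp,
                      double stimDur, int s2x0, int s2x1, int s2y0, int s2y1,
                      double s2Time, double s2Vtrig, double meanDt,
                      double snapDt = -1.0, double actThresh = -20.0,
                      double rearmThresh = -50.0) {
  sqt::Geno G = genoFromList(geno);
  int slen = sqt::stateLen(G);
  int nn = nx * ny;
  if (celltypes.size() != nn) stop("celltypes must have length nx*ny");
  if (dt <= 0) stop("dt must be positive");
  double dco = D * dt / (dx * dx);
  if (dco > 0.25) stop("explicit 2D diffusion unstable: D*dt/dx^2 = %f > 0.25", dco);

  sqt::Tables tabs[3];
  bool have[3] = {false, false, false};
  for (int c = 0; c < nn; ++c) {
    int ct = celltypes[c];
    if (ct < 0 || ct > 2) stop("celltype must be 0, 1 or 2");
    if (!have[ct]) { tabs[ct].build(dt, ct, G); have[ct] = true; }
  }

  std::vector<double> S((size_t)nn * slen);
  for (int c = 0; c < nn; ++c) {
    int ct = celltypes[c];
    NumericVector ist = initStates[ct];
    if (ist.size() != slen) stop("initial state has wrong length");
    std::copy(ist.begin(), ist.end(), S.begin() + (size_t)c * slen);
  }
  std::vector<sqt::Revs> rv(nn);
  for (int c = 0; c < nn; ++c) sqt::computeRevs(&S[(size_t)c * slen], rv[c]);

  std::vector<double> vold(nn);
  std::vector<double> lastAct(nn, -1.0);
  std::vector<int> nAct(nn, 0);
  std::vector<char> armed(nn, 1);

  long nstep = (long)std::floor(duration / dt + 0.5);
  int meanEvery = (int)std::floor(meanDt / dt + 0.5);
  int nmean = (int)(nstep / meanEvery) + 1;
  NumericVector meanT(nmean), meanV(nmean);
  {
    double acc = 0.0;
    for (int c = 0; c < nn; ++c) acc += S[(size_t)c * slen];
    meanT[0] = 0.0; meanV[0] = acc / nn;
  }
  int snapEvery = snapDt > 0 ? (int)std::floor(snapDt / dt + 0.5) : -1;
  std::vector<NumericMatrix> snapList;
  std::vector<double> snapTimes;

  bool s2Fired = (s2x1 < s2x0);   // empty region => no S2
  bool s2Armed = false;
  double s2FiredAt = -1.0;
  double s2End = -1.0;

  int imean = 0;
  for (long k = 0; k < nstep; ++k) {
    double t = k * dt;
    bool doRevs = (k % 25) == 0;
    // S2 trigger logic on old voltages: fire when the centroid of the
    // S2 region has repolarised below s2Vtrig while more distal parts of
    // the region are still refractory (partial capture at the border of
    // refractoriness, the substrate for unidirectional block)
    if (!s2Fired && s2Time < 0) {
      int probe = ((s2y0 + s2y1) / 2) * nx + (s2x0 + s2x1) / 2;
      double vprobe = S[(size_t)probe * slen];
      if (!s2Armed && vprobe > 0.0) s2Armed = true;
      if (s2Armed && vprobe < s2Vtrig) {
        s2Fired = true; s2FiredAt = t; s2End = t + stimDur;
      }
    } else if (!s2Fired && s2Time >= 0 && t >= s2Time) {
      s2Fired = true; s2FiredAt = s2Time; s2End = s2Time + stimDur;
    }
    for (int c = 0; c < nn; ++c) vold[c] = S[(size_t)c * slen];
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int c = y * nx + x;
        double* st = &S[(size_t)c * slen];
        if (doRevs) sqt::computeRevs(st, rv[c]);
        double istim = 0.0;
        if (t < stimDur && x < s1Width) istim += stimAmp;
        if (s2FiredAt >= 0 && t >= s2FiredAt && t < s2End &&
            x >= s2x0 && x <= s2x1 && y >= s2y0 && y <= s2y1)
          istim += stimAmp;
        double dV = sqt::cellStep(st, G, celltypes[c], dt, istim,
                                  tabs[celltypes[c]], rv[c], (double*)0);
        double vl = (x == 0) ? ((nx > 1) ? vold[c + 1] : vold[c]) : vold[c - 1];
        double vrt = (x == nx - 1) ? ((nx > 1) ? vold[c - 1] : vold[c]) : vold[c + 1];
        double vd = (y == 0) ? ((ny > 1) ? vold[c + nx] : vold[c]) : vold[c - nx];
        double vu = (y == ny - 1) ? ((ny > 1) ? vold[c - nx] : vold[c]) : vold[c + nx];
        double vnew = vold[c] + dV +
          dco * (vl + vrt + vd + vu - 4.0 * vold[c]);
        st[0] = vnew;
        if (!std::isfinite(vnew) || std::fabs(vnew) > 200.0)
          stop("numerical instability at node (%d,%d), t = %f ms", x, y, t);
        if (armed[c] && vnew >= actThresh) {
          lastAct[c] = t; ++nAct[c]; armed[c] = 0;
        } else if (!armed[c] && vnew < rearmThresh) {
          armed[c] = 1;
        }
      }
    }
    if (((k + 1) % meanEvery) == 0) {
      double acc = 0.0;
      for (int c = 0; c < nn; ++c) acc += S[(size_t)c * slen];
      ++imean;
      meanT[imean] = (k + 1) * dt;
      meanV[imean] = acc / nn;
    }
    if (snapEvery > 0 && ((k + 1) % snapEvery) == 0) {
      NumericMatrix sm(ny, nx);
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) sm(y, x) = S[(size_t)(y * nx + x) * slen];
      snapList.push_back(sm);
      snapTimes.push_back((k + 1) * dt);
    }
    // a fully repolarised monodomain sheet stays quiescent: once all
    // activity is extinguished after S2, stop integrating and pad the
    // mean-signal record with its final (resting) value
    if (s2Fired && s2FiredAt >= 0 && t > s2End + 100.0 && (k % 400) == 0) {
      double vmax = -1e9;
      for (int c = 0; c < nn; ++c) vmax = std::max(vmax, S[(size_t)c * slen]);
      if (vmax < -70.0) {
        double acc = 0.0;
        for (int c = 0; c < nn; ++c) acc += S[(size_t)c * slen];
        double vrest = acc / nn;
        while (imean + 1 < nmean) {
          ++imean;
          meanT[imean] = (double)(imean) * meanDt;
          meanV[imean] = vrest;
        }
        break;
      }
    }
  }
  List snaps(snapList.size());
  for (size_t q = 0; q < snapList.size(); ++q) snaps[q] = snapList[q];
  return List::create(_["meanTime"] = meanT, _["meanV"] = meanV,
                      _["lastActivation"] = wrap(lastAct),
                      _["nActivations"] = wrap(nAct),
                      _["s2Time"] = s2FiredAt,
                      _["snapshots"] = snaps,
                      _["snapshotTimes"] = wrap(snapTimes));
}

// End-of-step open probabilities for the standard activation protocol,
// computed exactly with one matrix exponential per distinct segment
// (fit-objective fast path; the sampled clamp route is mcClampCpp).
// [[Rcpp::export]]
NumericVector mcIvEndOpenCpp(NumericVector a, NumericVector b,
                             double holding, double preV, double preDur,
                             NumericVector potentials, double testDur) {
  sqt::IKsPop P; fillPop(P, a, b);
  const std::vector<sqt::MCEdge>& E = sqt::mcEdges();
  arma::mat Qpre(NMC, NMC, arma::fill::zeros);
  {
    double r[NRC]; sqt::mcRates(P, preV, r);
    for (size_t k = 0; k < E.size(); ++k) {
      double rate = E[k].mult * r[E[k].rc];
      Qpre(E[k].to, E[k].from) += rate;
      Qpre(E[k].from, E[k].from) -= rate;
    }
  }
  arma::mat Ppre = arma::expmat(Qpre * preDur);
  // steady state at holding
  arma::mat Qh(NMC, NMC, arma::fill::zeros);
  {
    double r[NRC]; sqt::mcRates(P, holding, r);
    for (size_t k = 0; k < E.size(); ++k) {
      double rate = E[k].mult * r[E[k].rc];
      Qh(E[k].to, E[k].from) += rate;
      Qh(E[k].from, E[k].from) -= rate;
    }
  }
  arma::mat A = Qh;
  A.row(NMC - 1).ones();
  arma::vec rhs(NMC, arma::fill::zeros);
  rhs(NMC - 1) = 1.0;
  arma::vec p0;
  if (!arma::solve(p0, A, rhs))
    stop("steady-state solve failed at the holding potential");
  p0.clamp(0.0, arma::datum::inf);
  p0 /= arma::accu(p0);
  arma::vec pPre = Ppre * p0;
  int np = potentials.size();
  NumericVector open(np);
  for (int i = 0; i < np; ++i) {
    arma::mat Qt(NMC, NMC, arma::fill::zeros);
    double r[NRC]; sqt::mcRates(P, potentials[i], r);
    for (size_t k = 0; k < E.size(); ++k) {
      double rate = E[k].mult * r[E[k].rc];
      Qt(E[k].to, E[k].from) += rate;
      Qt(E[k].from, E[k].from) -= rate;
    }
    arma::vec pe = arma::expmat(Qt * testDur) * pPre;
    open[i] = pe(sqt::ST_O1) + pe(sqt::ST_O2);
  }
  return open;
}
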