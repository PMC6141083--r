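// Langevin (BAOAB) integrator for the coarse-grained pulling model.
//
// Units: length A, energy kcal/mol, mass amu, time fs.  The conversion
// 1 kcal/mol/A / amu = 4.184e-4 A/fs^2 maps forces to accelerations.
// Thermal noise comes from a mersenne-twister stream seeded from R, so a
// run is a pure function of (model, params, seed).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double KCAL_TO_AKMA = 4.184e-4;   // (kcal/mol/A)/amu -> A/fs^2
static const double KB = 0.0019872041;         // kcal/mol/K

struct Pair { int i, j; double a, b; };

// [[Rcpp::export]]
List cvPullCore(NumericMatrix pos0,
                IntegerVector bondI, IntegerVector bondJ,
                NumericVector bondK, NumericVector bondR0,
                IntegerVector contI, IntegerVector contJ,
                NumericVector contEps, NumericVector contR0,
                double repEps, double repSigma,
                double mass, int fixedIdx, int pulledIdx,
                double springK, double velocityApNs, double temperature,
                double frictionPs, double dtFs, double durationNs,
                double recordIntervalPs, int seed,
                bool thermostat = true) {
  const int n = pos0.nrow();
  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos0(i, d);

  const int fixed = fixedIdx - 1, pulled = pulledIdx - 1;

  // pull axis: initial fixed -> pulled direction
  double ax = x[3 * pulled] - x[3 * fixed];
  double ay = x[3 * pulled + 1] - x[3 * fixed + 1];
  double az = x[3 * pulled + 2] - x[3 * fixed + 2];
  double an = std::sqrt(ax * ax + ay * ay + az * az);
  ax /= an; ay /= an; az /= an;
  const double dummy0x = x[3 * pulled], dummy0y = x[3 * pulled + 1],
               dummy0z = x[3 * pulled + 2];

  // repulsion pair list: non-bonded, non-contact pairs
  std::vector<std::vector<bool>> excl(n, std::vector<bool>(n, false));
  for (int b = 0; b < bondI.size(); ++b) {
    excl[bondI[b] - 1][bondJ[b] - 1] = true;
    excl[bondJ[b] - 1][bondI[b] - 1] = true;
  }
  for (int c = 0; c < contI.size(); ++c) {
    excl[contI[c] - 1][contJ[c] - 1] = true;
    excl[contJ[c] - 1][contI[c] - 1] = true;
  }
  std::vector<Pair> rep;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (!excl[i][j]) rep.push_back({i, j, 0.0, 0.0});

  std::mt19937_64 rng(static_cast<unsigned long long>(seed) + 0x9e3779b9ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);

  const double dt = dtFs;
  const long long nSteps =
      (long long)std::llround(durationNs * 1e6 / dt);
  const long long recEvery =
      std::max(1LL, (long long)std::llround(recordIntervalPs * 1e3 / dt));
  const double vA_fs = velocityApNs * 1e-6;          // A/ns -> A/fs
  const double gamma = frictionPs * 1e-3;            // ps^-1 -> fs^-1
  const double c1 = thermostat ? std::exp(-gamma * dt) : 1.0;
  const double kbt = KB * temperature;
  const double c2 = thermostat
      ? std::sqrt(kbt * KCAL_TO_AKMA / mass * (1.0 - c1 * c1)) : 0.0;

  // initial velocities from Maxwell-Boltzmann at the run temperature
  {
    const double sv = std::sqrt(kbt * KCAL_TO_AKMA / mass);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = sv * gauss(rng);
  }
  for (int d = 0; d < 3; ++d) v[3 * fixed + d] = 0.0;

  double potential = 0.0;
  auto computeForces = [&](double t) {
    std::fill(f.begin(), f.end(), 0.0);
    potential = 0.0;
    for (int b = 0; b < bondI.size(); ++b) {
      int i = bondI[b] - 1, j = bondJ[b] - 1;
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - bondR0[b];
      potential += 0.5 * bondK[b] * dr * dr;
      double fr = -bondK[b] * dr / r;
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
    for (int c = 0; c < contI.size(); ++c) {
      int i = contI[c] - 1, j = contJ[c] - 1;
      double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
             dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      double q = contR0[c] / r;
      double q2 = q * q;
      double q10 = q2 * q2 * q2 * q2 * q2;
      double q12 = q10 * q2;
      // 12-10 native contact: V = eps (5 q^12 - 6 q^10), minimum -eps at r0
      potential += contEps[c] * (5.0 * q12 - 6.0 * q10);
      double dVdr = contEps[c] * 60.0 * (q10 - q12) / r;
      double fr = -dVdr / r;
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
    const double cut2 = repSigma * repSigma;
    for (const Pair& p : rep) {
      double dx = x[3 * p.i] - x[3 * p.j],
             dy = x[3 * p.i + 1] - x[3 * p.j + 1],
             dz = x[3 * p.i + 2] - x[3 * p.j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      // purely repulsive, truncated and shifted 12th-power wall
      double s2 = cut2 / r2;
      double s6 = s2 * s2 * s2;
      double s12 = s6 * s6;
      potential += repEps * (s12 - 1.0);
      double dVdr2 = -6.0 * repEps * s12 / r2;   // dV/d(r^2)
      double fr = -2.0 * dVdr2;
      f[3 * p.i] += fr * dx; f[3 * p.i + 1] += fr * dy; f[3 * p.i + 2] += fr * dz;
      f[3 * p.j] -= fr * dx; f[3 * p.j + 1] -= fr * dy; f[3 * p.j + 2] -= fr * dz;
    }
    // spring between dummy (moving at constant velocity along axis) and
    // the pulled bead; force magnitude springK * extension along axis
    if (springK > 0.0) {
      double dxm = dummy0x + ax * vA_fs * t - x[3 * pulled];
      double dym = dummy0y + ay * vA_fs * t - x[3 * pulled + 1];
      double dzm = dummy0z + az * vA_fs * t - x[3 * pulled + 2];
      double ext = dxm * ax + dym * ay + dzm * az;
      potential += 0.5 * springK * ext * ext;
      f[3 * pulled] += springK * ext * ax;
      f[3 * pulled + 1] += springK * ext * ay;
      f[3 * pulled + 2] += springK * ext * az;
    }
  };

  const long long nRec = nSteps / recEvery + 1;
  NumericVector recTime(nRec), recDummy(nRec), recPulled(nRec),
      recExt(nRec), recForce(nRec), recKin(nRec), recPot(nRec);
  NumericMatrix frames(nRec, 3 * n);
  long long ri = 0;

  auto record = [&](long long step) {
    double t = step * dt;
    double dproj = (ax * (dummy0x + ax * vA_fs * t) +
                    ay * (dummy0y + ay * vA_fs * t) +
                    az * (dummy0z + az * vA_fs * t));
    double pproj = ax * x[3 * pulled] + ay * x[3 * pulled + 1] +
                   az * x[3 * pulled + 2];
    double ext = dproj - pproj;
    double kin = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        kin += 0.5 * mass * v[3 * i + d] * v[3 * i + d];
    kin /= KCAL_TO_AKMA;
    recTime[ri] = t * 1e-3;           // fs -> ps
    recDummy[ri] = dproj;
    recPulled[ri] = pproj;
    recExt[ri] = ext;
    recForce[ri] = springK * ext;
    recKin[ri] = kin;
    recPot[ri] = potential;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) frames(ri, 3 * i + d) = x[3 * i + d];
    ++ri;
  };

  computeForces(0.0);
  record(0);
  const double am = KCAL_TO_AKMA / mass;
  bool unstable = false;
  for (long long step = 1; step <= nSteps && !unstable; ++step) {
    // BAOAB: B (half kick), A (half drift), O (friction + noise),
    //        A (half drift), B (half kick with fresh forces)
    for (int i = 0; i < n; ++i) {
      if (i == fixed) continue;
      for (int d = 0; d < 3; ++d) {
        v[3 * i + d] += 0.5 * dt * f[3 * i + d] * am;
        x[3 * i + d] += 0.5 * dt * v[3 * i + d];
      }
    }
    if (thermostat)
      for (int i = 0; i < n; ++i) {
        if (i == fixed) continue;
        for (int d = 0; d < 3; ++d)
          v[3 * i + d] = c1 * v[3 * i + d] + c2 * gauss(rng);
      }
    for (int i = 0; i < n; ++i) {
      if (i == fixed) continue;
      for (int d = 0; d < 3; ++d)
        x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    computeForces(step * dt);
    for (int i = 0; i < n; ++i) {
      if (i == fixed) continue;
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] += 0.5 * dt * f[3 * i + d] * am;
    }
    if (step % recEvery == 0) {
      for (int i = 0; i < 3 * n && !unstable; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e4) unstable = true;
      if (!unstable) record(step);
    }
  }

  return List::create(
      _["time_ps"] = recTime[Range(0, ri - 1)],
      _["dummy_A"] = recDummy[Range(0, ri - 1)],
      _["pulled_A"] = recPulled[Range(0, ri - 1)],
      _["extension_A"] = recExt[Range(0, ri - 1)],
      _["force_kcalmolA"] = recForce[Range(0, ri - 1)],
      _["kinetic_kcalmol"] = recKin[Range(0, ri - 1)],
      _["potential_kcalmol"] = recPot[Range(0, ri - 1)],
      _["frames"] = frames,
      _["n_recorded"] = (double)ri,
      _["unstable"] = unstable);
}
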