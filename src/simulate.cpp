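#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian dynamics of point emitters in a periodic box with a 3D Gaussian
// detection profile and two-state (bright/dark) triplet blinking.
// Uses R's RNG so that set.seed() in R makes the trace reproducible.
//
// nMol[s]   molecules of species s
// D[s]      diffusion coefficient, um^2/s
// bG[s], bR[s]  peak brightness, photons/s at the volume center
// ft[s], tt[s]  stationary dark fraction and triplet relaxation time, s
// box       edge lengths (x, y, z), um; positions live in [-L/2, L/2)
// omega,z0  lateral/axial 1/e^2 radii, um
// dt        integration step, s; binWidth = stepsPerBin * dt
// [[Rcpp::export(name = ".simulateTraceCpp")]]
List simulateTraceCpp(IntegerVector nMol, NumericVector D,
                      NumericVector bG, NumericVector bR,
                      NumericVector ft, NumericVector tt,
                      NumericVector box, double omega, double z0,
                      double dt, int stepsPerBin, int nBins,
                      double bgGreen, double bgRed) {
  const int nSpec = nMol.size();
  int total = 0;
  for (int s = 0; s < nSpec; ++s) total += nMol[s];

  std::vector<double> x(total), y(total), z(total);
  std::vector<double> sdStep(total), brG(total), brR(total);
  std::vector<double> pToDark(total), pToBright(total);
  std::vector<int> bright(total);

  const double Lx = box[0], Ly = box[1], Lz = box[2];
  int k = 0;
  for (int s = 0; s < nSpec; ++s) {
    const double sd = std::sqrt(2.0 * D[s] * dt);
    // telegraph rates: dark fraction ft = kOff/(kOff+kOn), relaxation
    // time tt = 1/(kOff+kOn)
    const double kOff = ft[s] / tt[s];
    const double kOn  = (1.0 - ft[s]) / tt[s];
    const double pd = ft[s] > 0 ? 1.0 - std::exp(-kOff * dt) : 0.0;
    const double pb = ft[s] > 0 ? 1.0 - std::exp(-kOn * dt) : 0.0;
    for (int m = 0; m < nMol[s]; ++m, ++k) {
      x[k] = (unif_rand() - 0.5) * Lx;
      y[k] = (unif_rand() - 0.5) * Ly;
      z[k] = (unif_rand() - 0.5) * Lz;
      sdStep[k] = sd;
      brG[k] = bG[s] * dt;   // photons expected per step at volume center
      brR[k] = bR[s] * dt;
      pToDark[k] = pd;
      pToBright[k] = pb;
      bright[k] = (ft[s] > 0 && unif_rand() < ft[s]) ? 0 : 1;
    }
  }

  const double invW2 = 2.0 / (omega * omega);
  const double invZ2 = 2.0 / (z0 * z0);
  const double binWidth = stepsPerBin * dt;
  const double bgG = bgGreen * binWidth, bgR = bgRed * binWidth;

  IntegerVector outG(nBins), outR(nBins);

  for (int b = 0; b < nBins; ++b) {
    double accG = 0.0, accR = 0.0;
    for (int st = 0; st < stepsPerBin; ++st) {
      for (int m = 0; m < total; ++m) {
        double xm = x[m] + norm_rand() * sdStep[m];
        double ym = y[m] + norm_rand() * sdStep[m];
        double zm = z[m] + norm_rand() * sdStep[m];
        // periodic wrap (single wrap suffices: steps << box)
        if (xm < -0.5 * Lx) xm += Lx; else if (xm >= 0.5 * Lx) xm -= Lx;
        if (ym < -0.5 * Ly) ym += Ly; else if (ym >= 0.5 * Ly) ym -= Ly;
        if (zm < -0.5 * Lz) zm += Lz; else if (zm >= 0.5 * Lz) zm -= Lz;
        x[m] = xm; y[m] = ym; z[m] = zm;

        if (pToDark[m] > 0.0) {
          if (bright[m]) {
            if (unif_rand() < pToDark[m]) bright[m] = 0;
          } else {
            if (unif_rand() < pToBright[m]) bright[m] = 1;
          }
        }
        if (!bright[m]) continue;
        if (brG[m] <= 0.0 && brR[m] <= 0.0) continue;

        const double r2 = xm * xm + ym * ym;
        const double e = std::exp(-r2 * invW2 - zm * zm * invZ2);
        accG += brG[m] * e;
        accR += brR[m] * e;
      }
    }
    outG[b] = (accG + bgG > 0.0) ? (int) R::rpois(accG + bgG) : 0;
    outR[b] = (accR + bgR > 0.0) ? (int) R::rpois(accR + bgR) : 0;
  }

  return List::create(_["green"] = outG, _["red"] = outR);
}
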