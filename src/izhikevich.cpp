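#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the Izhikevich model for a population of
// units sharing one parameter set but with per-unit drive.
//
// drive: n_units x n_samples input current (already gain-scaled by the caller
// with K/Cm). State is recorded at sample boundaries; when the recorded v of
// a sample reaches v_peak a spike is logged at that sample time and the reset
// (v <- c, u <- u + d) consumes the step, so the next recorded v equals c
// exactly. v is updated before u within a step (original model ordering).
//
// [[Rcpp::export]]
List izh_integrate_cpp(NumericMatrix drive, double dt,
                       double a, double b, double c, double d,
                       double v_peak,
                       NumericVector v0, NumericVector u0,
                       bool record_state) {
  const int n_units = drive.nrow();
  const int n_samples = drive.ncol();
  std::vector< std::vector<double> > spikes(n_units);
  NumericVector v = clone(v0), u = clone(u0);
  NumericMatrix vtrace, utrace;
  if (record_state) {
    vtrace = NumericMatrix(n_units, n_samples);
    utrace = NumericMatrix(n_units, n_samples);
  }
  for (int i = 0; i < n_samples; ++i) {
    const double t = i * dt;
    for (int j = 0; j < n_units; ++j) {
      if (record_state) { vtrace(j, i) = v[j]; utrace(j, i) = u[j]; }
      if (v[j] >= v_peak) {
        spikes[j].push_back(t);
        v[j] = c;
        u[j] += d;
      } else {
        const double vj = v[j];
        const double dv = 0.04 * vj * vj + 5.0 * vj + 140.0 - u[j] + drive(j, i);
        v[j] = vj + dt * dv;
        u[j] += dt * a * (b * vj - u[j]);
      }
    }
  }
  List out_spikes(n_units);
  for (int j = 0; j < n_units; ++j) out_spikes[j] = wrap(spikes[j]);
  List out = List::create(_["spikes"] = out_spikes,
                          _["v_final"] = v, _["u_final"] = u);
  if (record_state) { out["v"] = vtrace; out["u"] = utrace; }
  return out;
}
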