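#include <Rcpp.h>
using namespace Rcpp;

// Beat-by-beat RRI generator. The recursion is inherently sequential: the
// innovation scale of the AR(1) noise depends on whether the current beat
// time falls inside an event effect window, and beat times are the running
// sum of the generated intervals. Modulation terms are evaluated at the time
// of the previous beat (the interval being generated starts there).
//
// drift is piecewise linear in time: slopes[i] (ms per s) applies on
// [knots[i], knots[i+1]) with knots[0] == 0; offsets[i] is the accumulated
// drift at knots[i].
//
// Windows [win_start[j], win_end[j]) are disjoint and ascending; inside them
// the innovation s.d. is sd_noise * (1 + effect_delta).
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List generate_rri_cpp(double duration_s, double mean_rri_ms,
                      NumericVector knots, NumericVector slopes,
                      NumericVector offsets,
                      double lf_amp, double lf_freq,
                      double hf_amp, double hf_freq,
                      double sd_noise, double ar,
                      NumericVector win_start, NumericVector win_end,
                      double effect_delta,
                      double clamp_lo, double clamp_hi) {
  std::vector<double> t_out, rri_out;
  const double two_pi = 2.0 * M_PI;
  double t = 0.0;   // time of previous beat (recording onset for the first)
  double x = 0.0;   // AR(1) state
  int n_clamped = 0;
  R_xlen_t w = 0;   // cursor into effect windows
  R_xlen_t k = 0;   // cursor into drift knots
  const R_xlen_t nw = win_start.size(), nk = knots.size();
  const double sd_in = sd_noise * (1.0 + effect_delta);

  while (t < duration_s) {
    // innovation scale at the start of this interval
    while (w < nw && t >= win_end[w]) ++w;
    const bool inside = (w < nw && t >= win_start[w]);
    const double sd = inside ? sd_in : sd_noise;
    x = ar * x + R::rnorm(0.0, sd);

    while (k + 1 < nk && t >= knots[k + 1]) ++k;
    const double drift = offsets[k] + slopes[k] * (t - knots[k]);

    double rri = mean_rri_ms + drift + x
      + lf_amp * std::sin(two_pi * lf_freq * t)
      + hf_amp * std::sin(two_pi * hf_freq * t);
    if (rri < clamp_lo) { rri = clamp_lo; ++n_clamped; }
    if (rri > clamp_hi) { rri = clamp_hi; ++n_clamped; }

    t += rri / 1000.0;
    if (t > duration_s) break;  // last partial interval is discarded
    t_out.push_back(t);
    rri_out.push_back(rri);
  }
  return List::create(_["t"] = wrap(t_out), _["rri"] = wrap(rri_out),
                      _["n_clamped"] = n_clamped);
}
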