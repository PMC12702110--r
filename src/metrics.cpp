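// Per-voxel cardiac DTI metrics from tensor components and local frames.
// Mirrors the scalar R functions (tensor_md, tensor_fa, helix_angle,
// sheetlet_angle); kept in C++ because bootstrap loops call it per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double wrap_half(double a) {
  // reduce (a + 90) modulo 180 into [0, 180) without fmod
  double x = a + 90.0;
  x -= 180.0 * std::floor(x / 180.0);
  x -= 90.0;
  if (x == -90.0) x = 90.0;
  return x;
}

// [[Rcpp::export(name = ".metric_maps_engine")]]
Rcpp::List metric_maps_engine(const arma::mat& tensors, // V x 6
                              const arma::mat& frames) { // V x 9
  const uword V = tensors.n_rows;
  vec md(V), fa(V), ha(V), e2a(V);
  const double rad2deg = 180.0 / datum::pi;

  for (uword v = 0; v < V; ++v) {
    mat D = {{tensors(v, 0), tensors(v, 3), tensors(v, 4)},
             {tensors(v, 3), tensors(v, 1), tensors(v, 5)},
             {tensors(v, 4), tensors(v, 5), tensors(v, 2)}};
    vec eval;
    mat evec;
    eig_sym(eval, evec, D); // ascending
    md(v) = mean(eval);
    vec l = clamp(eval, 0.0, datum::inf);
    double den = norm(l);
    double m = mean(l);
    fa(v) = den > 0 ? std::sqrt(1.5 * accu(square(l - m))) / den : 0.0;

    vec e1 = evec.col(2), e2 = evec.col(1);
    vec radial = frames.row(v).subvec(0, 2).t();
    vec circ = frames.row(v).subvec(3, 5).t();
    vec lng = frames.row(v).subvec(6, 8).t();
    double pc = dot(e1, circ), pl = dot(e1, lng);
    if (std::sqrt(pc * pc + pl * pl) < 1e-6) {
      ha(v) = NA_REAL;
      e2a(v) = NA_REAL;
      continue;
    }
    double hav = wrap_half(std::atan2(pl, pc) * rad2deg);
    ha(v) = hav;
    double har = hav / rad2deg;
    vec cm = -std::sin(har) * circ + std::cos(har) * lng;
    double pcm = dot(e2, cm), pr = dot(e2, radial);
    if (std::sqrt(pcm * pcm + pr * pr) < 1e-6) {
      e2a(v) = NA_REAL;
      continue;
    }
    e2a(v) = wrap_half(std::atan2(pr, pcm) * rad2deg);
  }
  return Rcpp::List::create(
    Rcpp::Named("md") = md, Rcpp::Named("fa") = fa,
    Rcpp::Named("ha") = ha, Rcpp::Named("e2a") = e2a
  );
}
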