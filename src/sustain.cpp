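#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Event-based model core. Events are (biomarker, z-threshold) pairs indexed
// 0..E-1; an ordering is a vector of event ids by sequence position. All
// orderings handled here are assumed valid (per-biomarker thresholds in
// increasing position order); validity is enforced at the R boundary and
// preserved by the move proposals below.

namespace {

// Piecewise-linear expected z for each biomarker at integer stages 0..E.
// Anchors: (0,0), one per event at (position, threshold), and (E, z_max)
// unless the biomarker's last event already sits at position E (threshold
// anchor takes precedence at the shared coordinate).
arma::mat trajectory_mat(const arma::ivec &ord, const arma::ivec &ev_bio,
                         const arma::vec &ev_z, int B, double zmax) {
  const int E = ord.n_elem;
  arma::mat G(B, E + 1, arma::fill::zeros);
  std::vector<std::vector<std::pair<int, double> > > anch(B);
  for (int b = 0; b < B; ++b) anch[b].push_back(std::make_pair(0, 0.0));
  for (int p = 0; p < E; ++p) {
    const int e = ord[p];
    anch[ev_bio[e]].push_back(std::make_pair(p + 1, ev_z[e]));
  }
  for (int b = 0; b < B; ++b) {
    std::vector<std::pair<int, double> > &a = anch[b];
    if (a.back().first < E) a.push_back(std::make_pair(E, zmax));
    const int nseg = (int)a.size() - 1;
    int seg = 0;
    for (int k = 0; k <= E; ++k) {
      while (seg < nseg - 1 && k > a[seg + 1].first) ++seg;
      const int x0 = a[seg].first, x1 = a[seg + 1].first;
      const double y0 = a[seg].second, y1 = a[seg + 1].second;
      if (k <= x0) G(b, k) = y0;
      else if (k >= x1) G(b, k) = y1;
      else G(b, k) = y0 + (y1 - y0) * double(k - x0) / double(x1 - x0);
    }
  }
  return G;
}

arma::vec row_logsumexp(const arma::mat &M) {
  arma::vec m = arma::max(M, 1);
  return m + arma::log(arma::sum(arma::exp(M.each_col() - m), 1));
}

// log N(z; g, sigma) summed over biomarkers, for every (subject, stage).
// Zs and Gs are pre-scaled by 1/sigma; c0 collects the normalizing constant.
arma::mat stage_logdens_scaled(const arma::mat &Zs, const arma::vec &sqz,
                               const arma::mat &Gs, double c0) {
  arma::rowvec sqg = arma::sum(arma::square(Gs), 0);
  arma::mat D = Zs * Gs;
  D.each_col() -= 0.5 * sqz;
  D.each_row() -= 0.5 * sqg;
  D += c0;
  return D;
}

struct ScaledData {
  arma::mat Zs;
  arma::vec sqz;
  double c0;
};

ScaledData scale_data(const arma::mat &Z, const arma::vec &sigma) {
  ScaledData s;
  s.Zs = Z;
  s.Zs.each_row() /= sigma.t();
  s.sqz = arma::sum(arma::square(s.Zs), 1);
  s.c0 = -arma::accu(arma::log(sigma)) -
         0.5 * double(Z.n_cols) * std::log(2.0 * M_PI);
  return s;
}

// Stage-marginal log-likelihood per subject under a uniform stage prior.
arma::vec subject_logliks_ord(const ScaledData &sd, const arma::ivec &ord,
                              const arma::ivec &ev_bio, const arma::vec &ev_z,
                              int B, double zmax, const arma::vec &sigma) {
  const int E = ord.n_elem;
  arma::mat G = trajectory_mat(ord, ev_bio, ev_z, B, zmax);
  G.each_col() /= sigma;
  arma::mat D = stage_logdens_scaled(sd.Zs, sd.sqz, G, sd.c0);
  return row_logsumexp(D) - std::log(double(E + 1));
}

// Valid insertion slots for event e into `reduced` (the ordering with e
// removed): strictly after the last same-biomarker event with a lower
// threshold and strictly before the first with a higher one.
void move_bounds(const std::vector<int> &reduced, int e,
                 const arma::ivec &ev_bio, const arma::vec &ev_z,
                 int &lo, int &hi) {
  const int b = ev_bio[e];
  const double z = ev_z[e];
  lo = 0;
  hi = (int)reduced.size();
  for (size_t i = 0; i < reduced.size(); ++i) {
    const int o = reduced[i];
    if (ev_bio[o] != b) continue;
    if (ev_z[o] < z) lo = (int)i + 1;
    else { hi = (int)i; break; }
  }
}

arma::ivec insert_event(const std::vector<int> &reduced, int e, int slot) {
  const int E = (int)reduced.size() + 1;
  arma::ivec out(E);
  int r = 0;
  for (int q = 0; q < E; ++q) {
    if (q == slot) out[q] = e;
    else out[q] = reduced[r++];
  }
  return out;
}

int runif_int(int n) {  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_trajectory(const arma::ivec &ord, const arma::ivec &ev_bio,
                         const arma::vec &ev_z, int B, double zmax) {
  return trajectory_mat(ord, ev_bio, ev_z, B, zmax);
}

// [[Rcpp::export]]
arma::mat cpp_stage_logdens(const arma::mat &Z, const arma::ivec &ord,
                            const arma::ivec &ev_bio, const arma::vec &ev_z,
                            int B, double zmax, const arma::vec &sigma) {
  ScaledData sd = scale_data(Z, sigma);
  arma::mat G = trajectory_mat(ord, ev_bio, ev_z, B, zmax);
  G.each_col() /= sigma;
  return stage_logdens_scaled(sd.Zs, sd.sqz, G, sd.c0);
}

// [[Rcpp::export]]
arma::vec cpp_subject_logliks(const arma::mat &Z, const arma::ivec &ord,
                              const arma::ivec &ev_bio, const arma::vec &ev_z,
                              int B, double zmax, const arma::vec &sigma) {
  ScaledData sd = scale_data(Z, sigma);
  return subject_logliks_ord(sd, ord, ev_bio, ev_z, B, zmax, sigma);
}

// Hill climb over orderings: passes over the events; for each event every
// valid relocation is scored and the best improving one applied
// immediately; passes repeat until none of the events can be improved.
// [[Rcpp::export]]
List cpp_greedy(const arma::mat &Z, const arma::ivec &ord0,
                const arma::ivec &ev_bio, const arma::vec &ev_z, int B,
                double zmax, const arma::vec &sigma, int max_sweeps) {
  ScaledData sd = scale_data(Z, sigma);
  const int E = ord0.n_elem;
  arma::ivec ord = ord0;
  double cur = arma::accu(
      subject_logliks_ord(sd, ord, ev_bio, ev_z, B, zmax, sigma));
  int sweeps = 0;
  bool improved = true;
  const double tol = 1e-9;
  while (improved && sweeps < max_sweeps) {
    improved = false;
    ++sweeps;
    for (int e = 0; e < E; ++e) {
      int p = 0;
      while (ord[p] != e) ++p;
      std::vector<int> reduced;
      reduced.reserve(E - 1);
      for (int q = 0; q < E; ++q)
        if (q != p) reduced.push_back(ord[q]);
      int lo, hi;
      move_bounds(reduced, e, ev_bio, ev_z, lo, hi);
      double best = cur;
      arma::ivec best_ord;
      for (int s = lo; s <= hi; ++s) {
        if (s == p) continue;
        arma::ivec cand = insert_event(reduced, e, s);
        double v = arma::accu(
            subject_logliks_ord(sd, cand, ev_bio, ev_z, B, zmax, sigma));
        if (v > best + tol) {
          best = v;
          best_ord = cand;
        }
      }
      if (best > cur + tol) {
        ord = best_ord;
        cur = best;
        improved = true;
      }
    }
  }
  return List::create(_["ord"] = ord, _["loglik"] = cur,
                      _["sweeps"] = sweeps);
}

// Metropolis sampler over orderings: one uniformly chosen subtype, one
// uniformly chosen event, relocated to a uniformly chosen valid slot
// (window size is move-invariant, so the proposal is symmetric). Mixture
// fractions are held fixed. Uses R's RNG so set.seed() governs the chain.
// [[Rcpp::export]]
List cpp_mcmc(const arma::mat &Z, List ord_list, const arma::vec &f,
              const arma::ivec &ev_bio, const arma::vec &ev_z, int B,
              double zmax, const arma::vec &sigma, int n_iter, int thin) {
  const int C = ord_list.size();
  const int n = Z.n_rows;
  ScaledData sd = scale_data(Z, sigma);
  std::vector<arma::ivec> ords(C);
  for (int c = 0; c < C; ++c) ords[c] = as<arma::ivec>(ord_list[c]);
  const int E = ords[0].n_elem;
  arma::rowvec logf = arma::log(f.t());

  arma::mat LL(n, C);
  for (int c = 0; c < C; ++c)
    LL.col(c) = subject_logliks_ord(sd, ords[c], ev_bio, ev_z, B, zmax, sigma);
  arma::mat M = LL;
  M.each_row() += logf;
  double total = arma::accu(row_logsumexp(M));

  double best_total = total;
  std::vector<arma::ivec> best_ords = ords;

  const int n_store = n_iter / thin;
  std::vector<IntegerMatrix> store;
  for (int c = 0; c < C; ++c) store.push_back(IntegerMatrix(n_store, E));
  NumericVector trace(n_store);
  int stored = 0;
  long accepted = 0;

  for (int it = 1; it <= n_iter; ++it) {
    const int c = runif_int(C);
    const int p = runif_int(E);
    const int e = ords[c][p];
    std::vector<int> reduced;
    reduced.reserve(E - 1);
    for (int q = 0; q < E; ++q)
      if (q != p) reduced.push_back(ords[c][q]);
    int lo, hi;
    move_bounds(reduced, e, ev_bio, ev_z, lo, hi);
    const int s = lo + runif_int(hi - lo + 1);
    if (s == p) {
      ++accepted;  // identity move, accepted with probability one
    } else {
      arma::ivec cand = insert_event(reduced, e, s);
      arma::vec newcol =
          subject_logliks_ord(sd, cand, ev_bio, ev_z, B, zmax, sigma);
      arma::vec oldcol = LL.col(c);
      LL.col(c) = newcol;
      arma::mat M2 = LL;
      M2.each_row() += logf;
      const double newtotal = arma::accu(row_logsumexp(M2));
      const double d = newtotal - total;
      if (d >= 0.0 || std::log(unif_rand()) < d) {
        ords[c] = cand;
        total = newtotal;
        ++accepted;
        if (total > best_total) {
          best_total = total;
          best_ords = ords;
        }
      } else {
        LL.col(c) = oldcol;
      }
    }
    if (thin > 0 && it % thin == 0 && stored < n_store) {
      for (int c2 = 0; c2 < C; ++c2)
        for (int q = 0; q < E; ++q) store[c2](stored, q) = ords[c2][q];
      trace[stored] = total;
      ++stored;
    }
  }

  List sample_list(C), ml_list(C);
  for (int c = 0; c < C; ++c) {
    sample_list[c] = store[c];
    ml_list[c] = IntegerVector(best_ords[c].begin(), best_ords[c].end());
  }
  return List::create(
      _["samples"] = sample_list, _["trace"] = trace,
      _["accept_rate"] = double(accepted) / double(n_iter),
      _["ml_ords"] = ml_list, _["ml_loglik"] = best_total,
      _["final_loglik"] = total);
}
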