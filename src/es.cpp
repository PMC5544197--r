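#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Weighted enrichment-score running sum, evaluated only at hit boundaries.
// Between consecutive hits the running sum decreases linearly, so the signed
// maximum deviation is attained either just before or just after a hit.
//
// hits: (position in the descending-rank ordering [1..N], weight) pairs,
// sorted by position. A zero total weight (possible when p > 0 and every hit
// sits exactly at the centre rank) falls back to uniform hit weights.
static double es_core(const std::vector<std::pair<int, double> >& hits,
                      const int N) {
  const int s = static_cast<int>(hits.size());
  double W = 0.0;
  for (int k = 0; k < s; ++k) W += hits[k].second;
  const bool uniform = (W <= 0.0);
  if (uniform) W = static_cast<double>(s);
  const double miss = 1.0 / static_cast<double>(N - s);

  double H = 0.0, up = 0.0, down = 0.0;
  for (int k = 0; k < s; ++k) {
    const int pos = hits[k].first;
    const double drop = static_cast<double>(pos - 1 - k) * miss;
    const double before = H / W - drop;
    H += uniform ? 1.0 : hits[k].second;
    const double after = H / W - drop;
    if (before < down) down = before;
    if (after > up) up = after;
    if (after < down) down = after;
    if (before > up) up = before;
  }
  // signed maximum deviation; magnitude ties (within float drift of the
  // accumulated sums) resolve to the positive deviation
  return (up >= -down - 1e-9) ? up : down;
}

// [[Rcpp::export(name = ".es_cpp")]]
double es_cpp(IntegerVector hit_pos, NumericVector hit_w, int N) {
  const int s = hit_pos.size();
  std::vector<std::pair<int, double> > hits(s);
  for (int k = 0; k < s; ++k)
    hits[k] = std::make_pair(hit_pos[k], hit_w[k]);
  std::sort(hits.begin(), hits.end());
  return es_core(hits, N);
}

static double es_set(const IntegerMatrix& pos, const NumericMatrix& w,
                     const IntegerMatrix& idx, const int i_set,
                     const int j_prof, std::vector<std::pair<int, double> >& buf) {
  const int s = idx.nrow();
  const int N = pos.nrow();
  buf.resize(s);
  for (int k = 0; k < s; ++k) {
    const int probe = idx(k, i_set) - 1;
    buf[k] = std::make_pair(pos(probe, j_prof), w(probe, j_prof));
  }
  std::sort(buf.begin(), buf.end());
  return es_core(buf, N);
}

// All-pairs signature distance.
// pos: probe position (1-based) in each sample's descending-rank ordering.
// w:   per-sample hit weights |rank - (N+1)/2|^p.
// up, down: s x n matrices of 1-based probe row indices (each sample's
// signature). distance(i,j) = 1 - (sim(i->j) + sim(j->i)) / 2 with
// sim(i->j) = (ES(up_i in j) - ES(down_i in j)) / 2.
// [[Rcpp::export(name = ".pair_distance_cpp")]]
NumericMatrix pair_distance_cpp(IntegerMatrix pos, NumericMatrix w,
                                IntegerMatrix up, IntegerMatrix down) {
  const int n = pos.ncol();
  NumericMatrix D(n, n);
  std::vector<std::pair<int, double> > buf;
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      const double sim_ij = (es_set(pos, w, up, i, j, buf) -
                             es_set(pos, w, down, i, j, buf)) / 2.0;
      const double sim_ji = (es_set(pos, w, up, j, i, buf) -
                             es_set(pos, w, down, j, i, buf)) / 2.0;
      const double d = 1.0 - (sim_ij + sim_ji) / 2.0;
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
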