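#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Seeded-growth neutral landscape: place n_nuclei random nuclei, then convert
// uniformly-chosen habitat-adjacent (rook neighbourhood) cells until exactly
// n_habitat cells are habitat. Uses R's RNG, so results are reproducible under
// set.seed() on the R side.
// [[Rcpp::export]]
IntegerMatrix grow_habitat_cpp(int nrow, int ncol, int n_habitat, int n_nuclei) {
  const int n_cells = nrow * ncol;
  IntegerMatrix grid(nrow, ncol);
  if (n_habitat <= 0) return grid;
  if (n_habitat >= n_cells) {
    std::fill(grid.begin(), grid.end(), 1);
    return grid;
  }
  if (n_nuclei > n_habitat) n_nuclei = n_habitat;

  std::vector<int> frontier;            // candidate cells (lazy deletion)
  frontier.reserve(4 * n_habitat);
  int placed = 0;

  // distinct nuclei
  std::vector<int> nuclei;
  while ((int)nuclei.size() < n_nuclei) {
    int cell = (int)std::floor(unif_rand() * n_cells);
    if (cell >= n_cells) cell = n_cells - 1;
    if (grid[cell] == 0) {
      grid[cell] = 1;
      nuclei.push_back(cell);
      ++placed;
    }
  }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  auto push_neighbours = [&](int cell) {
    int r = cell % nrow, c = cell / nrow;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      int nb = rr + cc * nrow;
      if (grid[nb] == 0) frontier.push_back(nb);
    }
  };
  for (int cell : nuclei) push_neighbours(cell);

  while (placed < n_habitat) {
    if (frontier.empty()) break;        // cannot happen while placed < n_cells
    int idx = (int)std::floor(unif_rand() * frontier.size());
    if (idx >= (int)frontier.size()) idx = frontier.size() - 1;
    int cell = frontier[idx];
    frontier[idx] = frontier.back();
    frontier.pop_back();
    if (grid[cell] == 1) continue;      // stale entry
    grid[cell] = 1;
    ++placed;
    push_neighbours(cell);
  }
  return grid;
}

// Connected-component labelling of habitat (value 1) cells under rook (4) or
// queen (8) connectivity. Background/nodata cells must be 0. Labels start at 1.
// [[Rcpp::export]]
List label_patches_cpp(IntegerMatrix grid, int connectivity) {
  const int nrow = grid.nrow(), ncol = grid.ncol();
  IntegerMatrix labels(nrow, ncol);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int n_nb = (connectivity == 8) ? 8 : 4;
  int n_patches = 0;
  std::vector<int> stack;
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      int cell = r + c * nrow;
      if (grid[cell] != 1 || labels[cell] != 0) continue;
      ++n_patches;
      labels[cell] = n_patches;
      stack.clear();
      stack.push_back(cell);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cr = cur % nrow, cc = cur / nrow;
        for (int k = 0; k < n_nb; ++k) {
          int rr = cr + dr8[k], c2 = cc + dc8[k];
          if (rr < 0 || rr >= nrow || c2 < 0 || c2 >= ncol) continue;
          int nb = rr + c2 * nrow;
          if (grid[nb] == 1 && labels[nb] == 0) {
            labels[nb] = n_patches;
            stack.push_back(nb);
          }
        }
      }
    }
  }
  return List::create(_["labels"] = labels, _["n_patches"] = n_patches);
}

// Mean Euclidean nearest-neighbour distance (ENN_MN) between patches, measured
// between border-cell centres (landscapemetrics convention). Border cell: any
// patch cell with a rook neighbour outside the patch or on the grid edge.
// Returns NA_real_ when fewer than two patches exist. Bounding-box pruning
// keeps the pairwise scan fast on compact patches.
// [[Rcpp::export]]
double enn_mn_cpp(IntegerMatrix labels, int n_patches, double cell_size) {
  if (n_patches < 2) return NA_REAL;
  const int nrow = labels.nrow(), ncol = labels.ncol();
  std::vector<std::vector<int>> br(n_patches), bc(n_patches);
  std::vector<int> rmin(n_patches, nrow), rmax(n_patches, -1),
                   cmin(n_patches, ncol), cmax(n_patches, -1);
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      int lab = labels(r, c);
      if (lab == 0) continue;
      bool border = false;
      for (int k = 0; k < 4 && !border; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) border = true;
        else if (labels(rr, cc) != lab) border = true;
      }
      if (border) {
        int i = lab - 1;
        br[i].push_back(r);
        bc[i].push_back(c);
        if (r < rmin[i]) rmin[i] = r;
        if (r > rmax[i]) rmax[i] = r;
        if (c < cmin[i]) cmin[i] = c;
        if (c > cmax[i]) cmax[i] = c;
      }
    }
  }
  auto bbox_gap2 = [&](int i, int j) -> double {
    double gr = std::max(0, std::max(rmin[i], rmin[j]) - std::min(rmax[i], rmax[j]));
    double gc = std::max(0, std::max(cmin[i], cmin[j]) - std::min(cmax[i], cmax[j]));
    return gr * gr + gc * gc;
  };
  std::vector<double> best(n_patches, R_PosInf); // squared cell distances
  for (int i = 0; i < n_patches; ++i) {
    for (int j = i + 1; j < n_patches; ++j) {
      double lb = bbox_gap2(i, j);
      if (lb >= best[i] && lb >= best[j]) continue;
      double mn = R_PosInf;
      for (size_t a = 0; a < br[i].size(); ++a) {
        for (size_t b = 0; b < br[j].size(); ++b) {
          double d1 = br[i][a] - br[j][b];
          double d2 = bc[i][a] - bc[j][b];
          double d = d1 * d1 + d2 * d2;
          if (d < mn) mn = d;
        }
      }
      if (mn < best[i]) best[i] = mn;
      if (mn < best[j]) best[j] = mn;
    }
  }
  double s = 0.0;
  for (int i = 0; i < n_patches; ++i) s += std::sqrt(best[i]);
  return cell_size * s / n_patches;
}

// Raup-Crick null replicates. For each replicate, draw richness-many species
// without replacement with probability proportional to pool_freq
// (Efraimidis-Spirakis exponential keys), distribute the observed total
// abundance among them multinomially with probability proportional to
// pool_relabund, and return the Bray-Curtis dissimilarity of the two null
// communities. Uses R's RNG.
// [[Rcpp::export]]
NumericVector rc_null_cpp(int rich_x, int tot_x, int rich_y, int tot_y,
                          NumericVector pool_freq, NumericVector pool_relabund,
                          int n_reps) {
  const int S = pool_freq.size();
  NumericVector out(n_reps);
  std::vector<double> key(S);
  std::vector<int> ord(S), chosen_x(rich_x), chosen_y(rich_y);
  std::vector<int> cnt_x(rich_x), cnt_y(rich_y);
  std::vector<double> prob(S), buf(S, 0.0);

  auto draw_species = [&](int k, std::vector<int> &chosen) {
    for (int s = 0; s < S; ++s) {
      double u = unif_rand();
      key[s] = (pool_freq[s] > 0) ? -std::log(u) / pool_freq[s] : R_PosInf;
      ord[s] = s;
    }
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int a, int b) { return key[a] < key[b]; });
    for (int s = 0; s < k; ++s) chosen[s] = ord[s];
  };
  auto draw_counts = [&](const std::vector<int> &chosen, int tot,
                         std::vector<int> &cnt) {
    int k = chosen.size();
    double tw = 0.0;
    for (int s = 0; s < k; ++s) tw += pool_relabund[chosen[s]];
    for (int s = 0; s < k; ++s)
      prob[s] = (tw > 0) ? pool_relabund[chosen[s]] / tw : 1.0 / k;
    rmultinom(tot, prob.data(), k, cnt.data());
  };

  for (int rep = 0; rep < n_reps; ++rep) {
    draw_species(rich_x, chosen_x);
    draw_species(rich_y, chosen_y);
    draw_counts(chosen_x, tot_x, cnt_x);
    draw_counts(chosen_y, tot_y, cnt_y);
    double A = 0.0;
    for (int s = 0; s < rich_x; ++s) buf[chosen_x[s]] = cnt_x[s];
    for (int s = 0; s < rich_y; ++s) {
      double v = buf[chosen_y[s]];
      if (v > 0) A += std::min(v, (double)cnt_y[s]);
    }
    for (int s = 0; s < rich_x; ++s) buf[chosen_x[s]] = 0.0;
    double tot = (double)tot_x + (double)tot_y;
    out[rep] = (tot - 2.0 * A) / tot;
  }
  return out;
}


// Mean pairwise Raup-Crick over all unordered row pairs of an abundance
// matrix, with a shared pool. Returns the per-pair rc_raw values in row-major
// pair order ((1,2), (1,3), ..., (n-1,n)). Ties weighted 0.5.
//
// Monte Carlo internals use a fast xoshiro256++ stream seeded from R's RNG at
// entry (so results are reproducible under set.seed), a Fenwick tree for
// weighted sampling without replacement, and a Walker alias table for the
// within-community multinomial.
namespace {
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};
}  // namespace

// [[Rcpp::export]]
NumericVector landscape_rc_cpp(IntegerMatrix m, NumericVector pool_freq,
                               NumericVector pool_relabund, int n_reps) {
  const int n = m.nrow(), S = m.ncol();
  // derive a 64-bit stream seed from R's RNG (keeps set.seed reproducibility)
  uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                  (uint64_t)(unif_rand() * 4294967296.0);
  Xoshiro rng(seed);

  std::vector<int> rich(n), tot(n);
  for (int i = 0; i < n; ++i) {
    int r = 0, t = 0;
    for (int s = 0; s < S; ++s) {
      if (m(i, s) > 0) { ++r; t += m(i, s); }
    }
    rich[i] = r; tot[i] = t;
  }

  // Fenwick tree over pool_freq; base copy restored per draw
  int tree_n = 1;
  while (tree_n < S) tree_n <<= 1;
  std::vector<double> base_tree(tree_n + 1, 0.0), tree(tree_n + 1);
  double total_w = 0.0;
  for (int s = 0; s < tree_n; ++s) {
    double w = (s < S) ? pool_freq[s] : 0.0;
    base_tree[s + 1] += w;
    int j = (s + 1) + ((s + 1) & -(s + 1));
    if (j <= tree_n) base_tree[j] += base_tree[s + 1];
    total_w += w;
  }
  std::vector<int> chosen_x(S), chosen_y(S), cnt_x(S), cnt_y(S);
  std::vector<double> buf(S, 0.0), aw(S);
  std::vector<double> alias_p(S);
  std::vector<int> alias_a(S), small_st(S), large_st(S);

  tree = base_tree;
  // draw k species without replacement by weight removal, then restore the
  // removed weights (cheaper than re-copying the tree every draw)
  auto draw_species = [&](int k, std::vector<int> &chosen) {
    double remaining = total_w;
    for (int got = 0; got < k; ++got) {
      double r = rng.unif() * remaining;
      int pos = 0;
      for (int step = tree_n >> 1; step > 0; step >>= 1) {
        int next = pos + step;
        if (next <= tree_n && tree[next] < r) {
          r -= tree[next];
          pos = next;
        }
      }
      int idx = pos < S ? pos : S - 1;
      double w = pool_freq[idx];
      for (int j = idx + 1; j <= tree_n; j += j & -j) tree[j] -= w;
      remaining -= w;
      chosen[got] = idx;
    }
    for (int got = 0; got < k; ++got) {
      double w = pool_freq[chosen[got]];
      for (int j = chosen[got] + 1; j <= tree_n; j += j & -j) tree[j] += w;
    }
  };
  // multinomial(t; relabund[chosen]) via Walker alias table, O(k) build,
  // O(1) per individual
  auto draw_counts = [&](const std::vector<int> &chosen, int k, int t,
                         std::vector<int> &cnt) {
    double tw = 0.0;
    for (int s = 0; s < k; ++s) {
      aw[s] = (pool_relabund[chosen[s]] > 0) ? pool_relabund[chosen[s]] : 1e-12;
      tw += aw[s];
      cnt[s] = 0;
    }
    int n_small = 0, n_large = 0;
    for (int s = 0; s < k; ++s) {
      alias_p[s] = aw[s] * k / tw;
      if (alias_p[s] < 1.0) small_st[n_small++] = s;
      else large_st[n_large++] = s;
    }
    while (n_small && n_large) {
      int sm = small_st[--n_small], lg = large_st[--n_large];
      alias_a[sm] = lg;
      alias_p[lg] = alias_p[lg] + alias_p[sm] - 1.0;
      if (alias_p[lg] < 1.0) small_st[n_small++] = lg;
      else large_st[n_large++] = lg;
    }
    while (n_large) alias_p[large_st[--n_large]] = 1.0;
    while (n_small) alias_p[small_st[--n_small]] = 1.0;
    for (int ind = 0; ind < t; ++ind) {
      double u = rng.unif() * k;
      int s = (int)u;
      if (s >= k) s = k - 1;
      ++cnt[(u - s) < alias_p[s] ? s : alias_a[s]];
    }
  };

  // one null community per inventory per replicate; all pairwise d* of a
  // replicate share those draws (matrix-per-permutation, the convention of
  // null-model dissimilarity tools)
  const int n_pairs = n * (n - 1) / 2;
  NumericVector out(n_pairs);
  std::vector<double> d_obs(n_pairs), n_less(n_pairs, 0.0), n_tie(n_pairs, 0.0);
  {
    int p = 0;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j, ++p) {
        double A = 0.0;
        for (int s = 0; s < S; ++s) A += std::min(m(i, s), m(j, s));
        double tt = (double)tot[i] + (double)tot[j];
        d_obs[p] = (tt - 2.0 * A) / tt;
      }
    }
  }
  std::vector<std::vector<int>> null_sp(n), null_cnt(n);
  for (int i = 0; i < n; ++i) {
    null_sp[i].resize(rich[i]);
    null_cnt[i].resize(rich[i]);
  }
  const double eps = 1e-12;
  for (int rep = 0; rep < n_reps; ++rep) {
    for (int i = 0; i < n; ++i) {
      draw_species(rich[i], null_sp[i]);
      draw_counts(null_sp[i], rich[i], tot[i], null_cnt[i]);
    }
    int p = 0;
    for (int i = 0; i < n - 1; ++i) {
      for (int s = 0; s < rich[i]; ++s) buf[null_sp[i][s]] = null_cnt[i][s];
      for (int j = i + 1; j < n; ++j, ++p) {
        double An = 0.0;
        for (int s = 0; s < rich[j]; ++s) {
          double v = buf[null_sp[j][s]];
          if (v > 0) An += std::min(v, (double)null_cnt[j][s]);
        }
        double tt = (double)tot[i] + (double)tot[j];
        double d = (tt - 2.0 * An) / tt;
        if (d < d_obs[p] - eps) n_less[p] += 1.0;
        else if (d <= d_obs[p] + eps) n_tie[p] += 1.0;
      }
      for (int s = 0; s < rich[i]; ++s) buf[null_sp[i][s]] = 0.0;
    }
  }
  for (int p = 0; p < n_pairs; ++p) {
    out[p] = 2.0 * ((n_less[p] + 0.5 * n_tie[p]) / n_reps) - 1.0;
  }
  return out;
}
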