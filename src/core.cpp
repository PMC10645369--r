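#include <Rcpp.h>
#include <array>
#include <vector>
#include <string>
#include <unordered_set>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3x3x3 cube geometry. Cells are indexed 0..26 as x + 3*y + 9*z.
// A compact fold is a Hamiltonian self-avoiding walk visiting every cell.
// ---------------------------------------------------------------------------

static std::vector<std::vector<int>> cube_adjacency() {
  std::vector<std::vector<int>> nb(27);
  for (int c = 0; c < 27; ++c) {
    int x = c % 3, y = (c / 3) % 3, z = c / 9;
    const int dx[6] = {1, -1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, 1, -1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, 1, -1};
    for (int k = 0; k < 6; ++k) {
      int nx = x + dx[k], ny = y + dy[k], nz = z + dz[k];
      if (nx >= 0 && nx < 3 && ny >= 0 && ny < 3 && nz >= 0 && nz < 3)
        nb[c].push_back(nx + 3 * ny + 9 * nz);
    }
  }
  return nb;
}

// The 48 cube symmetries (rotations + reflections) as cell permutations:
// all assignments of output axes to input axes (6) times sign flips (8).
static std::vector<std::array<int, 27>> cube_symmetries() {
  std::vector<std::array<int, 27>> syms;
  int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int p = 0; p < 6; ++p) {
    for (int f = 0; f < 8; ++f) {
      std::array<int, 27> m;
      for (int c = 0; c < 27; ++c) {
        int xyz[3] = {c % 3, (c / 3) % 3, c / 9};
        int out[3];
        for (int ax = 0; ax < 3; ++ax) {
          int v = xyz[perms[p][ax]];
          if (f & (1 << ax)) v = 2 - v;
          out[ax] = v;
        }
        m[c] = out[0] + 3 * out[1] + 9 * out[2];
      }
      syms.push_back(m);
    }
  }
  return syms;
}

// Lexicographically minimal image of a path under the symmetry group
// (optionally also under chain reversal). Used as the canonical fold key.
// Images are compared element-by-element with early exit.
static std::string canonical_key(const int *path,
                                 const std::vector<std::array<int, 27>> &syms,
                                 bool identify_reversal) {
  char best[27];
  for (int k = 0; k < 27; ++k) best[k] = (char) syms[0][path[k]];
  for (size_t s = 0; s < syms.size(); ++s) {
    const std::array<int, 27> &m = syms[s];
    for (int dir = 0; dir < (identify_reversal ? 2 : 1); ++dir) {
      if (s == 0 && dir == 0) continue;
      for (int k = 0; k < 27; ++k) {
        char v = (char) m[dir == 0 ? path[k] : path[26 - k]];
        if (v > best[k]) break;
        if (v < best[k]) { // strictly better: finish and adopt
          best[k] = v;
          for (int k2 = k + 1; k2 < 27; ++k2)
            best[k2] = (char) m[dir == 0 ? path[k2] : path[26 - k2]];
          break;
        }
      }
    }
  }
  return std::string(best, 27);
}

struct FoldEnum {
  std::vector<std::vector<int>> nb;
  std::vector<std::array<int, 27>> syms;
  bool identify_reversal;
  std::unordered_set<std::string> seen;
  std::vector<std::string> folds; // canonical paths, insertion order
  int path[27];
  bool visited[27];

  void dfs(int cell, int depth) {
    path[depth] = cell;
    if (depth == 26) {
      // enumerate each undirected walk once (start cell < end cell)
      if (path[0] < path[26] || !identify_reversal) {
        std::string key = canonical_key(path, syms, identify_reversal);
        if (seen.insert(key).second) folds.push_back(key);
      }
      return;
    }
    visited[cell] = true;
    for (int nxt : nb[cell])
      if (!visited[nxt]) dfs(nxt, depth + 1);
    visited[cell] = false;
  }
};

// [[Rcpp::export]]
IntegerMatrix enumerate_folds_cpp(bool identify_reversal) {
  FoldEnum E;
  E.nb = cube_adjacency();
  E.syms = cube_symmetries();
  E.identify_reversal = identify_reversal;
  std::fill(E.visited, E.visited + 27, false);
  for (int start = 0; start < 27; ++start) E.dfs(start, 0);
  IntegerMatrix out(E.folds.size(), 27);
  for (size_t f = 0; f < E.folds.size(); ++f)
    for (int k = 0; k < 27; ++k)
      out(f, k) = (int) E.folds[f][k]; // 0-based cell ids
  return out;
}

// Independent re-enumeration used as a cross-check: iterative (explicit
// stack) rather than recursive, visits neighbours in reverse order, and
// canonicalizes by the lexicographically *maximal* image. Returns the count.
// [[Rcpp::export]]
double count_folds_check_cpp(bool identify_reversal) {
  std::vector<std::vector<int>> nb = cube_adjacency();
  std::vector<std::array<int, 27>> syms = cube_symmetries();
  std::unordered_set<std::string> seen;
  int path[27], iter[27];
  bool visited[27] = {false};
  for (int start = 26; start >= 0; --start) {
    int depth = 0;
    path[0] = start; iter[0] = (int) nb[start].size() - 1;
    visited[start] = true;
    while (depth >= 0) {
      if (depth == 26) {
        char best[27];
        for (int k = 0; k < 27; ++k) best[k] = (char) syms[0][path[k]];
        for (size_t s = 0; s < syms.size(); ++s) {
          for (int dir = 0; dir < (identify_reversal ? 2 : 1); ++dir) {
            if (s == 0 && dir == 0) continue;
            for (int k = 0; k < 27; ++k) {
              char v = (char) syms[s][dir == 0 ? path[k] : path[26 - k]];
              if (v < best[k]) break;
              if (v > best[k]) { // maximal image variant
                best[k] = v;
                for (int k2 = k + 1; k2 < 27; ++k2)
                  best[k2] = (char) syms[s][dir == 0 ? path[k2] : path[26 - k2]];
                break;
              }
            }
          }
        }
        seen.insert(std::string(best, 27));
        visited[path[depth]] = false;
        --depth;
        continue;
      }
      int cell = path[depth];
      bool advanced = false;
      while (iter[depth] >= 0) {
        int nxt = nb[cell][iter[depth]--];
        if (!visited[nxt]) {
          ++depth;
          path[depth] = nxt;
          iter[depth] = (int) nb[nxt].size() - 1;
          visited[nxt] = true;
          advanced = true;
          break;
        }
      }
      if (!advanced) {
        visited[cell] = false;
        --depth;
      }
    }
  }
  return (double) seen.size();
}

// Contact list of each fold: unordered residue pairs (1-based, |i-j| > 1)
// occupying lattice-adjacent cells. Every compact fold has exactly 28.
// [[Rcpp::export]]
IntegerMatrix fold_contacts_cpp(IntegerMatrix paths) {
  std::vector<std::vector<int>> nb = cube_adjacency();
  int F = paths.nrow();
  IntegerMatrix out(F, 56);
  std::vector<int> res(27);
  for (int f = 0; f < F; ++f) {
    for (int k = 0; k < 27; ++k) res[paths(f, k)] = k;
    int n = 0;
    for (int c = 0; c < 27; ++c) {
      for (int d : nb[c]) {
        if (d <= c) continue;
        int i = res[c], j = res[d];
        if (std::abs(i - j) <= 1) continue;
        if (n >= 28) stop("fold %d has more than 28 contacts", f + 1);
        out(f, 2 * n) = std::min(i, j) + 1;
        out(f, 2 * n + 1) = std::max(i, j) + 1;
        ++n;
      }
    }
    if (n != 28) stop("fold %d has %d contacts (expected 28)", f + 1, n);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Energies and native-fold probability
// ---------------------------------------------------------------------------

// Folding energy of one sequence (codes 1..20) on every fold.
static void energies_one(const IntegerMatrix &contacts, const int *seq,
                         const NumericMatrix &mj, std::vector<double> &eps) {
  int F = contacts.nrow();
  for (int f = 0; f < F; ++f) {
    double e = 0.0;
    for (int c = 0; c < 28; ++c) {
      int i = contacts(f, 2 * c) - 1, j = contacts(f, 2 * c + 1) - 1;
      e += mj(seq[i] - 1, seq[j] - 1);
    }
    eps[f] = e;
  }
}

// [[Rcpp::export]]
NumericVector fold_energies_cpp(IntegerMatrix contacts, IntegerVector seq,
                                NumericMatrix mj) {
  std::vector<double> eps(contacts.nrow());
  std::vector<int> s(seq.begin(), seq.end());
  energies_one(contacts, s.data(), mj, eps);
  return wrap(eps);
}

// P_nat and H = -log P_nat for each row of seqs (M x 27, codes 1..20).
// [[Rcpp::export]]
List pnat_h_cpp(IntegerMatrix contacts, int native, IntegerMatrix seqs,
                NumericMatrix mj) {
  int M = seqs.nrow(), F = contacts.nrow();
  if (native < 1 || native > F) stop("native fold index out of range");
  NumericVector pnat(M), H(M);
  std::vector<double> eps(F);
  std::vector<int> s(27);
  for (int m = 0; m < M; ++m) {
    for (int k = 0; k < 27; ++k) s[k] = seqs(m, k);
    energies_one(contacts, s.data(), mj, eps);
    double mn = eps[0];
    for (int f = 1; f < F; ++f) if (eps[f] < mn) mn = eps[f];
    double Z = 0.0;
    for (int f = 0; f < F; ++f) Z += std::exp(-(eps[f] - mn));
    double lp = -(eps[native - 1] - mn) - std::log(Z);
    pnat[m] = std::exp(lp);
    H[m] = -lp;
  }
  return List::create(_["pnat"] = pnat, _["H"] = H);
}

// ---------------------------------------------------------------------------
// Metropolis chain on the distance-biased Hamiltonian
//   H_gamma(s) = -log P_nat(s) + gamma * d(wt, s) / N   (normalized distance)
// acceptance min(1, exp(-beta * Delta H_gamma)); one row recorded every
// `thin` proposals. Uses R's RNG so results are reproducible via set.seed().
// ---------------------------------------------------------------------------

// Fast sampler: maintains Boltzmann weights w_f = exp(-(eps_f - C))
// incrementally. A single-site proposal multiplies each affected fold's
// weight by exp(-v_j) per contact partner j, where v_j depends only on the
// partner's residue — so one proposal needs ~27 exp calls instead of one
// per fold. The reference C and all weights are refreshed periodically to
// bound floating-point drift.
// [[Rcpp::export]]
IntegerMatrix metropolis_sample_cpp(IntegerMatrix contacts, int native,
                                    IntegerVector wt, NumericMatrix mj,
                                    double gamma, double beta,
                                    int thin, int n_samples) {
  int F = contacts.nrow();
  if (wt.size() != 27) stop("wt must have 27 sites");
  std::vector<std::vector<std::pair<int,int>>> inc(27);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < 28; ++c) {
      int i = contacts(f, 2 * c) - 1, j = contacts(f, 2 * c + 1) - 1;
      inc[i].push_back(std::make_pair(f, j));
      inc[j].push_back(std::make_pair(f, i));
    }
  std::vector<int> s(wt.begin(), wt.end());
  std::vector<double> eps(F), w(F), saved_w(F), saved_eps(F);
  std::vector<char> mark(F, 0);
  std::vector<int> touched;
  touched.reserve(F);
  energies_one(contacts, s.data(), mj, eps);
  int nat = native - 1;
  double C = 0.0, S = 0.0, H = 0.0;
  auto refresh = [&]() {
    C = eps[nat];
    S = 0.0;
    for (int f = 0; f < F; ++f) {
      w[f] = std::exp(-(eps[f] - C));
      S += w[f];
    }
    H = std::log(S); // eps[nat] - C is zero by construction
  };
  refresh();
  int d = 0; // raw-count distance to wt
  double v[27], e[27];
  IntegerMatrix out(n_samples, 27);
  int since_refresh = 0;
  for (int rec = 0; rec < n_samples; ++rec) {
    for (int step = 0; step < thin; ++step) {
      // refresh early once the native energy drifts away from the
      // reference: S is maintained by small increments and would lose
      // precision to cancellation as soon as it leaves the O(1) range
      if (++since_refresh >= 128 || std::fabs(eps[nat] - C) > 5.0) {
        refresh();
        since_refresh = 0;
      }
      int i = (int) std::floor(unif_rand() * 27.0);
      if (i > 26) i = 26;
      int a = 1 + (int) std::floor(unif_rand() * 19.0);
      if (a >= s[i]) ++a; // uniform over the 19 other residues
      int old = s[i];
      for (int j = 0; j < 27; ++j) {
        v[j] = mj(a - 1, s[j] - 1) - mj(old - 1, s[j] - 1);
        e[j] = std::exp(-v[j]);
      }
      touched.clear();
      for (size_t t = 0; t < inc[i].size(); ++t) {
        int f = inc[i][t].first, j = inc[i][t].second;
        if (!mark[f]) {
          mark[f] = 1;
          touched.push_back(f);
          saved_w[f] = w[f];
          saved_eps[f] = eps[f];
        }
        w[f] *= e[j];
        eps[f] += v[j];
      }
      double Snew = S;
      for (int f : touched) Snew += w[f] - saved_w[f];
      double Hnew;
      if (!(Snew > 0.0) || !std::isfinite(Snew)) {
        // drift guard: recompute from the exact energies
        double mn = eps[0];
        for (int f = 1; f < F; ++f) if (eps[f] < mn) mn = eps[f];
        double Z = 0.0;
        for (int f = 0; f < F; ++f) Z += std::exp(-(eps[f] - mn));
        Hnew = (eps[nat] - mn) + std::log(Z);
      } else {
        Hnew = (eps[nat] - C) + std::log(Snew);
      }
      int dnew = d + (a == wt[i] ? 0 : 1) - (old == wt[i] ? 0 : 1);
      // gamma > 0 biases the chain toward the wild type; the distance in
      // the biased Hamiltonian is normalized (d/N), the convention used for
      // Hamming distances throughout the reweighting machinery
      double dHg = (Hnew - H) + gamma * (double)(dnew - d) / 27.0;
      bool accept = dHg <= 0.0 || unif_rand() < std::exp(-beta * dHg);
      if (accept) {
        s[i] = a;
        S = Snew;
        H = Hnew;
        d = dnew;
      } else {
        for (int f : touched) {
          w[f] = saved_w[f];
          eps[f] = saved_eps[f];
        }
      }
      for (int f : touched) mark[f] = 0;
    }
    for (int k = 0; k < 27; ++k) out(rec, k) = s[k];
  }
  return out;
}

// Naive reference sampler (full stabilized log-sum-exp on every proposal);
// kept as the independent cross-check for the fast implementation.
// [[Rcpp::export]]
IntegerMatrix metropolis_sample_naive_cpp(IntegerMatrix contacts, int native,
                                          IntegerVector wt, NumericMatrix mj,
                                          double gamma, double beta,
                                          int thin, int n_samples) {
  int F = contacts.nrow();
  if (wt.size() != 27) stop("wt must have 27 sites");
  std::vector<int> s(wt.begin(), wt.end());
  std::vector<double> eps(F);
  int nat = native - 1;
  auto curH = [&]() {
    energies_one(contacts, s.data(), mj, eps);
    double mn = eps[0];
    for (int f = 1; f < F; ++f) if (eps[f] < mn) mn = eps[f];
    double Z = 0.0;
    for (int f = 0; f < F; ++f) Z += std::exp(-(eps[f] - mn));
    return (eps[nat] - mn) + std::log(Z);
  };
  double H = curH();
  int d = 0;
  IntegerMatrix out(n_samples, 27);
  for (int rec = 0; rec < n_samples; ++rec) {
    for (int step = 0; step < thin; ++step) {
      int i = (int) std::floor(unif_rand() * 27.0);
      if (i > 26) i = 26;
      int a = 1 + (int) std::floor(unif_rand() * 19.0);
      if (a >= s[i]) ++a;
      int old = s[i];
      s[i] = a;
      double Hnew = curH();
      int dnew = d + (a == wt[i] ? 0 : 1) - (old == wt[i] ? 0 : 1);
      double dHg = (Hnew - H) + gamma * (double)(dnew - d) / 27.0;
      bool accept = dHg <= 0.0 || unif_rand() < std::exp(-beta * dHg);
      if (accept) {
        H = Hnew;
        d = dnew;
      } else {
        s[i] = old;
      }
    }
    for (int k = 0; k < 27; ++k) out(rec, k) = s[k];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sequence reweighting: z(s) = 1 / #{s' : d_norm(s, s') < threshold}
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector msa_weights_cpp(IntegerMatrix seqs, double threshold) {
  int M = seqs.nrow(), N = seqs.ncol();
  std::vector<int> counts(M, 1); // self always counted
  int cut = (int) std::ceil(threshold * N); // d < thr*N  <=>  d <= cut - 1
  for (int a = 0; a < M; ++a) {
    for (int b = a + 1; b < M; ++b) {
      int d = 0;
      for (int k = 0; k < N; ++k) {
        if (seqs(a, k) != seqs(b, k)) {
          ++d;
          if (d >= cut) break;
        }
      }
      if ((double) d / N < threshold) {
        ++counts[a];
        ++counts[b];
      }
    }
  }
  NumericVector w(M);
  for (int a = 0; a < M; ++a) w[a] = 1.0 / counts[a];
  return w;
}

// Raw Hamming distances of each row to a reference sequence.
// [[Rcpp::export]]
IntegerVector hamming_to_ref_cpp(IntegerMatrix seqs, IntegerVector ref) {
  int M = seqs.nrow(), N = seqs.ncol();
  if (ref.size() != N) stop("reference length mismatch");
  IntegerVector d(M);
  for (int a = 0; a < M; ++a) {
    int x = 0;
    for (int k = 0; k < N; ++k) x += (seqs(a, k) != ref[k]);
    d[a] = x;
  }
  return d;
}
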