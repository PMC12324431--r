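// Log-space dynamic programming kernels for the G6 and G5 RNA SCFGs.
//
// Sequences arrive as 0-based integer codes (0=A, 1=C, 2=G, 3=U).
// Intervals are closed [i,j], 0-based.  All recursions run in log space
// with explicit -Inf for impossible derivations.
//
// G6:  S -> LS (tS) | L (1-tS)
//      L -> aFb (tL * pbp(a,b)) | a ((1-tL) * ps(a))
//      F -> aFb (tF * pbp(a,b)) | LS (1-tF)
// F derives at least two residues, so every pair (i,j) satisfies
// j - i >= 3 (hairpin loop >= 2).
//
// G5:  S -> aS (tu * ps(a)) | aSbS (tp * pbp(a,b)) | eps (1-tu-tp)
// The empty interval scores 1 - tu - tp; adjacent pairs are allowed.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <utility>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logadd(double la, double lb) {
  if (la < lb) std::swap(la, lb);
  if (lb == NEG_INF) return la;
  const double d = lb - la;
  if (d < -37.0) return la;  // below double-precision resolution
  return la + std::log1p(std::exp(d));
}

static inline double slog(double x) { return x > 0.0 ? std::log(x) : NEG_INF; }

struct G6Log {
  double ltS, l1S, ltL, l1L, ltF, l1F;
  double lps[4];
  double lpbp[4][4];
  G6Log(double tS, double tL, double tF, NumericVector ps, NumericMatrix pbp) {
    ltS = slog(tS); l1S = slog(1.0 - tS);
    ltL = slog(tL); l1L = slog(1.0 - tL);
    ltF = slog(tF); l1F = slog(1.0 - tF);
    for (int a = 0; a < 4; ++a) lps[a] = slog(ps[a]);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) lpbp[a][b] = slog(pbp(a, b));
  }
};

// [[Rcpp::export]]
List g6_inside_cpp(IntegerVector s, double tS, double tL, double tF,
                   NumericVector ps, NumericMatrix pbp) {
  const int n = s.size();
  G6Log P(tS, tL, tF, ps, pbp);
  NumericMatrix IS(n, n), IL(n, n), IF(n, n), SPLIT(n, n);
  std::fill(IS.begin(), IS.end(), NEG_INF);
  std::fill(IL.begin(), IL.end(), NEG_INF);
  std::fill(IF.begin(), IF.end(), NEG_INF);
  std::fill(SPLIT.begin(), SPLIT.end(), NEG_INF);
  double* pIS = IS.begin();
  double* pIL = IL.begin();
  // ILt(k stored contiguously for fixed i): ILt[i*n + k] = IL(i,k)
  std::vector<double> ILt((size_t)n * n, NEG_INF);
  std::vector<double> w((size_t)n);

  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      if (len == 1) {
        const double l1 = P.l1L + P.lps[s[i]];
        IL(i, j) = l1;
        ILt[(size_t)i * n + j] = l1;
        IS(i, j) = P.l1S + l1;
        continue;
      }
      if (len >= 4) {
        const double lv = P.ltL + P.lpbp[s[i]][s[j]] + IF(i + 1, j - 1);
        IL(i, j) = lv;
        ILt[(size_t)i * n + j] = lv;
      }
      // split = logsumexp_k IL(i,k) + IS(k+1,j), two-pass over
      // contiguous buffers
      const double* rowL = &ILt[(size_t)i * n];
      const double* colS = pIS + (size_t)j * n;
      double m = NEG_INF;
      for (int k = i; k < j; ++k) {
        w[k] = rowL[k] + colS[k + 1];
        if (w[k] > m) m = w[k];
      }
      double split = NEG_INF;
      if (m != NEG_INF) {
        double acc = 0.0;
        for (int k = i; k < j; ++k)
          if (w[k] != NEG_INF) acc += std::exp(w[k] - m);
        split = m + std::log(acc);
      }
      SPLIT(i, j) = split;
      double f = P.l1F + split;
      if (len >= 4)
        f = logadd(f, P.ltF + P.lpbp[s[i]][s[j]] + IF(i + 1, j - 1));
      IF(i, j) = f;
      IS(i, j) = logadd(P.ltS + split, P.l1S + IL(i, j));
    }
  }
  (void)pIL;
  return List::create(_["loglik"] = n > 0 ? IS(0, n - 1) : NEG_INF,
                      _["IS"] = IS, _["IL"] = IL, _["IF"] = IF,
                      _["SPLIT"] = SPLIT);
}

// Outside pass + expected rule counts + base-pair / unpaired posteriors.
// The outside recursion is organized as gathers: every cell's value is a
// single log-sum-exp over contiguous slices of longer-interval results,
// using transposed copies where row access would otherwise be strided.
// [[Rcpp::export]]
List g6_outside_cpp(IntegerVector s, double tS, double tL, double tF,
                    NumericVector ps, NumericMatrix pbp,
                    NumericMatrix IS, NumericMatrix IL, NumericMatrix IF,
                    NumericMatrix SPLIT, double logZ) {
  const int n = s.size();
  G6Log P(tS, tL, tF, ps, pbp);
  NumericMatrix OS(n, n), OL(n, n), OF(n, n);
  std::fill(OS.begin(), OS.end(), NEG_INF);
  std::fill(OL.begin(), OL.end(), NEG_INF);
  std::fill(OF.begin(), OF.end(), NEG_INF);
  const double* pIS = IS.begin();
  const double* pIL = IL.begin();
  // transposed IS: ISt[r*n + c] = IS(r, c) stored so that row r is
  // contiguous; likewise combo in both orientations
  std::vector<double> ISt((size_t)n * n, NEG_INF);
  for (int c = 0; c < n; ++c)
    for (int r = 0; r <= c; ++r)
      ISt[(size_t)r * n + c] = pIS[(size_t)c * n + r];
  std::vector<double> comboC((size_t)n * n, NEG_INF);  // combo(i,j) at [j*n+i]
  std::vector<double> comboR((size_t)n * n, NEG_INF);  // combo(i,j) at [i*n+j]
  std::vector<double> w((size_t)n);

  for (int len = n; len >= 1; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      // OS(i,j): the right child of a split at (i', j), i' < i
      if (len == n) {
        OS(i, j) = 0.0;
      } else if (i >= 1) {
        const double* colC = &comboC[(size_t)j * n];   // combo(i', j)
        const double* colL = pIL + (size_t)(i - 1) * n; // IL(i', i-1)
        double m = NEG_INF;
        for (int a = 0; a < i; ++a) {
          w[a] = colC[a] + colL[a];
          if (w[a] > m) m = w[a];
        }
        if (m != NEG_INF) {
          double acc = 0.0;
          for (int a = 0; a < i; ++a)
            if (w[a] != NEG_INF) acc += std::exp(w[a] - m);
          OS(i, j) = m + std::log(acc);
        }
      }
      // OF(i,j): only reachable through the pair rules at (i-1, j+1)
      if (len >= 2 && i >= 1 && j <= n - 2) {
        const double lp = P.lpbp[s[i - 1]][s[j + 1]];
        double t = NEG_INF;
        if (OL(i - 1, j + 1) != NEG_INF) t = OL(i - 1, j + 1) + P.ltL + lp;
        if (OF(i - 1, j + 1) != NEG_INF)
          t = logadd(t, OF(i - 1, j + 1) + P.ltF + lp);
        OF(i, j) = t;
      }
      // OL(i,j): S -> L at the same interval, plus the left child of a
      // split at (i, j'), j' > j
      double ol = (OS(i, j) == NEG_INF) ? NEG_INF : OS(i, j) + P.l1S;
      if (j < n - 1) {
        const double* rowC = &comboR[(size_t)i * n];      // combo(i, j')
        const double* rowS = &ISt[(size_t)(j + 1) * n];   // IS(j+1, j')
        double m = NEG_INF;
        for (int b = j + 1; b < n; ++b) {
          w[b] = rowC[b] + rowS[b];
          if (w[b] > m) m = w[b];
        }
        if (m != NEG_INF) {
          double acc = 0.0;
          for (int b = j + 1; b < n; ++b)
            if (w[b] != NEG_INF) acc += std::exp(w[b] - m);
          ol = logadd(ol, m + std::log(acc));
        }
      }
      OL(i, j) = ol;
      // combo: outside mass feeding split children (S -> LS, F -> LS)
      double cb = (OS(i, j) == NEG_INF) ? NEG_INF : OS(i, j) + P.ltS;
      if (len >= 2 && OF(i, j) != NEG_INF)
        cb = logadd(cb, OF(i, j) + P.l1F);
      comboC[(size_t)j * n + i] = cb;
      comboR[(size_t)i * n + j] = cb;
    }
  }

  double nSLS = 0, nSL = 0, nLaFb = 0, nLa = 0, nFaFb = 0, nFLS = 0;
  NumericVector ps_counts(4);
  NumericMatrix pbp_counts(4, 4);
  NumericMatrix pair_post(n, n);
  NumericVector unpaired_post(n);

  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      const int len = j - i + 1;
      if (len == 1 && OL(i, i) != NEG_INF) {
        double eU = std::exp(OL(i, i) + P.l1L + P.lps[s[i]] - logZ);
        nLa += eU;
        ps_counts[s[i]] += eU;
        unpaired_post[i] = eU;
      }
      if (len >= 4) {
        const double em = P.lpbp[s[i]][s[j]] + IF(i + 1, j - 1);
        double eL = (OL(i, j) == NEG_INF) ? 0.0
                      : std::exp(OL(i, j) + P.ltL + em - logZ);
        double eF = (OF(i, j) == NEG_INF) ? 0.0
                      : std::exp(OF(i, j) + P.ltF + em - logZ);
        nLaFb += eL;
        nFaFb += eF;
        pbp_counts(s[i], s[j]) += eL + eF;
        pair_post(i, j) = eL + eF;
      }
      if (len >= 2 && SPLIT(i, j) != NEG_INF) {
        if (OS(i, j) != NEG_INF)
          nSLS += std::exp(OS(i, j) + P.ltS + SPLIT(i, j) - logZ);
        if (OF(i, j) != NEG_INF)
          nFLS += std::exp(OF(i, j) + P.l1F + SPLIT(i, j) - logZ);
      }
      if (OS(i, j) != NEG_INF && IL(i, j) != NEG_INF)
        nSL += std::exp(OS(i, j) + P.l1S + IL(i, j) - logZ);
    }
  }

  return List::create(
      _["counts"] = NumericVector::create(
          _["SLS"] = nSLS, _["SL"] = nSL, _["LaFb"] = nLaFb, _["La"] = nLa,
          _["FaFb"] = nFaFb, _["FLS"] = nFLS),
      _["ps_counts"] = ps_counts, _["pbp_counts"] = pbp_counts,
      _["pair_post"] = pair_post, _["unpaired_post"] = unpaired_post);
}

struct G5Log {
  double ltu, ltp, leps;
  double lps[4];
  double lpbp[4][4];
  G5Log(double tu, double tp, NumericVector ps, NumericMatrix pbp) {
    ltu = slog(tu); ltp = slog(tp); leps = slog(1.0 - tu - tp);
    for (int a = 0; a < 4; ++a) lps[a] = slog(ps[a]);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) lpbp[a][b] = slog(pbp(a, b));
  }
};

static inline double g5_val(const NumericMatrix& I, int i, int j, double leps) {
  return (i > j) ? leps : I(i, j);
}

// [[Rcpp::export]]
List g5_inside_cpp(IntegerVector s, double tu, double tp,
                   NumericVector ps, NumericMatrix pbp) {
  const int n = s.size();
  G5Log P(tu, tp, ps, pbp);
  NumericMatrix I(n, n);
  std::fill(I.begin(), I.end(), NEG_INF);
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double acc = P.ltu + P.lps[s[i]] + g5_val(I, i + 1, j, P.leps);
      for (int k = i + 1; k <= j; ++k)
        acc = logadd(acc, P.ltp + P.lpbp[s[i]][s[k]] +
                            g5_val(I, i + 1, k - 1, P.leps) +
                            g5_val(I, k + 1, j, P.leps));
      I(i, j) = acc;
    }
  }
  return List::create(_["loglik"] = n > 0 ? I(0, n - 1) : NEG_INF,
                      _["I"] = I);
}

// [[Rcpp::export]]
List g5_outside_cpp(IntegerVector s, double tu, double tp,
                    NumericVector ps, NumericMatrix pbp,
                    NumericMatrix I, double logZ) {
  const int n = s.size();
  G5Log P(tu, tp, ps, pbp);
  NumericMatrix O(n, n);
  std::fill(O.begin(), O.end(), NEG_INF);
  O(0, n - 1) = 0.0;

  for (int len = n; len >= 1; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      if (O(i, j) == NEG_INF) continue;
      if (i < j)
        O(i + 1, j) = logadd(O(i + 1, j), O(i, j) + P.ltu + P.lps[s[i]]);
      for (int k = i + 1; k <= j; ++k) {
        const double em = O(i, j) + P.ltp + P.lpbp[s[i]][s[k]];
        if (k - 1 >= i + 1)
          O(i + 1, k - 1) = logadd(O(i + 1, k - 1),
                                   em + g5_val(I, k + 1, j, P.leps));
        if (j >= k + 1)
          O(k + 1, j) = logadd(O(k + 1, j),
                               em + g5_val(I, i + 1, k - 1, P.leps));
      }
    }
  }

  double n_aS = 0, n_aSbS = 0;
  NumericVector ps_counts(4);
  NumericMatrix pbp_counts(4, 4);
  NumericMatrix pair_post(n, n);
  NumericVector unpaired_post(n);

  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      if (O(i, j) == NEG_INF) continue;
      double eU = std::exp(O(i, j) + P.ltu + P.lps[s[i]] +
                           g5_val(I, i + 1, j, P.leps) - logZ);
      n_aS += eU;
      ps_counts[s[i]] += eU;
      unpaired_post[i] += eU;
      for (int k = i + 1; k <= j; ++k) {
        double eP = std::exp(O(i, j) + P.ltp + P.lpbp[s[i]][s[k]] +
                             g5_val(I, i + 1, k - 1, P.leps) +
                             g5_val(I, k + 1, j, P.leps) - logZ);
        n_aSbS += eP;
        pbp_counts(s[i], s[k]) += eP;
        pair_post(i, k) += eP;
      }
    }
  }

  return List::create(
      _["counts"] = NumericVector::create(
          _["aS"] = n_aS, _["aSbS"] = n_aSbS, _["eps"] = 1.0 + n_aSbS),
      _["ps_counts"] = ps_counts, _["pbp_counts"] = pbp_counts,
      _["pair_post"] = pair_post, _["unpaired_post"] = unpaired_post);
}

// ---------------------------------------------------------------- CYK --

// [[Rcpp::export]]
List g6_cyk_cpp(IntegerVector s, double tS, double tL, double tF,
                NumericVector ps, NumericMatrix pbp) {
  const int n = s.size();
  G6Log P(tS, tL, tF, ps, pbp);
  NumericMatrix CS(n, n), CL(n, n), CF(n, n);
  IntegerMatrix kS(n, n), kF(n, n);  // split choices; kS = -1: S->L; kF = -2: F->aFb
  std::fill(CS.begin(), CS.end(), NEG_INF);
  std::fill(CL.begin(), CL.end(), NEG_INF);
  std::fill(CF.begin(), CF.end(), NEG_INF);

  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      if (len == 1) {
        CL(i, j) = P.l1L + P.lps[s[i]];
        CS(i, j) = P.l1S + CL(i, j);
        kS(i, j) = -1;
        continue;
      }
      if (len >= 4)
        CL(i, j) = P.ltL + P.lpbp[s[i]][s[j]] + CF(i + 1, j - 1);
      // F: pair rule first, then splits in ascending k (strict > keeps
      // the lexicographically smallest choice on ties)
      double bestF = NEG_INF; int chF = -2;
      if (len >= 4)
        bestF = P.ltF + P.lpbp[s[i]][s[j]] + CF(i + 1, j - 1);
      for (int k = i; k < j; ++k) {
        double cand = P.l1F + CL(i, k) + CS(k + 1, j);
        if (cand > bestF) { bestF = cand; chF = k; }
      }
      CF(i, j) = bestF; kF(i, j) = chF;
      // S: S->L first, then splits ascending
      double bestS = P.l1S + CL(i, j); int chS = -1;
      for (int k = i; k < j; ++k) {
        double cand = P.ltS + CL(i, k) + CS(k + 1, j);
        if (cand > bestS) { bestS = cand; chS = k; }
      }
      CS(i, j) = bestS; kS(i, j) = chS;
    }
  }

  // traceback: stack of (nonterminal, i, j); 0=S, 1=L, 2=F
  std::vector<std::pair<int, int>> pairs;
  std::vector<std::array<int, 3>> stack;
  stack.push_back({0, 0, n - 1});
  while (!stack.empty()) {
    auto fr = stack.back(); stack.pop_back();
    int nt = fr[0], i = fr[1], j = fr[2];
    if (nt == 0) {
      int k = kS(i, j);
      if (k < 0) stack.push_back({1, i, j});
      else { stack.push_back({1, i, k}); stack.push_back({0, k + 1, j}); }
    } else if (nt == 1) {
      if (i == j) continue;
      pairs.push_back({i, j});
      stack.push_back({2, i + 1, j - 1});
    } else {
      int k = kF(i, j);
      if (k == -2) { pairs.push_back({i, j}); stack.push_back({2, i + 1, j - 1}); }
      else { stack.push_back({1, i, k}); stack.push_back({0, k + 1, j}); }
    }
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;   // 1-based for R
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["logp"] = CS(0, n - 1), _["pairs"] = pm);
}

// [[Rcpp::export]]
List g5_cyk_cpp(IntegerVector s, double tu, double tp,
                NumericVector ps, NumericMatrix pbp) {
  const int n = s.size();
  G5Log P(tu, tp, ps, pbp);
  NumericMatrix C(n, n);
  IntegerMatrix ch(n, n);  // -1: aS, else pairing partner k
  std::fill(C.begin(), C.end(), NEG_INF);
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double best = P.ltu + P.lps[s[i]] + g5_val(C, i + 1, j, P.leps);
      int choice = -1;
      for (int k = i + 1; k <= j; ++k) {
        double cand = P.ltp + P.lpbp[s[i]][s[k]] +
                      g5_val(C, i + 1, k - 1, P.leps) +
                      g5_val(C, k + 1, j, P.leps);
        if (cand > best) { best = cand; choice = k; }
      }
      C(i, j) = best; ch(i, j) = choice;
    }
  }
  std::vector<std::pair<int, int>> pairs;
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    auto fr = stack.back(); stack.pop_back();
    int i = fr.first, j = fr.second;
    if (i > j) continue;
    int k = ch(i, j);
    if (k < 0) stack.push_back({i + 1, j});
    else {
      pairs.push_back({i, k});
      if (k - 1 >= i + 1) stack.push_back({i + 1, k - 1});
      if (j >= k + 1) stack.push_back({k + 1, j});
    }
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["logp"] = n > 0 ? C(0, n - 1) : P.leps,
                      _["pairs"] = pm);
}

// ---------------------------------------------------------------- MEA --
// Maximize sum over pairs of 2*gamma*pair_post(i,j) plus sum over
// unpaired positions of unpaired_post(i), over nested structures whose
// pairs all satisfy j - i >= min_span.  Ties prefer the unpaired option,
// then the smallest pairing partner.

// [[Rcpp::export]]
List mea_cpp(NumericMatrix pair_post, NumericVector unpaired_post,
             double gamma, int min_span) {
  const int n = unpaired_post.size();
  NumericMatrix M(n, n);
  IntegerMatrix ch(n, n);  // -1: i unpaired, else partner k
  std::fill(M.begin(), M.end(), 0.0);
  auto mval = [&](int i, int j) { return (i > j) ? 0.0 : M(i, j); };
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double best = unpaired_post[i] + mval(i + 1, j);
      int choice = -1;
      for (int k = i + min_span; k <= j; ++k) {
        double cand = 2.0 * gamma * pair_post(i, k) +
                      mval(i + 1, k - 1) + mval(k + 1, j);
        if (cand > best) { best = cand; choice = k; }
      }
      M(i, j) = best; ch(i, j) = choice;
    }
  }
  std::vector<std::pair<int, int>> pairs;
  std::vector<std::pair<int, int>> stack;
  if (n > 0) stack.push_back({0, n - 1});
  while (!stack.empty()) {
    auto fr = stack.back(); stack.pop_back();
    int i = fr.first, j = fr.second;
    if (i > j) continue;
    int k = ch(i, j);
    if (k < 0) stack.push_back({i + 1, j});
    else {
      pairs.push_back({i, k});
      if (k - 1 >= i + 1) stack.push_back({i + 1, k - 1});
      if (j >= k + 1) stack.push_back({k + 1, j});
    }
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first + 1;
    pm(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["score"] = n > 0 ? M(0, n - 1) : 0.0,
                      _["pairs"] = pm);
}
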