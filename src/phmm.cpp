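#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Local (uniform fragment entry/exit) profile-HMM scoring in log-odds
// space. Paths are anchored on match states; flanking residues score 0
// against the background; a no-match path of odds 1 is always
// available, so scores are bounded below by 0 bits.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// transitions columns: 0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 DM, 6 DD
// lm, li: L x 20 log-odds emission matrices; seq: 0-based residue
// indices, -1 for unknown (odds 1).

// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(NumericMatrix lm, NumericMatrix li,
                    NumericMatrix ltr, IntegerVector seq) {
  const int L = lm.nrow(), n = seq.size();
  const double entry = std::log(2.0 / (double(L) * (L + 1.0)));
  double total = 0.0;  // log-odds of the no-match path (odds 1)
  if (n == 0) return 0.0;
  std::vector<double> vmPrev(L, NEG_INF), viPrev(L, NEG_INF);
  std::vector<double> vdPrev(L, NEG_INF);
  std::vector<double> vm(L), vi(L), vd(L);
  for (int i = 0; i < n; ++i) {
    const int x = seq[i];
    for (int k = 0; k < L; ++k) {
      const double em = (x >= 0) ? lm(k, x) : 0.0;
      double acc = entry;
      if (k > 0 && i > 0) {
        acc = lse2(acc, vmPrev[k - 1] + ltr(k - 1, 0));
        acc = lse2(acc, viPrev[k - 1] + ltr(k - 1, 3));
        acc = lse2(acc, vdPrev[k - 1] + ltr(k - 1, 5));
      }
      vm[k] = em + acc;
    }
    for (int k = 0; k < L - 1; ++k) {
      const double ei = (x >= 0) ? li(k, x) : 0.0;
      double acc = NEG_INF;
      if (i > 0) {
        acc = lse2(vmPrev[k] + ltr(k, 1), viPrev[k] + ltr(k, 4));
      }
      vi[k] = ei + acc;
    }
    if (L - 1 >= 0) vi[L - 1] = NEG_INF;
    vd[0] = NEG_INF;
    for (int k = 1; k < L; ++k) {
      vd[k] = lse2(vm[k - 1] + ltr(k - 1, 2), vd[k - 1] + ltr(k - 1, 6));
    }
    for (int k = 0; k < L; ++k) total = lse2(total, vm[k]);
    vmPrev = vm; viPrev = vi; vdPrev = vd;
  }
  return total / std::log(2.0);
}

// [[Rcpp::export(name = ".phmm_viterbi")]]
List phmm_viterbi(NumericMatrix lm, NumericMatrix li,
                  NumericMatrix ltr, IntegerVector seq) {
  const int L = lm.nrow(), n = seq.size();
  const double entry = std::log(2.0 / (double(L) * (L + 1.0)));
  if (n == 0)
    return List::create(_["bits"] = 0.0,
                        _["path"] = CharacterVector(0));
  // DP matrices (n x L); pointers: 0 start, 1 M, 2 I, 3 D
  std::vector<std::vector<double> > VM(n, std::vector<double>(L, NEG_INF)),
      VI(n, std::vector<double>(L, NEG_INF)),
      VD(n, std::vector<double>(L, NEG_INF));
  std::vector<std::vector<int> > PM(n, std::vector<int>(L, 0)),
      PI(n, std::vector<int>(L, 0)), PD(n, std::vector<int>(L, 0));
  for (int i = 0; i < n; ++i) {
    const int x = seq[i];
    for (int k = 0; k < L; ++k) {
      const double em = (x >= 0) ? lm(k, x) : 0.0;
      double best = entry; int ptr = 0;
      if (k > 0 && i > 0) {
        double c = VM[i - 1][k - 1] + ltr(k - 1, 0);
        if (c > best) { best = c; ptr = 1; }
        c = VI[i - 1][k - 1] + ltr(k - 1, 3);
        if (c > best) { best = c; ptr = 2; }
        c = VD[i - 1][k - 1] + ltr(k - 1, 5);
        if (c > best) { best = c; ptr = 3; }
      }
      VM[i][k] = em + best; PM[i][k] = ptr;
    }
    for (int k = 0; k < L - 1; ++k) {
      if (i == 0) continue;
      const double ei = (x >= 0) ? li(k, x) : 0.0;
      double a = VM[i - 1][k] + ltr(k, 1);
      double b = VI[i - 1][k] + ltr(k, 4);
      if (a >= b) { VI[i][k] = ei + a; PI[i][k] = 1; }
      else        { VI[i][k] = ei + b; PI[i][k] = 2; }
    }
    for (int k = 1; k < L; ++k) {
      double a = VM[i][k - 1] + ltr(k - 1, 2);
      double b = VD[i][k - 1] + ltr(k - 1, 6);
      if (a >= b) { VD[i][k] = a; PD[i][k] = 1; }
      else        { VD[i][k] = b; PD[i][k] = 3; }
    }
  }
  double best = 0.0; int bi = -1, bk = -1;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < L; ++k)
      if (VM[i][k] > best) { best = VM[i][k]; bi = i; bk = k; }
  std::vector<std::string> path;
  if (bi >= 0) {
    int st = 1, i = bi, k = bk;
    while (true) {
      char code = st == 1 ? 'M' : (st == 2 ? 'I' : 'D');
      path.push_back(code + std::to_string(k + 1));
      int ptr;
      if (st == 1) {
        ptr = PM[i][k];
        if (ptr == 0) break;
        --i; --k; st = ptr;
      } else if (st == 2) {
        ptr = PI[i][k];
        --i; st = ptr;
      } else {
        ptr = PD[i][k];
        --k; st = ptr;
      }
    }
    std::reverse(path.begin(), path.end());
  }
  return List::create(_["bits"] = best / std::log(2.0),
                      _["path"] = wrap(path));
}
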