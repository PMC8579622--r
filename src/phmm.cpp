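// Local-alignment dynamic programming for a nucleotide profile HMM.
//
// Model grammar (Plan-7-like local mode, no J segment):
//   entry: B -> M_k for any k with probability 1/M
//   core:  M_k -> {M_{k+1}, I_k, D_{k+1}},  I_k -> {I_k, M_{k+1}},
//          D_k -> {M_{k+1}, D_{k+1}}
//   exit:  any M_k -> E (free)
// Scores are log2 odds against an i.i.d. background; a path's bit score is
//   log2(1/M) + sum(log2 t) + sum(log2 e(x)/q(x)).
// Residue codes: 0..3 = ACGT, 4 = N (neutral, log-odds 0), 5 = masked
// (forbidden: -inf), matching the R-side encoder.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const double NEG = -1e30;

static inline double emis(const NumericMatrix& lo, int k, int code) {
  if (code == 4) return 0.0;        // N: missing data, neutral
  if (code >= 5) return NEG;        // masked span
  return lo(k, code);
}

// base-2 log-sum-exp of two terms
static inline double lse2(double a, double b) {
  if (a < b) { double t = a; a = b; b = t; }
  if (b <= NEG / 2) return a;
  return a + std::log1p(std::exp2(b - a)) / M_LN2;
}

// Flat, cache-friendly copy of the model for the hot loops. Emission rows
// use stride 6 over residue codes 0..5 (ACGT, N neutral, mask forbidden).
struct FlatModel {
  int M;
  std::vector<double> em, ei;                    // M x 6 each
  std::vector<double> tMM, tMI, tMD, tIM, tII, tDM, tDD;
  double entry;
  FlatModel(const NumericMatrix& lom, const NumericMatrix& loi,
            const NumericMatrix& trans)
      : M(lom.nrow()), em(6 * lom.nrow()), ei(6 * lom.nrow()),
        tMM(lom.nrow()), tMI(lom.nrow()), tMD(lom.nrow()),
        tIM(lom.nrow()), tII(lom.nrow()), tDM(lom.nrow()),
        tDD(lom.nrow()), entry(-std::log2((double)lom.nrow())) {
    for (int k = 0; k < M; ++k) {
      for (int c = 0; c < 4; ++c) {
        em[6 * k + c] = lom(k, c);
        ei[6 * k + c] = loi(k, c);
      }
      em[6 * k + 4] = 0.0; ei[6 * k + 4] = 0.0;   // N: neutral
      em[6 * k + 5] = NEG; ei[6 * k + 5] = NEG;   // masked
      tMM[k] = trans(k, 0); tMI[k] = trans(k, 1); tMD[k] = trans(k, 2);
      tIM[k] = trans(k, 3); tII[k] = trans(k, 4);
      tDM[k] = trans(k, 5); tDD[k] = trans(k, 6);
    }
  }
};

// Rolling-row Viterbi over the whole sequence; returns best score and the
// cell (end position, end match state) achieving it. 1-based outputs.
static void viterbi_best(const FlatModel& fm, const std::vector<int>& seq,
                         double* best, int* best_i, int* best_k) {
  const int M = fm.M, n = (int)seq.size();
  const double entry = fm.entry;
  std::vector<double> vmp(M, NEG), vip(M, NEG), vdp(M, NEG);
  std::vector<double> vm(M, NEG), vi(M, NEG), vd(M, NEG);
  double bestv = NEG; int bi = 0, bk = 0;
  const double* em = fm.em.data();
  const double* ei = fm.ei.data();
  const double* tMM = fm.tMM.data(); const double* tMI = fm.tMI.data();
  const double* tMD = fm.tMD.data(); const double* tIM = fm.tIM.data();
  const double* tII = fm.tII.data(); const double* tDM = fm.tDM.data();
  const double* tDD = fm.tDD.data();
  for (int i = 0; i < n; ++i) {
    const int c = seq[i];
    double* pm = vmp.data(); double* pi_ = vip.data();
    double* pd = vdp.data();
    double* cm = vm.data(); double* ci = vi.data(); double* cd = vd.data();
    {
      // k = 0: entry only
      cm[0] = em[c] + entry;
      ci[0] = (M > 1) ? ei[c] + std::max(pm[0] + tMI[0], pi_[0] + tII[0])
                      : NEG;
      cd[0] = NEG;
      if (cm[0] > bestv) { bestv = cm[0]; bi = i + 1; bk = 1; }
    }
    for (int k = 1; k < M; ++k) {
      double sc = entry;
      double a = pm[k - 1] + tMM[k - 1];
      double b = pi_[k - 1] + tIM[k - 1];
      double d = pd[k - 1] + tDM[k - 1];
      if (a > sc) sc = a;
      if (b > sc) sc = b;
      if (d > sc) sc = d;
      const double* erow = em + 6 * k;
      cm[k] = erow[c] + sc;
      if (k < M - 1) {
        double x = pm[k] + tMI[k];
        double y = pi_[k] + tII[k];
        ci[k] = ei[6 * k + c] + (x > y ? x : y);
      } else ci[k] = NEG;
      double u = cm[k - 1] + tMD[k - 1];
      double v = cd[k - 1] + tDD[k - 1];
      cd[k] = (u > v ? u : v);
      if (cm[k] > bestv) { bestv = cm[k]; bi = i + 1; bk = k + 1; }
    }
    vmp.swap(vm); vip.swap(vi); vdp.swap(vd);
  }
  *best = bestv; *best_i = bi; *best_k = bk;
}

// [[Rcpp::export(name = ".phmm_viterbi_best")]]
NumericVector phmm_viterbi_best(NumericMatrix lom, NumericMatrix loi,
                                NumericMatrix trans, IntegerVector seq) {
  FlatModel fm(lom, loi, trans);
  std::vector<int> s(seq.begin(), seq.end());
  double best; int bi, bk;
  viterbi_best(fm, s, &best, &bi, &bk);
  return NumericVector::create(best, (double)bi, (double)bk);
}

// Full-matrix Viterbi with traceback on seq[from..to] (0-based inclusive,
// global frame). Returns score, start, end, start state k1, path string.
struct TraceHit { double score; int start, end, k1, k2; std::string path; };

static bool viterbi_trace(const NumericMatrix& lom, const NumericMatrix& loi,
                          const NumericMatrix& trans,
                          const std::vector<int>& seq, int from, int to,
                          int end_k, double expect, TraceHit* out) {
  const int M = lom.nrow();
  const int L = to - from + 1;
  const double entry = -std::log2((double)M);
  // DP matrices (L+1) x M; ptr codes: 0 entry, 1 M, 2 I, 3 D
  std::vector<double> vm((L + 1) * M, NEG), vi((L + 1) * M, NEG),
      vd((L + 1) * M, NEG);
  std::vector<signed char> pm((L + 1) * M, -1), pi((L + 1) * M, -1),
      pd((L + 1) * M, -1);
  auto at = [M](int i, int k) { return i * M + k; };
  for (int i = 1; i <= L; ++i) {
    const int c = seq[from + i - 1];
    for (int k = 0; k < M; ++k) {
      double sc = entry; int pt = 0;
      if (k > 0) {
        double a = vm[at(i - 1, k - 1)] + trans(k - 1, 0);
        double b = vi[at(i - 1, k - 1)] + trans(k - 1, 3);
        double d = vd[at(i - 1, k - 1)] + trans(k - 1, 5);
        if (a > sc) { sc = a; pt = 1; }
        if (b > sc) { sc = b; pt = 2; }
        if (d > sc) { sc = d; pt = 3; }
      }
      vm[at(i, k)] = emis(lom, k, c) + sc; pm[at(i, k)] = (signed char)pt;
      if (k < M - 1) {
        double a = vm[at(i - 1, k)] + trans(k, 1);
        double b = vi[at(i - 1, k)] + trans(k, 4);
        if (a >= b) { vi[at(i, k)] = emis(loi, k, c) + a; pi[at(i, k)] = 1; }
        else        { vi[at(i, k)] = emis(loi, k, c) + b; pi[at(i, k)] = 2; }
      }
      if (k > 0) {
        double a = vm[at(i, k - 1)] + trans(k - 1, 2);
        double b = vd[at(i, k - 1)] + trans(k - 1, 6);
        if (a >= b) { vd[at(i, k)] = a; pd[at(i, k)] = 1; }
        else        { vd[at(i, k)] = b; pd[at(i, k)] = 3; }
      }
    }
  }
  // locate the best end cell in the requested end column
  int ei = -1;
  const int ek = end_k - 1;
  double bestv = NEG;
  for (int i = 1; i <= L; ++i)
    if (vm[at(i, ek)] > bestv) { bestv = vm[at(i, ek)]; ei = i; }
  // a truncated window cannot see paths entering before it: widen
  if (ei < 0 || (from > 0 && std::fabs(bestv - expect) > 1e-6)) return false;
  // traceback; cell semantics: M(i,k) and I(i,k) consumed residue i,
  // D(i,k) has consumed i residues so far
  std::string rev;
  int i = ei, k = ek, st = 1; // st: 1=M, 2=I, 3=D
  while (true) {
    if (st == 1) {
      rev.push_back('M');
      int pt = pm[at(i, k)];
      if (pt == 0) break;     // local entry: path starts at residue i
      st = pt; --i; --k;      // all of M/I/D predecessors sit at (i-1, k-1)
    } else if (st == 2) {
      rev.push_back('I');
      st = pi[at(i, k)]; --i; // M/I predecessor at (i-1, k)
    } else {
      rev.push_back('D');
      st = pd[at(i, k)]; --k; // M/D predecessor at (i, k-1)
    }
  }
  out->score = bestv;
  out->start = from + i;      // i is 1-based within the window here
  out->end = from + ei;
  out->k1 = k + 1;
  out->k2 = end_k;
  out->path.assign(rev.rbegin(), rev.rend());
  // path flush against a truncated window start may itself be truncated
  return !(from > 0 && out->start == from + 1);
}

// Multi-hit scan by mask-and-rescan. Returns a list of hits with 1-based
// start/end, bit score, model columns k1/k2 and the MID path string.
// [[Rcpp::export(name = ".phmm_scan")]]
List phmm_scan(NumericMatrix lom, NumericMatrix loi, NumericMatrix trans,
               IntegerVector seq, double min_score, int max_hits = 10000) {
  FlatModel fm(lom, loi, trans);
  std::vector<int> s(seq.begin(), seq.end());
  const int M = lom.nrow(), n = (int)s.size();
  std::vector<double> score; std::vector<int> st, en, k1, k2;
  std::vector<std::string> paths;
  for (int iter = 0; iter < max_hits; ++iter) {
    double best; int bi, bk;
    viterbi_best(fm, s, &best, &bi, &bk);
    if (best < min_score || bi == 0) break;
    int win = 4 * M + 200;
    TraceHit h;
    bool ok = false;
    while (!ok) {
      int from = bi - win; if (from < 0) from = 0;
      ok = viterbi_trace(lom, loi, trans, s, from, bi - 1, bk, best, &h);
      if (from == 0) break; // full prefix is exact; accept whatever it found
      win *= 2;
    }
    score.push_back(h.score); st.push_back(h.start); en.push_back(h.end);
    k1.push_back(h.k1); k2.push_back(h.k2); paths.push_back(h.path);
    for (int i = h.start - 1; i < h.end && i < n; ++i) s[i] = 5;
  }
  return List::create(_["score"] = wrap(score), _["start"] = wrap(st),
                      _["end"] = wrap(en), _["k1"] = wrap(k1),
                      _["k2"] = wrap(k2), _["path"] = wrap(paths));
}

// Local forward score in bits: log2 of the sum over all legal local paths
// (all spans, entries and exits) of P(path, emissions)/P_background(span).
// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(NumericMatrix lom, NumericMatrix loi, NumericMatrix trans,
                    IntegerVector seq) {
  FlatModel fmod(lom, loi, trans);
  const int M = fmod.M, n = seq.size();
  const double entry = fmod.entry;
  std::vector<double> fmp(M, NEG), fip(M, NEG), fdp(M, NEG);
  std::vector<double> fm(M, NEG), fi(M, NEG), fd(M, NEG);
  double total = NEG;
  for (int i = 0; i < n; ++i) {
    const int c = seq[i];
    for (int k = 0; k < M; ++k) {
      double sc = entry;
      if (k > 0) {
        sc = lse2(sc, fmp[k - 1] + fmod.tMM[k - 1]);
        sc = lse2(sc, fip[k - 1] + fmod.tIM[k - 1]);
        sc = lse2(sc, fdp[k - 1] + fmod.tDM[k - 1]);
      }
      fm[k] = fmod.em[6 * k + c] + sc;
      if (k < M - 1)
        fi[k] = fmod.ei[6 * k + c] +
                lse2(fmp[k] + fmod.tMI[k], fip[k] + fmod.tII[k]);
      else fi[k] = NEG;
      if (k > 0)
        fd[k] = lse2(fm[k - 1] + fmod.tMD[k - 1],
                     fd[k - 1] + fmod.tDD[k - 1]);
      else fd[k] = NEG;
      total = lse2(total, fm[k]); // free exit from any match state
    }
    fmp.swap(fm); fip.swap(fi); fdp.swap(fd);
  }
  return total;
}

// Best Viterbi bit score for each row of an integer matrix of sequences
// (calibration workhorse).
// [[Rcpp::export(name = ".phmm_best_scores")]]
NumericVector phmm_best_scores(NumericMatrix lom, NumericMatrix loi,
                               NumericMatrix trans, IntegerMatrix seqs) {
  FlatModel fm(lom, loi, trans);
  const int nseq = seqs.nrow(), len = seqs.ncol();
  NumericVector out(nseq);
  std::vector<int> s(len);
  for (int r = 0; r < nseq; ++r) {
    for (int j = 0; j < len; ++j) s[j] = seqs(r, j);
    double best; int bi, bk;
    viterbi_best(fm, s, &best, &bi, &bk);
    out[r] = best;
  }
  return out;
}
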