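#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap (Gotoh) pairwise alignment with traceback, plus a score-only
// variant used to pick the best rotation/strand before a single full
// alignment. Bases are compared as uppercase ASCII; any column involving a
// non-ACGT character is scored as a mismatch and excluded from the
// transition/transversion tallies.

namespace {

const double NEG_INF = -1e30;

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline bool is_transition(char a, char b) {
  return (a == 'A' && b == 'G') || (a == 'G' && b == 'A') ||
         (a == 'C' && b == 'T') || (a == 'T' && b == 'C');
}

struct AlnStats {
  double score = 0;
  int matches = 0, mismatches = 0, transitions = 0, transversions = 0;
  int gap_events = 0, gap_nt = 0, columns = 0;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;  // 1-based inclusive
};

// state codes for traceback: 0 = M (diagonal), 1 = X (gap in b, consumes a),
// 2 = Y (gap in a, consumes b), 3 = stop
// mode: 0 = local, 1 = global, 2 = tail-overlap (local alignment forced to
// end at a's last position, used for dovetail contig extension)
AlnStats gotoh_align(const std::string& a, const std::string& b, int mode,
                     double match, double mismatch, double gap_open,
                     double gap_ext) {
  const bool global = mode == 1;
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF),
      X((size_t)(n + 1) * W, NEG_INF), Y((size_t)(n + 1) * W, NEG_INF);
  // ptr: predecessor state for each cell/state, packed 2 bits each
  std::vector<unsigned char> pM((size_t)(n + 1) * W, 3),
      pX((size_t)(n + 1) * W, 3), pY((size_t)(n + 1) * W, 3);

  M[0] = 0;
  if (global) {
    for (int i = 1; i <= n; ++i) {
      X[(size_t)i * W] = gap_open + gap_ext * (i - 1);
      pX[(size_t)i * W] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[(size_t)j] = gap_open + gap_ext * (j - 1);
      pY[(size_t)j] = (j == 1) ? 0 : 2;
    }
  } else {
    for (int i = 1; i <= n; ++i) M[(size_t)i * W] = 0;
    for (int j = 1; j <= m; ++j) M[(size_t)j] = 0;
  }

  double best = global ? NEG_INF : 0;
  int bi = 0, bj = 0, bstate = 0;

  for (int i = 1; i <= n; ++i) {
    const char ai = a[(size_t)i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)i * W + j, d = (size_t)(i - 1) * W + (j - 1),
                   u = (size_t)(i - 1) * W + j, l = c - 1;
      const char bj_ = b[(size_t)j - 1];
      const double s =
          (ai == bj_ && is_acgt(ai)) ? match : mismatch;
      // M: diagonal move from best of three
      double vm = M[d], vx = X[d], vy = Y[d];
      double dm = vm;
      unsigned char pm = 0;
      if (vx > dm) { dm = vx; pm = 1; }
      if (vy > dm) { dm = vy; pm = 2; }
      double mval = (dm <= NEG_INF / 2) ? NEG_INF : dm + s;
      unsigned char mptr = pm;
      if (!global && mval <= 0) { mval = 0; mptr = 3; }
      M[c] = mval; pM[c] = mptr;
      // X: gap in b (consume a_i)
      double xo = M[u] + gap_open, xe = X[u] + gap_ext;
      if (xo >= xe) { X[c] = xo; pX[c] = 0; } else { X[c] = xe; pX[c] = 1; }
      // Y: gap in a (consume b_j)
      double yo = M[l] + gap_open, ye = Y[l] + gap_ext;
      if (yo >= ye) { Y[c] = yo; pY[c] = 0; } else { Y[c] = ye; pY[c] = 2; }
      if (mode == 0 && M[c] > best) { best = M[c]; bi = i; bj = j; bstate = 0; }
    }
  }

  if (global) {
    const size_t c = (size_t)n * W + m;
    best = M[c]; bstate = 0;
    if (X[c] > best) { best = X[c]; bstate = 1; }
    if (Y[c] > best) { best = Y[c]; bstate = 2; }
    bi = n; bj = m;
  } else if (mode == 2) {
    best = 0; bi = 0; bj = 0; bstate = 0;
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)n * W + j;
      if (M[c] > best) { best = M[c]; bi = n; bj = j; }
    }
  }

  AlnStats st;
  st.score = best;
  if (!global && best <= 0) return st;  // empty local alignment
  st.a_end = bi; st.b_end = bj;

  int i = bi, j = bj, state = bstate;
  while (true) {
    if (i == 0 && j == 0) break;
    if (state == 0 && (i == 0 || j == 0)) {
      if (global) { state = (j > 0) ? 2 : 1; } else { break; }
    }
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      const char ca = a[(size_t)i - 1], cb = b[(size_t)j - 1];
      st.columns++;
      if (ca == cb && is_acgt(ca)) {
        st.matches++;
      } else {
        st.mismatches++;
        if (is_acgt(ca) && is_acgt(cb)) {
          if (is_transition(ca, cb)) st.transitions++; else st.transversions++;
        }
      }
      st.a_start = i; st.b_start = j;
      const unsigned char p = pM[c];
      i--; j--;
      if (!global && p == 3) break;  // local alignment starts here
      state = p;
    } else if (state == 1) {  // gap in b, consumes a[i]
      st.columns++; st.gap_nt++;
      const unsigned char p = pX[c];
      if (p == 0) st.gap_events++;  // gap-open: run starts here
      st.a_start = i;
      i--;
      state = p;
    } else {  // state == 2: gap in a, consumes b[j]
      st.columns++; st.gap_nt++;
      const unsigned char p = pY[c];
      if (p == 0) st.gap_events++;
      st.b_start = j;
      j--;
      state = p;
    }
  }
  return st;
}

double gotoh_score(const std::string& a, const std::string& b, bool global,
                   double match, double mismatch, double gap_open,
                   double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> M(m + 1, NEG_INF), X(m + 1, NEG_INF), Y(m + 1, NEG_INF);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp.assign(m + 1, NEG_INF); Xp.assign(m + 1, NEG_INF); Yp.assign(m + 1, NEG_INF);
  Mp[0] = 0;
  for (int j = 1; j <= m; ++j) {
    if (global) Yp[j] = gap_open + gap_ext * (j - 1); else Mp[j] = 0;
  }
  double best = global ? NEG_INF : 0;
  for (int i = 1; i <= n; ++i) {
    M.assign(m + 1, NEG_INF); X.assign(m + 1, NEG_INF); Y.assign(m + 1, NEG_INF);
    if (global) X[0] = gap_open + gap_ext * (i - 1); else M[0] = 0;
    const char ai = a[(size_t)i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj_ = b[(size_t)j - 1];
      const double s = (ai == bj_ && is_acgt(ai)) ? match : mismatch;
      double dm = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      double mval = (dm <= NEG_INF / 2) ? NEG_INF : dm + s;
      if (!global && mval < 0) mval = 0;
      M[j] = mval;
      X[j] = std::max(Mp[j] + gap_open, Xp[j] + gap_ext);
      Y[j] = std::max(M[j - 1] + gap_open, Y[j - 1] + gap_ext);
      if (!global && M[j] > best) best = M[j];
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  if (global) best = std::max(Mp[m], std::max(Xp[m], Yp[m]));
  return best;
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
  return r;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".align_pairs_cpp")]]
DataFrame align_pairs_cpp(CharacterVector a, CharacterVector b,
                          int mode = 0, double match = 2,
                          double mismatch = -3, double gap_open = -5,
                          double gap_ext = -2) {
  const int n = a.size();
  if (b.size() != n) stop("a and b must have equal length");
  NumericVector score(n);
  IntegerVector matches(n), mismatches(n), transitions(n), transversions(n),
      gap_events(n), gap_nt(n), columns(n), a_start(n), a_end(n), b_start(n),
      b_end(n);
  for (int k = 0; k < n; ++k) {
    AlnStats st = gotoh_align(as<std::string>(a[k]), as<std::string>(b[k]),
                              mode, match, mismatch, gap_open, gap_ext);
    score[k] = st.score; matches[k] = st.matches; mismatches[k] = st.mismatches;
    transitions[k] = st.transitions; transversions[k] = st.transversions;
    gap_events[k] = st.gap_events; gap_nt[k] = st.gap_nt;
    columns[k] = st.columns;
    a_start[k] = st.a_start; a_end[k] = st.a_end;
    b_start[k] = st.b_start; b_end[k] = st.b_end;
  }
  return DataFrame::create(
      _["score"] = score, _["matches"] = matches, _["mismatches"] = mismatches,
      _["transitions"] = transitions, _["transversions"] = transversions,
      _["gap_events"] = gap_events, _["gap_nt"] = gap_nt,
      _["columns"] = columns, _["a_start"] = a_start, _["a_end"] = a_end,
      _["b_start"] = b_start, _["b_end"] = b_end);
}

//' @noRd
// [[Rcpp::export(name = ".rotational_identity_cpp")]]
List rotational_identity_cpp(std::string a, std::string b, double match = 2,
                             double mismatch = -3, double gap_open = -5,
                             double gap_ext = -2) {
  const int L = (int)a.size();
  if (L == 0 || b.empty()) stop("sequences must be non-empty");
  std::string arc = revcomp_str(a);
  double best = NEG_INF;
  int best_rot = 0, best_strand = 1;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& src = strand == 0 ? a : arc;
    std::string dbl = src + src;
    for (int r = 0; r < L; ++r) {
      std::string rot = dbl.substr(r, L);
      double sc = gotoh_score(rot, b, true, match, mismatch, gap_open, gap_ext);
      if (sc > best) { best = sc; best_rot = r; best_strand = strand; }
    }
  }
  const std::string& src = best_strand == 0 ? a : arc;
  std::string rot = (src + src).substr(best_rot, L);
  AlnStats st = gotoh_align(rot, b, 1, match, mismatch, gap_open, gap_ext);
  double identity =
      st.columns > 0 ? 100.0 * st.matches / st.columns : NA_REAL;
  return List::create(
      _["identity"] = identity, _["score"] = st.score,
      _["matches"] = st.matches, _["substitutions"] = st.mismatches,
      _["indel_events"] = st.gap_events, _["indel_nt"] = st.gap_nt,
      _["columns"] = st.columns, _["rotation"] = best_rot,
      _["strand"] = best_strand == 0 ? "+" : "-");
}
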