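#include <Rcpp.h>
#include <vector>
#include <string>
#include <cfloat>

using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3, anything else (incl. N) = -1.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::vector<int> encode(const std::string &seq) {
  std::vector<int> codes(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) codes[i] = base_code(seq[i]);
  return codes;
}

// Sliding-window k-mer tally over an encoded sequence.  Windows containing
// an invalid code (e.g. N) are skipped.  `counts` must be a zeroed array of
// length 4^k; indices that become non-zero are appended to `touched`.
static void count_kmers(const std::vector<int> &codes, int k,
                        std::vector<int> &counts, std::vector<int> &touched) {
  const int n = (int) codes.size();
  if (n < k) return;
  const unsigned mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  unsigned idx = 0;
  int run = 0;  // length of current valid run ending at position i
  for (int i = 0; i < n; ++i) {
    int c = codes[i];
    if (c < 0) { run = 0; idx = 0; continue; }
    idx = ((idx << 2) | (unsigned) c) & mask;
    if (++run >= k) {
      if (counts[idx] == 0) touched.push_back((int) idx);
      counts[idx]++;
    }
  }
}

// Fisher-Yates shuffle using R's RNG so set.seed() governs reproducibility.
static void fy_shuffle(std::vector<int> &v) {
  for (int i = (int) v.size() - 1; i > 0; --i) {
    int j = (int) (unif_rand() * (i + 1));
    if (j > i) j = i;  // guard against unif_rand() == 1.0 edge
    std::swap(v[i], v[j]);
  }
}

// For every k-mer observed in `seq` (m_obs > 0), count in how many of B
// mononucleotide shuffles the k-mer occurs m_obs times or more.
// [[Rcpp::export]]
List cpp_shuffle_tails(std::string seq, int k, int B) {
  std::vector<int> codes = encode(seq);
  const int n = (int) codes.size();
  if (k < 1 || k > 15) stop("k must be between 1 and 15");
  if (n < k) {
    return List::create(_["word_index"] = IntegerVector(0),
                        _["m_obs"] = IntegerVector(0),
                        _["tail"] = IntegerVector(0));
  }
  const size_t nwords = (size_t) 1 << (2 * k);
  std::vector<int> counts(nwords, 0), touched;
  count_kmers(codes, k, counts, touched);

  const int nobs = (int) touched.size();
  std::vector<int> m_obs(nobs), tails(nobs, 0);
  for (int t = 0; t < nobs; ++t) m_obs[t] = counts[touched[t]];

  RNGScope scope;
  std::vector<int> scounts(nwords, 0), stouched;
  std::vector<int> work = codes;
  for (int b = 0; b < B; ++b) {
    fy_shuffle(work);
    stouched.clear();
    count_kmers(work, k, scounts, stouched);
    for (int t = 0; t < nobs; ++t)
      if (scounts[touched[t]] >= m_obs[t]) tails[t]++;
    for (size_t t = 0; t < stouched.size(); ++t) scounts[stouched[t]] = 0;
  }

  IntegerVector wi(nobs), mo(nobs), tl(nobs);
  for (int t = 0; t < nobs; ++t) {
    wi[t] = touched[t];
    mo[t] = m_obs[t];
    tl[t] = tails[t];
  }
  return List::create(_["word_index"] = wi, _["m_obs"] = mo, _["tail"] = tl);
}

// Raw occurrence counts of every k-mer present in `seq` (overlapping).
// [[Rcpp::export]]
List cpp_kmer_counts(std::string seq, int k) {
  std::vector<int> codes = encode(seq);
  if (k < 1 || k > 15) stop("k must be between 1 and 15");
  const size_t nwords = (size_t) 1 << (2 * k);
  std::vector<int> counts(nwords, 0), touched;
  if ((int) codes.size() >= k) count_kmers(codes, k, counts, touched);
  const int nobs = (int) touched.size();
  IntegerVector wi(nobs), mo(nobs);
  for (int t = 0; t < nobs; ++t) {
    wi[t] = touched[t];
    mo[t] = counts[touched[t]];
  }
  return List::create(_["word_index"] = wi, _["count"] = mo);
}

// Max running sum of mean-centered scores, per word (column), for each
// supplied row ordering.  `scores` is n x W; `orders` is n x R with 1-based
// row indices.  Returns an R x W matrix of statistics.
// [[Rcpp::export]]
NumericMatrix cpp_max_running_sums(NumericMatrix scores, IntegerMatrix orders) {
  const int n = scores.nrow(), W = scores.ncol(), R = orders.ncol();
  if (orders.nrow() != n) stop("orders must have one row per sequence");
  std::vector<double> colmean(W);
  for (int j = 0; j < W; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += scores(i, j);
    colmean[j] = s / n;
  }
  NumericMatrix out(R, W);
  std::vector<int> ord(n);
  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) ord[i] = orders(i, r) - 1;
    for (int j = 0; j < W; ++j) {
      const double *col = &scores(0, j);
      const double mu = colmean[j];
      double s = 0, mx = -DBL_MAX;
      for (int i = 0; i < n; ++i) {
        s += col[ord[i]] - mu;
        if (s > mx) mx = s;
      }
      out(r, j) = mx > 0 ? mx : 0.0;  // S_n = 0 exactly, so max >= 0
    }
  }
  return out;
}

// Scan one sequence with a 4 x L weight matrix (rows A,C,G,T).  Windows
// containing invalid bases are skipped; hits with relative score >=
// `threshold` are returned in coordinate order.  Minus-strand windows are
// scored with the reverse-complemented matrix and reported on the input
// sequence's frame.
// [[Rcpp::export]]
DataFrame cpp_scan_pssm(std::string seq, NumericMatrix w, double threshold,
                        bool both_strands) {
  if (w.nrow() != 4) stop("weight matrix must have 4 rows (A,C,G,T)");
  const int L = w.ncol();
  std::vector<int> codes = encode(seq);
  const int n = (int) codes.size();

  double smin = 0, smax = 0;
  for (int j = 0; j < L; ++j) {
    double mn = w(0, j), mx = w(0, j);
    for (int b = 1; b < 4; ++b) {
      if (w(b, j) < mn) mn = w(b, j);
      if (w(b, j) > mx) mx = w(b, j);
    }
    smin += mn;
    smax += mx;
  }
  const double range = smax - smin;

  // reverse-complement matrix: wrc(b, j) = w(3 - b, L - 1 - j)
  NumericMatrix wrc(4, L);
  for (int j = 0; j < L; ++j)
    for (int b = 0; b < 4; ++b) wrc(b, j) = w(3 - b, L - 1 - j);

  std::vector<int> starts;
  std::vector<int> strands;  // 0 = '+', 1 = '-'
  std::vector<double> abs_scores, rel_scores;

  // valid[i] = 1 if window starting at i contains no invalid base
  for (int i = 0; i + L <= n; ++i) {
    bool ok = true;
    for (int j = 0; j < L; ++j)
      if (codes[i + j] < 0) { ok = false; break; }
    if (!ok) continue;
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      const NumericMatrix &m = strand == 0 ? w : wrc;
      double s = 0;
      for (int j = 0; j < L; ++j) s += m(codes[i + j], j);
      double rel = range > 0 ? (s - smin) / range : 1.0;
      if (rel >= threshold) {
        starts.push_back(i);
        strands.push_back(strand);
        abs_scores.push_back(s);
        rel_scores.push_back(rel);
      }
    }
  }

  const int h = (int) starts.size();
  IntegerVector st(h);
  CharacterVector sd(h);
  NumericVector ab(h), rl(h);
  for (int i = 0; i < h; ++i) {
    st[i] = starts[i];
    sd[i] = strands[i] == 0 ? "+" : "-";
    ab[i] = abs_scores[i];
    rl[i] = rel_scores[i];
  }
  return DataFrame::create(_["start"] = st, _["strand"] = sd,
                           _["abs_score"] = ab, _["rel_score"] = rl,
                           _["stringsAsFactors"] = false);
}

// Random DNA sequences with a fixed per-base composition, drawn with R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_random_dna(IntegerVector lens, NumericVector probs) {
  if (probs.size() != 4) stop("probs must have length 4 (A,C,G,T)");
  double cum[4];
  double tot = 0;
  for (int b = 0; b < 4; ++b) tot += probs[b];
  double acc = 0;
  for (int b = 0; b < 4; ++b) { acc += probs[b] / tot; cum[b] = acc; }
  static const char bases[] = "ACGT";
  RNGScope scope;
  const int n = lens.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const int len = lens[i];
    if (len < 0) stop("sequence length must be non-negative");
    buf.assign(len, 'A');
    for (int p = 0; p < len; ++p) {
      double u = unif_rand();
      int b = 0;
      while (b < 3 && u > cum[b]) ++b;
      buf[p] = bases[b];
    }
    out[i] = buf;
  }
  return out;
}
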