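#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Residue alphabet shared with the R side: 20 amino acids plus X.
static const char ALPHA[] = "ARNDCQEGHILKMFPSTWYVX";
static const int NALPHA = 21;

static void build_lookup(int *lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < NALPHA; ++i) lut[(unsigned char)ALPHA[i]] = i;
}

static std::vector<int> encode(const std::string &s, const int *lut,
                               const char *what) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = lut[(unsigned char)s[i]];
    if (c < 0)
      stop("unknown residue '%c' in %s (alphabet is the 20 amino acids plus X)",
           s[i], what);
    v[i] = c;
  }
  return v;
}

struct Aln {
  int score, qs, qe, ss, se, matches, cols;
};

struct SwBuffers {
  std::vector<int> Hrow, Erow, Fcol;
  std::vector<uint8_t> tb;
};

// Smith-Waterman local alignment with affine gaps (gap of length L costs
// gap_open + L * gap_extend). Packed traceback: bits 0-1 = H origin
// (0 stop, 1 diag, 2 E, 3 F); bit 2 = E opened from H; bit 3 = F opened
// from H. Interior traceback cells are always written before being read.
static Aln sw_core(const std::vector<int> &q, const std::vector<int> &s,
                   const int *submat, int gap_open, int gap_extend,
                   SwBuffers &buf) {
  const int n = (int)q.size(), m = (int)s.size();
  const int go = gap_open + gap_extend;
  const int ge = gap_extend;
  buf.Hrow.assign(m + 1, 0);
  buf.Erow.assign(m + 1, INT32_MIN / 2);
  buf.Fcol.assign(m + 1, INT32_MIN / 2);
  size_t need = (size_t)(n + 1) * (m + 1);
  if (buf.tb.size() < need) buf.tb.resize(need);
  int *Hrow = buf.Hrow.data();
  int *Erow = buf.Erow.data();
  int *Fcol = buf.Fcol.data();
  uint8_t *tb = buf.tb.data();

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = Hrow[0];
    const int *srow = &submat[q[i - 1] * NALPHA];
    size_t off = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      int e_open = Hrow[j - 1] - go;
      int e_ext = Erow[j - 1] - ge;
      int E = e_open >= e_ext ? e_open : e_ext;
      uint8_t t = e_open >= e_ext ? 4 : 0;
      int f_open = Hrow[j] - go;
      int f_ext = Fcol[j] - ge;
      int F = f_open >= f_ext ? f_open : f_ext;
      if (f_open >= f_ext) t |= 8;
      int diag = Hdiag + srow[s[j - 1]];
      int H = 0;
      if (diag > H) { H = diag; t |= 1; }
      if (E > H) { H = E; t = (t & 12) | 2; }
      if (F > H) { H = F; t = (t & 12) | 3; }
      tb[off + j] = t;
      Hdiag = Hrow[j];
      Hrow[j] = H;
      Erow[j] = E;
      Fcol[j] = F;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    Erow[0] = INT32_MIN / 2;
  }

  Aln a;
  a.score = best;
  a.qs = a.qe = a.ss = a.se = a.matches = a.cols = NA_INTEGER;
  if (best <= 0) return a;
  int i = bi, j = bj, st = 0, nmatch = 0, ncol = 0;
  while (true) {
    if (i == 0 || j == 0) break;
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (st == 0) {
      uint8_t o = t & 3;
      if (o == 0) break;
      if (o == 1) {
        ++ncol;
        if (q[i - 1] == s[j - 1]) ++nmatch;
        --i; --j;
      } else if (o == 2) {
        st = 1;
      } else {
        st = 2;
      }
    } else if (st == 1) {  // E: gap column consuming subject j
      ++ncol;
      --j;
      st = (t & 4) ? 0 : 1;
    } else {  // F: gap column consuming query i
      ++ncol;
      --i;
      st = (t & 8) ? 0 : 2;
    }
  }
  a.qs = i + 1; a.ss = j + 1;
  a.qe = bi; a.se = bj;
  a.matches = nmatch; a.cols = ncol;
  return a;
}

// One query against many subjects; raw score 0 => no positive-scoring
// local alignment, endpoints NA. Coordinates 1-based inclusive; identity
// is matches / align_cols with gap columns counted.
// [[Rcpp::export(name = ".sw_batch")]]
DataFrame sw_batch(std::string query, CharacterVector subjects,
                   IntegerMatrix submat, int gap_open, int gap_extend) {
  if (submat.nrow() != NALPHA || submat.ncol() != NALPHA)
    stop("substitution matrix must be %d x %d", NALPHA, NALPHA);
  int lut[256];
  build_lookup(lut);
  std::vector<int> q = encode(query, lut, "query");
  if (q.empty()) stop("empty query sequence");
  const int ns = subjects.size();
  IntegerVector score(ns), qs(ns), qe(ns), ss(ns), se(ns), matches(ns),
      cols(ns);
  SwBuffers buf;
  for (int k = 0; k < ns; ++k) {
    std::vector<int> s = encode(as<std::string>(subjects[k]), lut, "subject");
    if (s.empty()) stop("empty subject sequence");
    Aln a = sw_core(q, s, &submat[0], gap_open, gap_extend, buf);
    score[k] = a.score;
    qs[k] = a.qs; qe[k] = a.qe; ss[k] = a.ss; se[k] = a.se;
    matches[k] = a.matches; cols[k] = a.cols;
  }
  return DataFrame::create(
      _["raw_score"] = score, _["qstart"] = qs, _["qend"] = qe,
      _["sstart"] = ss, _["send"] = se, _["matches"] = matches,
      _["align_cols"] = cols, _["stringsAsFactors"] = false);
}

static std::vector<int> kmer_set(const std::vector<int> &s, int k) {
  std::vector<int> codes;
  int n = (int)s.size();
  if (n < k) return codes;
  codes.reserve(n - k + 1);
  for (int i = 0; i + k <= n; ++i) {
    int code = 0;
    for (int j = 0; j < k; ++j) code = code * NALPHA + s[i + j];
    codes.push_back(code);
  }
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  return codes;
}

// Unique k-mer codes per sequence, base-21 encoding over the shared alphabet.
// [[Rcpp::export(name = ".kmer_codes")]]
List kmer_codes(CharacterVector seqs, int k) {
  if (k < 1 || k > 6) stop("k must be in 1..6");
  int lut[256];
  build_lookup(lut);
  List out(seqs.size());
  for (int si = 0; si < seqs.size(); ++si) {
    std::vector<int> s = encode(as<std::string>(seqs[si]), lut, "sequence");
    std::vector<int> codes = kmer_set(s, k);
    out[si] = IntegerVector(codes.begin(), codes.end());
  }
  return out;
}

// Greedy incremental clustering core. Sequences must arrive already sorted
// (length-descending, ties by id). Each sequence joins the first existing
// cluster (creation order) whose representative satisfies identity >=
// min_id and both-way coverage >= min_cov, else founds a new cluster.
// Candidate clusters are prescreened by shared k-mers (>= min_words) and a
// contract-implied length bound: matches >= (min_id/100)(min_cov/100) *
// rep_len and matches <= member_len, so longer reps cannot qualify.
// [[Rcpp::export(name = ".greedy_cluster_core")]]
List greedy_cluster_core(CharacterVector seqs, IntegerMatrix submat,
                         int gap_open, int gap_extend, double min_id,
                         double min_cov, int k, int min_words) {
  int lut[256];
  build_lookup(lut);
  const int n = seqs.size();
  const double len_factor = (min_id / 100.0) * (min_cov / 100.0);

  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i)
    enc[i] = encode(as<std::string>(seqs[i]), lut, "sequence");

  std::unordered_map<int, std::vector<int> > index;  // kmer -> cluster ids
  std::vector<int> rep_of_cluster;                   // cluster id -> row
  IntegerVector cluster(n);
  NumericVector identity(n), cov_member(n), cov_rep(n);
  SwBuffers buf;
  std::vector<int> count_of;   // per-cluster shared-word counts
  std::vector<int> touched;

  for (int i = 0; i < n; ++i) {
    const std::vector<int> &s = enc[i];
    std::vector<int> codes = kmer_set(s, k);
    // shared-word counts over candidate clusters
    count_of.assign(rep_of_cluster.size(), 0);
    touched.clear();
    for (size_t c = 0; c < codes.size(); ++c) {
      std::unordered_map<int, std::vector<int> >::iterator it =
          index.find(codes[c]);
      if (it == index.end()) continue;
      const std::vector<int> &cl = it->second;
      for (size_t t = 0; t < cl.size(); ++t) {
        if (count_of[cl[t]] == 0) touched.push_back(cl[t]);
        ++count_of[cl[t]];
      }
    }
    std::sort(touched.begin(), touched.end());  // creation order
    int assigned = -1;
    const int mlen = (int)s.size();
    for (size_t t = 0; t < touched.size(); ++t) {
      int cl = touched[t];
      if (count_of[cl] < min_words) continue;
      int r = rep_of_cluster[cl];
      int rlen = (int)enc[r].size();
      if ((double)rlen * len_factor > (double)mlen) continue;
      Aln a = sw_core(s, enc[r], &submat[0], gap_open, gap_extend, buf);
      if (a.score <= 0) continue;
      double idy = 100.0 * a.matches / a.cols;
      double cm = 100.0 * (a.qe - a.qs + 1) / mlen;
      double cr = 100.0 * (a.se - a.ss + 1) / rlen;
      if (idy >= min_id && cm >= min_cov && cr >= min_cov) {
        assigned = cl;
        identity[i] = idy; cov_member[i] = cm; cov_rep[i] = cr;
        break;
      }
    }
    if (assigned < 0) {
      assigned = (int)rep_of_cluster.size();
      rep_of_cluster.push_back(i);
      identity[i] = 100.0; cov_member[i] = 100.0; cov_rep[i] = 100.0;
      for (size_t c = 0; c < codes.size(); ++c)
        index[codes[c]].push_back(assigned);
    }
    cluster[i] = assigned + 1;  // 1-based for R
  }

  IntegerVector rep_rows(rep_of_cluster.size());
  for (size_t c = 0; c < rep_of_cluster.size(); ++c)
    rep_rows[c] = rep_of_cluster[c] + 1;
  return List::create(_["cluster"] = cluster, _["identity"] = identity,
                      _["cov_member"] = cov_member, _["cov_rep"] = cov_rep,
                      _["rep_row"] = rep_rows);
}

// FNV-1a 64-bit content hash, hex-encoded; used for stable protein ids.
// [[Rcpp::export(name = ".fnv1a64")]]
CharacterVector fnv1a64(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    uint64_t h = 1469598103934665603ULL;
    for (size_t j = 0; j < s.size(); ++j) {
      h ^= (unsigned char)s[j];
      h *= 1099511628211ULL;
    }
    char buf[17];
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
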