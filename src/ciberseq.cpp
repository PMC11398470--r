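// Core compiled kernels: anchored Hamming scanning for read parsing,
// directional error-network collapse, and per-feature NB IRLS fits.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

const int NOT_FOUND = -1;

// Leftmost-best Hamming match of `pat` in `seq[from, to)`.
// Returns 0-based offset or NOT_FOUND if best distance > max_mm.
// 'N' never matches (counts as a mismatch).
int best_hamming_match(const std::string& seq, const std::string& pat,
                       int max_mm, int from, int to) {
  const int m = static_cast<int>(pat.size());
  const int last = std::min<int>(to, static_cast<int>(seq.size())) - m;
  int best_off = NOT_FOUND, best_mm = max_mm + 1;
  for (int off = from; off <= last; ++off) {
    int mm = 0;
    for (int k = 0; k < m; ++k) {
      if (seq[off + k] != pat[k]) {
        if (++mm >= best_mm) break;
      }
    }
    if (mm < best_mm) {  // strict: leftmost wins ties
      best_mm = mm;
      best_off = off;
      if (mm == 0) break;
    }
  }
  return (best_mm <= max_mm) ? best_off : NOT_FOUND;
}

char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

bool valid_alphabet(const std::string& s) {
  for (char c : s)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'N') return false;
  return true;
}

bool has_n(const std::string& s) {
  return s.find('N') != std::string::npos;
}

// One oriented parse attempt. Fills outputs and returns "" on success,
// otherwise the failure reason.
std::string try_parse(const std::string& seq,
                      const std::string& up_red, const std::string& dn_red,
                      const std::string& up_ir,  const std::string& dn_ir,
                      const std::string& g_up,   const std::string& g_dn,
                      int bc_len, int max_mm,
                      std::string& bc_red, std::string& bc_ir,
                      std::string& cassette) {
  const int n = static_cast<int>(seq.size());

  int o_ur = best_hamming_match(seq, up_red, max_mm, 0, n);
  if (o_ur == NOT_FOUND) return "anchor_missing";
  int bc_red_at = o_ur + static_cast<int>(up_red.size());
  int o_dr = best_hamming_match(seq, dn_red, max_mm, bc_red_at, n);
  if (o_dr == NOT_FOUND) return "anchor_missing";
  if (o_dr - bc_red_at != bc_len) return "length_mismatch";

  int after_red = o_dr + static_cast<int>(dn_red.size());
  int o_ui = best_hamming_match(seq, up_ir, max_mm, after_red, n);
  if (o_ui == NOT_FOUND) return "anchor_missing";
  int bc_ir_at = o_ui + static_cast<int>(up_ir.size());
  int o_di = best_hamming_match(seq, dn_ir, max_mm, bc_ir_at, n);
  if (o_di == NOT_FOUND) return "anchor_missing";
  if (o_di - bc_ir_at != bc_len) return "length_mismatch";

  int o_gu = best_hamming_match(seq, g_up, max_mm, 0, n);
  if (o_gu == NOT_FOUND) return "anchor_missing";
  int cass_at = o_gu + static_cast<int>(g_up.size());
  int o_gd = best_hamming_match(seq, g_dn, max_mm, cass_at, n);
  if (o_gd == NOT_FOUND) return "anchor_missing";
  if (o_gd <= cass_at) return "length_mismatch";

  bc_red = seq.substr(bc_red_at, bc_len);
  bc_ir = seq.substr(bc_ir_at, bc_len);
  cassette = seq.substr(cass_at, o_gd - cass_at);
  if (has_n(bc_red) || has_n(bc_ir) || has_n(cassette))
    return "ambiguous_base";
  return "";
}

}  // namespace

// [[Rcpp::export(name = ".cpp_parse_long_reads")]]
List cpp_parse_long_reads(CharacterVector seqs,
                          std::string up_red, std::string dn_red,
                          std::string up_ir, std::string dn_ir,
                          std::string g_up, std::string g_dn,
                          int bc_len, int max_mm) {
  const int n = seqs.size();
  CharacterVector bc_red(n, NA_STRING), bc_ir(n, NA_STRING),
      cassette(n, NA_STRING), orientation(n, NA_STRING), reason(n, NA_STRING);
  for (int i = 0; i < n; ++i) {
    std::string seq = as<std::string>(seqs[i]);
    if (!valid_alphabet(seq))
      stop("read %d contains characters outside {A,C,G,T,N}", i + 1);
    std::string br, bi, cs;
    std::string why = try_parse(seq, up_red, dn_red, up_ir, dn_ir, g_up, g_dn,
                                bc_len, max_mm, br, bi, cs);
    if (why.empty()) {
      bc_red[i] = br; bc_ir[i] = bi; cassette[i] = cs;
      orientation[i] = "forward";
      continue;
    }
    std::string rc = revcomp(seq);
    std::string why_rc = try_parse(rc, up_red, dn_red, up_ir, dn_ir, g_up,
                                   g_dn, bc_len, max_mm, br, bi, cs);
    if (why_rc.empty()) {
      bc_red[i] = br; bc_ir[i] = bi; cassette[i] = cs;
      orientation[i] = "reverse-complement";
    } else {
      reason[i] = why;  // report the forward-orientation failure
    }
  }
  return List::create(_["bc_red"] = bc_red, _["bc_ir"] = bc_ir,
                      _["cassette"] = cassette,
                      _["orientation"] = orientation, _["reason"] = reason);
}

// [[Rcpp::export(name = ".cpp_extract_tags")]]
List cpp_extract_tags(CharacterVector seqs, std::string anchor,
                      int bc_len, int umi_len, int max_mm,
                      bool anchor_then_barcode) {
  const int n = seqs.size();
  const int alen = static_cast<int>(anchor.size());
  CharacterVector barcode(n, NA_STRING), umi(n, NA_STRING),
      reason(n, NA_STRING);
  for (int i = 0; i < n; ++i) {
    std::string seq = as<std::string>(seqs[i]);
    if (!valid_alphabet(seq))
      stop("read %d contains characters outside {A,C,G,T,N}", i + 1);
    const int len = static_cast<int>(seq.size());
    if (len < umi_len + bc_len + alen) { reason[i] = "too_short"; continue; }
    std::string u = seq.substr(0, umi_len);
    int off = best_hamming_match(seq, anchor, max_mm, umi_len, len);
    if (off == NOT_FOUND) { reason[i] = "anchor_missing"; continue; }
    int bc_at;
    if (anchor_then_barcode) {
      bc_at = off + alen;
      if (bc_at + bc_len > len) { reason[i] = "too_short"; continue; }
    } else {
      bc_at = off - bc_len;
      if (bc_at < umi_len) { reason[i] = "too_short"; continue; }
    }
    std::string b = seq.substr(bc_at, bc_len);
    if (has_n(u) || has_n(b)) { reason[i] = "ambiguous_base"; continue; }
    barcode[i] = b;
    umi[i] = u;
  }
  return List::create(_["barcode"] = barcode, _["umi"] = umi,
                      _["reason"] = reason);
}

// Directional collapse. Nodes are processed in (count desc, sequence asc)
// order; each node is absorbed by the best already-processed neighbour a
// with Hamming(a, b) <= max_dist and count(a) >= 2*count(b) - 1 ("best" =
// highest count, then lexicographically smallest), inheriting a's root.
// Candidate neighbours come from exact-match buckets over max_dist + 1
// disjoint segments of the sequence (pigeonhole).
// [[Rcpp::export(name = ".cpp_directional_collapse")]]
IntegerVector cpp_directional_collapse(CharacterVector seqs,
                                       NumericVector counts, int max_dist) {
  const int n = seqs.size();
  IntegerVector canon(n);
  if (n == 0) return canon;
  std::vector<std::string> s(n);
  size_t slen = 0;
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    if (i == 0) slen = s[i].size();
    else if (s[i].size() != slen)
      stop("sequences must all have the same length");
  }
  if (max_dist == 0) {
    for (int i = 0; i < n; ++i) canon[i] = i + 1;
    return canon;
  }

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (counts[a] != counts[b]) return counts[a] > counts[b];
    return s[a] < s[b];
  });

  // segment boundaries for the pigeonhole buckets
  const int nseg = max_dist + 1;
  std::vector<int> seg_from(nseg), seg_len(nseg);
  {
    int base = static_cast<int>(slen) / nseg, rem = static_cast<int>(slen) % nseg, at = 0;
    for (int k = 0; k < nseg; ++k) {
      seg_len[k] = base + (k < rem ? 1 : 0);
      seg_from[k] = at;
      at += seg_len[k];
    }
  }
  std::vector<std::unordered_map<std::string, std::vector<int>>> buckets(nseg);

  std::vector<int> root(n, -1);
  auto hamming_le = [&](int a, int b, int d) {
    int mm = 0;
    for (size_t k = 0; k < slen; ++k)
      if (s[a][k] != s[b][k] && ++mm > d) return false;
    return true;
  };

  for (int oi = 0; oi < n; ++oi) {
    int b = ord[oi];
    int best = -1;
    for (int k = 0; k < nseg && seg_len[k] > 0; ++k) {
      auto it = buckets[k].find(s[b].substr(seg_from[k], seg_len[k]));
      if (it == buckets[k].end()) continue;
      for (int a : it->second) {
        if (a == b) continue;
        if (counts[a] < 2.0 * counts[b] - 1.0) continue;
        if (!hamming_le(a, b, max_dist)) continue;
        if (best == -1 || counts[a] > counts[best] ||
            (counts[a] == counts[best] && s[a] < s[best]))
          best = a;
      }
    }
    root[b] = (best == -1) ? b : root[best];
    for (int k = 0; k < nseg; ++k)
      if (seg_len[k] > 0)
        buckets[k][s[b].substr(seg_from[k], seg_len[k])].push_back(b);
  }
  for (int i = 0; i < n; ++i) canon[i] = root[i] + 1;
  return canon;
}

// [[Rcpp::export(name = ".cpp_hamming")]]
IntegerVector cpp_hamming(CharacterVector x, CharacterVector y) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  IntegerVector d(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(x[i]), b = as<std::string>(y[i]);
    if (a.size() != b.size()) stop("strings %d differ in length", i + 1);
    int mm = 0;
    for (size_t k = 0; k < a.size(); ++k)
      if (a[k] != b[k]) ++mm;
    d[i] = mm;
  }
  return d;
}

// Per-base substitution errors at rate `rate`, drawn from R's RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export(name = ".cpp_mutate_seqs")]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double rate) {
  RNGScope scope;
  const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t k = 0; k < s.size(); ++k) {
      if (unif_rand() < rate) {
        char c = s[k];
        char sub = c;
        while (sub == c) sub = bases[static_cast<int>(unif_rand() * 4) % 4];
        s[k] = sub;
      }
    }
    out[i] = s;
  }
  return out;
}

// Per-feature NB log-link IRLS with fixed dispersion and per-observation
// offsets. X is shared across features; returns the contrast estimate
// c'beta (natural log scale), its Wald SE, and a convergence flag.
// [[Rcpp::export(name = ".cpp_nb_irls")]]
List cpp_nb_irls(arma::mat Y, arma::mat X, arma::mat offset,
                 arma::vec alpha, arma::vec contrast,
                 int maxit, double tol) {
  const arma::uword nfeat = Y.n_rows, nobs = Y.n_cols, p = X.n_cols;
  if (offset.n_rows != nfeat || offset.n_cols != nobs)
    stop("offset must match the count matrix");
  if (alpha.n_elem != nfeat) stop("one dispersion per feature required");
  if (contrast.n_elem != p) stop("contrast length must equal ncol(X)");

  arma::vec est(nfeat), se(nfeat);
  est.fill(arma::datum::nan);
  se.fill(arma::datum::nan);
  LogicalVector converged(nfeat, false);

  for (arma::uword i = 0; i < nfeat; ++i) {
    arma::rowvec y = Y.row(i), o = offset.row(i);
    if (arma::max(y) <= 0) continue;  // all-zero feature: NA
    const double a = alpha[i];

    // init from log counts with pseudo-count
    arma::vec eta(nobs), beta(p, arma::fill::zeros);
    for (arma::uword j = 0; j < nobs; ++j)
      eta[j] = std::log(y[j] + 0.5);
    {
      arma::mat XtX = X.t() * X;
      arma::vec rhs = X.t() * (eta - o.t());
      beta = arma::solve(XtX, rhs, arma::solve_opts::fast);
    }

    bool ok = false;
    arma::mat info(p, p, arma::fill::zeros);
    for (int it = 0; it < maxit; ++it) {
      eta = X * beta + o.t();
      eta = arma::clamp(eta, -30.0, 30.0);
      arma::vec mu = arma::exp(eta);
      arma::vec w = mu / (1.0 + a * mu);
      arma::vec z = (eta - o.t()) + (y.t() - mu) / mu;
      arma::mat Xw = X.each_col() % w;
      info = X.t() * Xw;
      arma::vec beta_new;
      bool solved = arma::solve(beta_new, info, Xw.t() * z,
                                arma::solve_opts::no_approx);
      if (!solved) break;
      double delta = arma::abs(beta_new - beta).max();
      beta = beta_new;
      if (delta < tol) { ok = true; break; }
    }
    if (!ok) continue;

    arma::mat cov;
    if (!arma::inv_sympd(cov, info)) continue;
    est[i] = arma::dot(contrast, beta);
    double v = arma::as_scalar(contrast.t() * cov * contrast);
    if (v <= 0) continue;
    se[i] = std::sqrt(v);
    converged[i] = true;
  }
  return List::create(_["estimate"] = est, _["se"] = se,
                      _["converged"] = converged);
}
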