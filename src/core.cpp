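#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding; -1 for anything outside ACGT
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// Index of k-mer -> position (value -2 marks a k-mer seen more than once).
static void build_unique_index(const std::string& ref, int k,
                               std::unordered_map<uint64_t, int64_t>& idx) {
  const int64_t n = (int64_t)ref.size();
  if (n < k) return;
  idx.reserve((size_t)(n * 1.3));
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int64_t i = 0; i < n; ++i) {
    int c = base_code(ref[(size_t)i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    int64_t pos = i - k + 1;
    auto it = idx.find(kmer);
    if (it == idx.end()) idx.emplace(kmer, pos); else it->second = -2;
  }
}

// Maximal exact-match anchors between ref and qry, seeded at k-mers unique in
// the reference, both strands.  Coordinates 0-based; reverse anchors report
// the ascending span on the original query strand.
// [[Rcpp::export]]
DataFrame cpp_find_anchors(std::string ref, std::string qry, int k) {
  std::unordered_map<uint64_t, int64_t> idx;
  build_unique_index(ref, k, idx);
  std::vector<int64_t> r0, q0, len;
  std::vector<int> orient; // 0 forward, 1 reverse
  const int64_t qn = (int64_t)qry.size(), rn = (int64_t)ref.size();

  for (int strand = 0; strand < 2; ++strand) {
    std::string q = strand == 0 ? qry : revcomp(qry);
    std::unordered_map<int64_t, int64_t> diag_end; // diagonal -> q end already covered
    uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int64_t i = 0; i < qn; ++i) {
      int c = base_code(q[(size_t)i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      auto it = idx.find(kmer);
      if (it == idx.end() || it->second < 0) continue;
      int64_t qs = i - k + 1, rs = it->second, d = rs - qs;
      auto de = diag_end.find(d);
      if (de != diag_end.end() && qs < de->second) continue;
      // extend maximally (exact, ACGT only)
      int64_t l = 0;
      while (rs - l > 0 && qs - l > 0 &&
             base_code(ref[(size_t)(rs - l - 1)]) >= 0 &&
             ref[(size_t)(rs - l - 1)] == q[(size_t)(qs - l - 1)]) ++l;
      int64_t re = rs + k, qe = qs + k;
      while (re < rn && qe < qn && base_code(ref[(size_t)re]) >= 0 &&
             ref[(size_t)re] == q[(size_t)qe]) { ++re; ++qe; }
      int64_t L = re - (rs - l);
      diag_end[d] = qe;
      int64_t qstart = qs - l;
      if (strand == 1) qstart = qn - (qstart + L); // back to original strand
      r0.push_back(rs - l); q0.push_back(qstart);
      len.push_back(L); orient.push_back(strand);
    }
  }
  return DataFrame::create(_["ref_start"] = wrap(r0), _["qry_start"] = wrap(q0),
                           _["length"] = wrap(len), _["orientation"] = wrap(orient));
}

// Greedy chaining of anchors for one chromosome pair.  Anchors must be given
// with query coordinates already in oriented space (reverse anchors expressed
// on the reverse-complemented query), so that a chain is ascending in both
// coordinates.  Returns a chain id per anchor.
// [[Rcpp::export]]
IntegerVector cpp_chain_anchors(NumericVector ref_start, NumericVector qry_start,
                                NumericVector len, double max_gap, int k) {
  const int n = ref_start.size();
  IntegerVector chain(n);
  if (n == 0) return chain;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ref_start[a] != ref_start[b]) return ref_start[a] < ref_start[b];
    return len[a] > len[b];
  });
  struct Tail { double re, qe; int id; };
  std::vector<Tail> tails;
  int next_id = 0;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    double rs = ref_start[i], qs = qry_start[i];
    int best = -1; double best_cost = R_PosInf;
    for (size_t t = 0; t < tails.size(); ++t) {
      double rgap = rs - tails[t].re, qgap = qs - tails[t].qe;
      if (rgap > max_gap || qgap > max_gap) continue;
      if (rgap < -(double)(k - 1) || qgap < -(double)(k - 1)) continue;
      if (rs + len[i] <= tails[t].re || qs + len[i] <= tails[t].qe) continue;
      double cost = std::max(rgap, 0.0) + std::max(qgap, 0.0) +
        std::abs(rgap - qgap);
      if (cost < best_cost) { best_cost = cost; best = (int)t; }
    }
    if (best < 0) {
      tails.push_back({rs + len[i], qs + len[i], next_id});
      chain[i] = next_id++;
    } else {
      tails[best].re = rs + len[i];
      tails[best].qe = qs + len[i];
      chain[i] = tails[best].id;
    }
  }
  return chain;
}

// Needleman-Wunsch with traceback (match +1, mismatch -1, gap -2).
// Falls back to a crude pairing when the DP matrix would be too large.
static void nw_align(const std::string& a, const std::string& b,
                     std::string& out_a, std::string& out_b) {
  const int64_t n = (int64_t)a.size(), m = (int64_t)b.size();
  if (n == 0) { out_a.append(m, '-'); out_b.append(b); return; }
  if (m == 0) { out_a.append(a); out_b.append(n, '-'); return; }
  if ((n + 1) * (m + 1) > 16000000LL) {
    int64_t c = std::min(n, m);
    out_a.append(a.substr(0, (size_t)c)); out_b.append(b.substr(0, (size_t)c));
    if (n > c) { out_a.append(a.substr((size_t)c)); out_b.append((size_t)(n - c), '-'); }
    if (m > c) { out_a.append((size_t)(m - c), '-'); out_b.append(b.substr((size_t)c)); }
    return;
  }
  const int GAP = -2, MATCH = 1, MIS = -1;
  std::vector<int> prev((size_t)m + 1), cur((size_t)m + 1);
  std::vector<uint8_t> tb((size_t)((n + 1) * (m + 1))); // 0 diag, 1 up(gap in b), 2 left(gap in a)
  for (int64_t j = 0; j <= m; ++j) { prev[(size_t)j] = (int)(GAP * j); tb[(size_t)j] = 2; }
  tb[0] = 0;
  for (int64_t i = 1; i <= n; ++i) {
    cur[0] = (int)(GAP * i); tb[(size_t)(i * (m + 1))] = 1;
    char ai = a[(size_t)(i - 1)];
    for (int64_t j = 1; j <= m; ++j) {
      int sd = prev[(size_t)(j - 1)] + (ai == b[(size_t)(j - 1)] &&
                base_code(ai) >= 0 ? MATCH : MIS);
      int su = prev[(size_t)j] + GAP;
      int sl = cur[(size_t)(j - 1)] + GAP;
      int s = sd; uint8_t t = 0;
      if (su > s) { s = su; t = 1; }
      if (sl > s) { s = sl; t = 2; }
      cur[(size_t)j] = s; tb[(size_t)(i * (m + 1) + j)] = t;
    }
    std::swap(prev, cur);
  }
  std::string ra, rb;
  int64_t i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)(i * (m + 1) + j)];
    if (i > 0 && j > 0 && t == 0) {
      ra.push_back(a[(size_t)(i - 1)]); rb.push_back(b[(size_t)(j - 1)]); --i; --j;
    } else if (i > 0 && (t == 1 || j == 0)) {
      ra.push_back(a[(size_t)(i - 1)]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[(size_t)(j - 1)]); --j;
    }
  }
  out_a.append(ra.rbegin(), ra.rend());
  out_b.append(rb.rbegin(), rb.rend());
}

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b) {
  std::string oa, ob;
  nw_align(a, b, oa, ob);
  return List::create(_["a"] = oa, _["b"] = ob);
}

// Build the base-level alignment of one chain.  `q` must already be the
// oriented query sequence (reverse-complemented for reverse chains) and the
// anchor coordinates expressed on it.  Returns gapped strings plus stats.
// [[Rcpp::export]]
List cpp_chain_alignment(std::string ref, std::string q,
                         NumericVector ref_start, NumericVector qry_start,
                         NumericVector len) {
  const int n = ref_start.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return ref_start[a] < ref_start[b];
  });
  std::string ra, qa;
  int64_t cur_r = (int64_t)ref_start[ord[0]];
  int64_t cur_q = (int64_t)qry_start[ord[0]];
  const int64_t block_r0 = cur_r, block_q0 = cur_q;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    int64_t rs = (int64_t)ref_start[i], qs = (int64_t)qry_start[i];
    int64_t L = (int64_t)len[i];
    // trim overlap with what is already emitted
    if (rs < cur_r) { int64_t s = cur_r - rs; rs += s; qs += s; L -= s; }
    if (qs < cur_q) { int64_t s = cur_q - qs; rs += s; qs += s; L -= s; }
    if (L <= 0) continue;
    if (rs > cur_r || qs > cur_q) {
      nw_align(ref.substr((size_t)cur_r, (size_t)(rs - cur_r)),
               q.substr((size_t)cur_q, (size_t)(qs - cur_q)), ra, qa);
    }
    ra.append(ref.substr((size_t)rs, (size_t)L));
    qa.append(q.substr((size_t)qs, (size_t)L));
    cur_r = rs + L; cur_q = qs + L;
  }
  int64_t matches = 0;
  for (size_t i = 0; i < ra.size(); ++i)
    if (ra[i] == qa[i] && ra[i] != '-' && base_code(ra[i]) >= 0) ++matches;
  return List::create(
    _["ref_aln"] = ra, _["qry_aln"] = qa,
    _["ref_start"] = (double)block_r0, _["ref_end"] = (double)cur_r,
    _["qry_start"] = (double)block_q0, _["qry_end"] = (double)cur_q,
    _["matches"] = (double)matches, _["columns"] = (double)ra.size());
}

// Walk alignment columns and emit variants relative to the reference strand.
// ref_pos for an indel is the 0-based reference coordinate of the column
// after the event (insertions) or of its first deleted base (deletions).
// [[Rcpp::export]]
DataFrame cpp_alignment_variants(std::string ref_aln, std::string qry_aln,
                                 double ref_start) {
  std::vector<std::string> kind, ref_allele, alt_allele;
  std::vector<double> pos;
  std::vector<double> edge_l; // distance from block start in ref columns
  int64_t rpos = (int64_t)ref_start;
  const size_t n = ref_aln.size();
  size_t i = 0;
  while (i < n) {
    char rc = ref_aln[i], qc = qry_aln[i];
    if (rc != '-' && qc != '-') {
      if (rc != qc && base_code(rc) >= 0 && base_code(qc) >= 0) {
        kind.push_back("snp"); pos.push_back((double)rpos);
        ref_allele.push_back(std::string(1, rc));
        alt_allele.push_back(std::string(1, qc));
        edge_l.push_back((double)i);
      }
      ++rpos; ++i;
    } else if (rc == '-') { // insertion in query
      std::string ins;
      size_t j = i;
      while (j < n && ref_aln[j] == '-') { ins.push_back(qry_aln[j]); ++j; }
      kind.push_back("insertion"); pos.push_back((double)rpos);
      ref_allele.push_back(""); alt_allele.push_back(ins);
      edge_l.push_back((double)i);
      i = j;
    } else { // deletion from reference
      std::string del;
      size_t j = i;
      while (j < n && qry_aln[j] == '-' && ref_aln[j] != '-') { del.push_back(ref_aln[j]); ++j; }
      kind.push_back("deletion"); pos.push_back((double)rpos);
      ref_allele.push_back(del); alt_allele.push_back("");
      edge_l.push_back((double)i);
      rpos += (int64_t)del.size();
      i = j;
    }
  }
  return DataFrame::create(_["kind"] = wrap(kind), _["ref_pos"] = wrap(pos),
                           _["ref_allele"] = wrap(ref_allele),
                           _["alt_allele"] = wrap(alt_allele),
                           _["column"] = wrap(edge_l),
                           _["stringsAsFactors"] = false);
}

// Maximal exact matches of at least min_len bases between query and target
// (either strand), reported as query-coordinate segments.  Seeded at k-mers
// (k <= 31), occurrences per k-mer capped at max_occ.
// [[Rcpp::export]]
DataFrame cpp_exact_segments(std::string target, std::string query,
                             int k, int min_len, int max_occ) {
  std::vector<double> out_qs, out_qe, out_ts;
  std::vector<int> out_strand;
  const int64_t tn = (int64_t)target.size(), qn = (int64_t)query.size();
  if (tn < k || qn < k)
    return DataFrame::create(_["qry_start"] = wrap(out_qs),
                             _["qry_end"] = wrap(out_qe),
                             _["tgt_start"] = wrap(out_ts),
                             _["strand"] = wrap(out_strand));
  std::unordered_map<uint64_t, std::vector<int32_t>> idx;
  idx.reserve((size_t)(tn * 1.3));
  uint64_t kmer = 0, mask = (1ULL << (2 * k)) - 1;
  int run = 0;
  for (int64_t i = 0; i < tn; ++i) {
    int c = base_code(target[(size_t)i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    auto& v = idx[kmer];
    if ((int)v.size() < max_occ) v.push_back((int32_t)(i - k + 1));
  }
  for (int strand = 0; strand < 2; ++strand) {
    std::string q = strand == 0 ? query : revcomp(query);
    std::unordered_map<int64_t, int64_t> diag_end;
    kmer = 0; run = 0;
    for (int64_t i = 0; i < qn; ++i) {
      int c = base_code(q[(size_t)i]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      auto it = idx.find(kmer);
      if (it == idx.end()) continue;
      int64_t qs = i - k + 1;
      for (int32_t rs0 : it->second) {
        int64_t rs = rs0, d = rs - qs;
        auto de = diag_end.find(d);
        if (de != diag_end.end() && qs < de->second) continue;
        int64_t l = 0;
        while (rs - l > 0 && qs - l > 0 &&
               base_code(target[(size_t)(rs - l - 1)]) >= 0 &&
               target[(size_t)(rs - l - 1)] == q[(size_t)(qs - l - 1)]) ++l;
        int64_t re = rs + k, qe = qs + k;
        while (re < tn && qe < qn && base_code(target[(size_t)re]) >= 0 &&
               target[(size_t)re] == q[(size_t)qe]) { ++re; ++qe; }
        diag_end[d] = qe;
        int64_t L = qe - (qs - l);
        if (L < min_len) continue;
        int64_t a = qs - l, b = qe;
        if (strand == 1) { int64_t a2 = qn - b; b = qn - a; a = a2; }
        out_qs.push_back((double)a); out_qe.push_back((double)b);
        out_ts.push_back((double)(rs - l)); out_strand.push_back(strand);
      }
    }
  }
  return DataFrame::create(_["qry_start"] = wrap(out_qs),
                           _["qry_end"] = wrap(out_qe),
                           _["tgt_start"] = wrap(out_ts),
                           _["strand"] = wrap(out_strand));
}
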