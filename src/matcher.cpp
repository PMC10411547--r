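// Ungapped seed-and-extend matching of marker/primer sequences against a
// genome. Substitution-only alignment: a hit is one diagonal (offset), scored
// by match count over the clipped query span. Indels are out of scope for the
// built-in backend (divergence model is substitutions only); an external
// gapped aligner can be plugged in upstream.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp_codes(const std::vector<int> &v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c < 0) ? -1 : 3 - c;
  }
  return r;
}

// k-mer index over one encoded sequence: bucket of start positions per code.
// Windows containing non-ACGT bases are not indexed.
struct KmerIndex {
  int k;
  std::vector<int32_t> starts;    // size 4^k + 1 (CSR offsets)
  std::vector<int32_t> pos;       // positions, bucketed by code
  void build(const std::vector<int> &seq, int k_) {
    k = k_;
    size_t nb = (size_t)1 << (2 * k);
    starts.assign(nb + 1, 0);
    if ((int)seq.size() < k) { pos.clear(); return; }
    size_t n = seq.size() - k + 1;
    std::vector<int64_t> codes(n, -1);
    int64_t code = 0, mask = ((int64_t)1 << (2 * k)) - 1;
    int bad = 0;  // bases in current window that are non-ACGT
    for (size_t i = 0; i < seq.size(); ++i) {
      int c = seq[i];
      code = ((code << 2) | (c < 0 ? 0 : c)) & mask;
      if (c < 0) bad = k;            // poisons the next k windows
      else if (bad > 0) --bad;
      if (i + 1 >= (size_t)k && bad == 0) codes[i + 1 - k] = code;
    }
    for (size_t i = 0; i < n; ++i)
      if (codes[i] >= 0) ++starts[codes[i] + 1];
    for (size_t b = 0; b < nb; ++b) starts[b + 1] += starts[b];
    pos.assign(starts[nb], 0);
    std::vector<int32_t> fill(starts.begin(), starts.end() - 1);
    for (size_t i = 0; i < n; ++i)
      if (codes[i] >= 0) pos[fill[codes[i]]++] = (int32_t)i;
  }
};

// One diagonal evaluation: query placed at subject offset `off`, clipped to
// the subject; returns matches and aligned length.
static inline void eval_offset(const std::vector<int> &q,
                               const std::vector<int> &s, long off,
                               int &matches, int &aln_len) {
  long qs = off < 0 ? -off : 0;
  long qe = std::min<long>((long)q.size(), (long)s.size() - off);
  matches = 0;
  aln_len = (int)std::max<long>(0, qe - qs);
  for (long i = qs; i < qe; ++i)
    if (q[i] >= 0 && q[i] == s[off + i]) ++matches;
}

// [[Rcpp::export]]
DataFrame cpp_seed_hits(CharacterVector queries, CharacterVector chrom_seqs,
                        int k, int step, double min_identity,
                        int min_aln_len, int max_bucket) {
  int nq = queries.size(), nc = chrom_seqs.size();
  std::vector<int> out_q, out_c, out_matches, out_len;
  std::vector<long> out_start, out_end;
  std::vector<std::string> out_strand;

  std::vector<std::vector<int>> qf(nq), qr(nq);
  for (int i = 0; i < nq; ++i) {
    qf[i] = encode(std::string(queries[i]));
    qr[i] = revcomp_codes(qf[i]);
  }

  KmerIndex idx;
  for (int ci = 0; ci < nc; ++ci) {
    std::vector<int> sub = encode(std::string(chrom_seqs[ci]));
    idx.build(sub, k);
    for (int qi = 0; qi < nq; ++qi) {
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<int> &q = strand == 0 ? qf[qi] : qr[qi];
        int qlen = (int)q.size();
        if (qlen < k) continue;
        // seed positions: every `step` bases plus the terminal window
        std::vector<int> seeds;
        for (int p = 0; p + k <= qlen; p += step) seeds.push_back(p);
        if (seeds.empty() || seeds.back() != qlen - k)
          seeds.push_back(qlen - k);
        std::unordered_set<long> offsets;
        int64_t mask = ((int64_t)1 << (2 * k)) - 1;
        for (int p : seeds) {
          int64_t code = 0; bool ok = true;
          for (int j = 0; j < k; ++j) {
            if (q[p + j] < 0) { ok = false; break; }
            code = ((code << 2) | q[p + j]) & mask;
          }
          if (!ok) continue;
          int32_t b0 = idx.starts[code], b1 = idx.starts[code + 1];
          if (b1 - b0 > max_bucket) continue;  // over-represented repeat seed
          for (int32_t b = b0; b < b1; ++b)
            offsets.insert((long)idx.pos[b] - p);
        }
        std::vector<long> offs(offsets.begin(), offsets.end());
        std::sort(offs.begin(), offs.end());
        for (long off : offs) {
          int matches, aln_len;
          eval_offset(q, sub, off, matches, aln_len);
          if (aln_len < min_aln_len) continue;
          double ident = 100.0 * matches / aln_len;
          if (!(ident > min_identity)) continue;
          long s0 = std::max<long>(0, off);
          long s1 = std::min<long>((long)sub.size(), off + qlen);
          out_q.push_back(qi + 1);
          out_c.push_back(ci + 1);
          out_start.push_back(s0);
          out_end.push_back(s1);
          out_strand.push_back(strand == 0 ? "+" : "-");
          out_matches.push_back(matches);
          out_len.push_back(aln_len);
        }
      }
    }
  }
  return DataFrame::create(
      _["query"] = out_q, _["chrom_idx"] = out_c,
      _["start"] = NumericVector(out_start.begin(), out_start.end()),
      _["end"] = NumericVector(out_end.begin(), out_end.end()),
      _["strand"] = out_strand, _["matches"] = out_matches,
      _["aln_len"] = out_len, _["stringsAsFactors"] = false);
}

// Primer-site scan with an exact 3'-terminal seed. For a plus-strand site
// the seed is the primer's last `seed_len` bases; for a minus-strand site the
// reverse complement's first `seed_len` bases (genome coordinates). Non-seed
// positions may mismatch up to max_mm.
// [[Rcpp::export]]
DataFrame cpp_primer_sites(CharacterVector primers, CharacterVector chrom_seqs,
                           int seed_len, IntegerVector max_mm) {
  int np = primers.size(), nc = chrom_seqs.size();
  std::vector<int> out_p, out_c, out_mm;
  std::vector<long> out_start;
  std::vector<std::string> out_strand;

  std::vector<std::vector<int>> pf(np), pr(np);
  for (int i = 0; i < np; ++i) {
    pf[i] = encode(std::string(primers[i]));
    pr[i] = revcomp_codes(pf[i]);
  }

  KmerIndex idx;
  for (int ci = 0; ci < nc; ++ci) {
    std::vector<int> sub = encode(std::string(chrom_seqs[ci]));
    idx.build(sub, seed_len);
    int64_t mask = ((int64_t)1 << (2 * seed_len)) - 1;
    for (int pi = 0; pi < np; ++pi) {
      int plen = (int)pf[pi].size();
      if (plen < seed_len) continue;
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<int> &p = strand == 0 ? pf[pi] : pr[pi];
        // seed window within the (possibly reverse-complemented) primer
        int sp = strand == 0 ? plen - seed_len : 0;
        int64_t code = 0; bool ok = true;
        for (int j = 0; j < seed_len; ++j) {
          if (p[sp + j] < 0) { ok = false; break; }
          code = ((code << 2) | p[sp + j]) & mask;
        }
        if (!ok) continue;
        for (int32_t b = idx.starts[code]; b < idx.starts[code + 1]; ++b) {
          long site = (long)idx.pos[b] - sp;
          if (site < 0 || site + plen > (long)sub.size()) continue;
          int mm = 0;
          for (int j = 0; j < plen; ++j)
            if (p[j] < 0 || p[j] != sub[site + j]) ++mm;
          if (mm > max_mm[pi]) continue;
          out_p.push_back(pi + 1);
          out_c.push_back(ci + 1);
          out_start.push_back(site);
          out_strand.push_back(strand == 0 ? "+" : "-");
          out_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(
      _["primer"] = out_p, _["chrom_idx"] = out_c,
      _["start"] = NumericVector(out_start.begin(), out_start.end()),
      _["strand"] = out_strand, _["mismatches"] = out_mm,
      _["stringsAsFactors"] = false);
}
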