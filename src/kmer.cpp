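#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit base codes; -1 for anything outside upper-case ACGT
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'T': return 'A';
  case 'C': return 'G'; case 'G': return 'C';
  case 'a': return 't'; case 't': return 'a';
  case 'c': return 'g'; case 'g': return 'c';
  // IUPAC ambiguity codes
  case 'R': return 'Y'; case 'Y': return 'R';
  case 'S': return 'S'; case 'W': return 'W';
  case 'K': return 'M'; case 'M': return 'K';
  case 'B': return 'V'; case 'V': return 'B';
  case 'D': return 'H'; case 'H': return 'D';
  case 'N': return 'N';
  }
  return 'N';
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_char(out[i]);
  return out;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerMap;

// index canonical k-mer code -> 1-based forward start positions in the construct
static void build_index(const std::string& construct, int k, KmerMap& idx) {
  const int L = (int) construct.size();
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t f = 0, r = 0;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int c = base_code(construct[i]);
    if (c < 0) { run = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (uint64_t) c) & mask;
    r = (r >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      uint64_t canon = f < r ? f : r;
      idx[canon].push_back(i - k + 2);
    }
  }
}

// Count, for every k-mer occurrence in every read (canonical orientation),
// the construct start positions it maps to.
// [[Rcpp::export]]
List cpp_count_kmers(std::string construct, int k, CharacterVector reads) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  const int L = (int) construct.size();
  if (L < k) stop("construct shorter than k");
  KmerMap idx;
  build_index(construct, k, idx);

  const int npos = L - k + 1;
  IntegerVector counts(npos);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  double total = 0.0, matched = 0.0, possible = 0.0;
  int short_reads = 0;

  for (R_xlen_t j = 0; j < reads.size(); ++j) {
    SEXP el = STRING_ELT(reads, j);
    const char* s = CHAR(el);
    const int n = (int) LENGTH(el);
    if (n < k) { ++short_reads; continue; }
    possible += (double)(n - k + 1);
    uint64_t f = 0, r = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; continue; }
      f = ((f << 2) | (uint64_t) c) & mask;
      r = (r >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        total += 1.0;
        uint64_t canon = f < r ? f : r;
        KmerMap::const_iterator it = idx.find(canon);
        if (it != idx.end()) {
          matched += 1.0;
          const std::vector<int>& pos = it->second;
          for (size_t u = 0; u < pos.size(); ++u) counts[pos[u] - 1]++;
        }
      }
    }
  }

  return List::create(
    _["counts"] = counts,
    _["total_read_kmers"] = total,
    _["matched_kmers"] = matched,
    _["skipped_kmers"] = possible - total,
    _["short_reads"] = short_reads);
}

// ---------------------------------------------------------------------------
// off-target scanning: exhaustive Hamming scan with IUPAC-aware PAM matching
// ---------------------------------------------------------------------------

// 4-bit IUPAC set membership (A=1, C=2, G=4, T=8)
static inline int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
  case 'R': return 5; case 'Y': return 10; case 'S': return 6; case 'W': return 9;
  case 'K': return 12; case 'M': return 3;
  case 'B': return 14; case 'D': return 13; case 'H': return 11; case 'V': return 7;
  case 'N': return 15;
  }
  return 0;
}

// guide base (unambiguous) vs genome base: a match when the guide base is a
// member of the genome code's set
static inline bool guide_matches(char guide, char genome) {
  return (iupac_mask(guide) & iupac_mask(genome)) != 0;
}

struct Hit {
  int seq;      // index into seqs
  int start;    // 1-based plus-strand coordinate of protospacer 5'-most base
  char strand;
  int mm;
  std::string site;
};

static void scan_one_strand(const std::string& g, int seq_idx, char strand,
                            const std::string& proto, const std::string& pam,
                            int max_mm, std::vector<Hit>& hits) {
  const int P = (int) proto.size(), M = (int) pam.size();
  const int W = P + M;
  const int L = (int) g.size();
  // pattern on this strand: for '+' scan proto+pam directly; for '-' the caller
  // passes the plus-strand sequence and we scan revcomp(pam)+revcomp(proto)
  if (strand == '+') {
    for (int i = 0; i + W <= L; ++i) {
      int mm = 0;
      for (int p = 0; p < P && mm <= max_mm; ++p)
        if (!guide_matches(proto[p], g[i + p])) ++mm;
      if (mm > max_mm) continue;
      bool pam_ok = true;
      for (int p = 0; p < M; ++p)
        if ((iupac_mask(pam[p]) & iupac_mask(g[i + P + p])) == 0) { pam_ok = false; break; }
      if (!pam_ok) continue;
      Hit h; h.seq = seq_idx; h.start = i + 1; h.strand = '+'; h.mm = mm;
      h.site = g.substr(i, W);
      hits.push_back(h);
    }
  } else {
    std::string rproto = proto, rpam = pam;
    { std::string t(proto.rbegin(), proto.rend());
      for (size_t q = 0; q < t.size(); ++q) t[q] = comp_char(t[q]); rproto = t; }
    { std::string t(pam.rbegin(), pam.rend());
      for (size_t q = 0; q < t.size(); ++q) t[q] = comp_char(t[q]); rpam = t; }
    // minus-strand site occupies plus coords [i, i+W): first M bases are the
    // reverse-complemented PAM, the remaining P the reverse-complemented spacer
    for (int i = 0; i + W <= L; ++i) {
      bool pam_ok = true;
      for (int p = 0; p < M; ++p)
        if ((iupac_mask(rpam[p]) & iupac_mask(g[i + p])) == 0) { pam_ok = false; break; }
      if (!pam_ok) continue;
      int mm = 0;
      for (int p = 0; p < P && mm <= max_mm; ++p)
        if (!guide_matches(rproto[p], g[i + M + p])) ++mm;
      if (mm > max_mm) continue;
      Hit h; h.seq = seq_idx; h.start = i + M + 1; h.strand = '-'; h.mm = mm;
      std::string win = g.substr(i, W);
      std::string rc(win.rbegin(), win.rend());
      for (size_t q = 0; q < rc.size(); ++q) rc[q] = comp_char(rc[q]);
      h.site = rc;
      hits.push_back(h);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_scan_offtargets(CharacterVector seqs, CharacterVector ids,
                              std::string protospacer, std::string pam,
                              int max_mm) {
  std::vector<Hit> hits;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    std::string g = as<std::string>(seqs[j]);
    if ((int) g.size() < (int)(protospacer.size() + pam.size())) continue;
    scan_one_strand(g, (int) j, '+', protospacer, pam, max_mm, hits);
    scan_one_strand(g, (int) j, '-', protospacer, pam, max_mm, hits);
  }
  const int n = (int) hits.size();
  CharacterVector seq_id(n), strand(n), site(n);
  IntegerVector start(n), end(n), mm(n);
  LogicalVector on_target(n);
  for (int i = 0; i < n; ++i) {
    seq_id[i] = ids[hits[i].seq];
    start[i] = hits[i].start;
    end[i] = hits[i].start + (int) protospacer.size() - 1;
    strand[i] = std::string(1, hits[i].strand);
    mm[i] = hits[i].mm;
    site[i] = hits[i].site;
    on_target[i] = (hits[i].mm == 0);
  }
  return DataFrame::create(
    _["seq_id"] = seq_id, _["start"] = start, _["end"] = end,
    _["strand"] = strand, _["mismatches"] = mm,
    _["site_sequence"] = site, _["on_target"] = on_target,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// synthetic-data helpers (use R's RNG so set.seed() governs everything)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_random_dna(int n, double gc) {
  std::string out(n, 'A');
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    if (u < gc) out[i] = (unif_rand() < 0.5) ? 'G' : 'C';
    else        out[i] = (unif_rand() < 0.5) ? 'A' : 'T';
  }
  return out;
}

// n_templates sequencing templates; each emits either one read (paired = false)
// or an R1/R2 mate pair in FR orientation (paired = true, interleaved output)
// [[Rcpp::export]]
CharacterVector cpp_simulate_reads(std::string genome, int n_templates,
                                   int read_len, double error_rate, bool paired) {
  const int L = (int) genome.size();
  const int span = paired ? 2 * read_len : read_len;
  if (L < span) stop("genome shorter than the template span");
  CharacterVector out(paired ? 2 * n_templates : n_templates);
  for (int t = 0; t < n_templates; ++t) {
    int s = (int) std::floor(unif_rand() * (double)(L - span + 1));
    if (s > L - span) s = L - span;
    std::string frag = genome.substr((size_t) s, (size_t) span);
    if (unif_rand() < 0.5) {  // template drawn from the minus strand
      std::string rc(frag.rbegin(), frag.rend());
      for (size_t q = 0; q < rc.size(); ++q) rc[q] = comp_char(rc[q]);
      frag = rc;
    }
    if (error_rate > 0) {
      for (int i = 0; i < span; ++i) {
        if (unif_rand() < error_rate) {
          int c = base_code(frag[i]);
          if (c >= 0) {
            int alt = (int) std::floor(unif_rand() * 3.0);
            if (alt > 2) alt = 2;
            frag[i] = BASES[(c + 1 + alt) & 3];
          }
        }
      }
    }
    if (paired) {
      out[2 * t] = frag.substr(0, read_len);
      std::string r2 = frag.substr(read_len, read_len);
      std::string rc(r2.rbegin(), r2.rend());
      for (size_t q = 0; q < rc.size(); ++q) rc[q] = comp_char(rc[q]);
      out[2 * t + 1] = rc;
    } else {
      out[t] = frag;
    }
  }
  return out;
}
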