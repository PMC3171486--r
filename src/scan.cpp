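#include <Rcpp.h>
using namespace Rcpp;

// 4-bit nucleotide-set masks. Subject letters map A,C,G,T -> 1,2,4,8 and
// anything else (including N) -> 0, so an ambiguous subject base never
// satisfies a specified pattern position. Pattern letters use full IUPAC
// sets; pattern N (mask 15) positions are skipped as non-informative.
static inline int subject_mask(char c) {
  switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': return 8;
    default:  return 0;
  }
}

static inline int pattern_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'M': return 3;  case 'R': return 5;  case 'W': return 9;  case 'S': return 6;
    case 'Y': return 10; case 'K': return 12; case 'V': return 7;  case 'H': return 11;
    case 'D': return 13; case 'B': return 14; case 'N': return 15;
    default:  return -1;
  }
}

struct CompiledPattern {
  std::vector<int> pos;   // informative positions (0-based)
  std::vector<int> mask;  // their IUPAC masks
  int span;
};

static CompiledPattern compile_pattern(const std::string& pat) {
  CompiledPattern cp;
  cp.span = (int) pat.size();
  for (int j = 0; j < cp.span; ++j) {
    int m = pattern_mask(pat[j]);
    if (m < 0) stop("invalid IUPAC character '%s' in pattern", std::string(1, pat[j]));
    if (m != 15) { cp.pos.push_back(j); cp.mask.push_back(m); }
  }
  return cp;
}

static void scan_one(const char* s, int n, const CompiledPattern& cp,
                     int max_mismatch, int seq_index, bool minus,
                     std::vector<int>& out_seq, std::vector<int>& out_off,
                     std::vector<int>& out_strand, std::vector<int>& out_mm) {
  const int span = cp.span;
  const int k = (int) cp.pos.size();
  for (int i = 0; i + span <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < k; ++j) {
      if (!(subject_mask(s[i + cp.pos[j]]) & cp.mask[j])) {
        if (++mm > max_mismatch) break;
      }
    }
    if (mm <= max_mismatch) {
      out_seq.push_back(seq_index);
      out_off.push_back(i);
      out_strand.push_back(minus ? 1 : 0);
      out_mm.push_back(mm);
    }
  }
}

// Scan all sequences for matches of an IUPAC pattern with at most
// `max_mismatch` mismatches at informative (non-N) positions. When
// `both_strands` is true the reverse-complement pattern is also scanned
// (reported with strand code 1); the caller is responsible for turning that
// off for self-reverse-complementary patterns.
// [[Rcpp::export]]
DataFrame scan_iupac_cpp(CharacterVector seqs, std::string pattern,
                         std::string pattern_rc, int max_mismatch,
                         bool both_strands) {
  if (pattern.size() == 0) stop("pattern has zero span");
  CompiledPattern fwd = compile_pattern(pattern);
  CompiledPattern rev = compile_pattern(pattern_rc);
  std::vector<int> out_seq, out_off, out_strand, out_mm;
  for (int si = 0; si < seqs.size(); ++si) {
    const char* s = CHAR(STRING_ELT(seqs, si));
    int n = (int) LENGTH(STRING_ELT(seqs, si));
    scan_one(s, n, fwd, max_mismatch, si + 1, false, out_seq, out_off, out_strand, out_mm);
    if (both_strands)
      scan_one(s, n, rev, max_mismatch, si + 1, true, out_seq, out_off, out_strand, out_mm);
  }
  return DataFrame::create(_["seq_index"] = out_seq, _["offset"] = out_off,
                           _["strand_code"] = out_strand, _["mismatches"] = out_mm);
}
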