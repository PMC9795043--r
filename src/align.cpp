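#include <Rcpp.h>
using namespace Rcpp;

// Gap-free semi-global placement of `ref` inside `read`: every offset at
// which ref fits entirely is scored (match +1, mismatch -2) and the best
// offset wins; ties go to the smallest offset. If the read is shorter than
// the ref the single offset 0 is scored over the read and flagged partial.
// [[Rcpp::export(name = ".align_gapfree_cpp")]]
List align_gapfree_cpp(std::string read, std::string ref,
                       int match = 1, int mismatch = -2) {
  const int lr = read.size(), lf = ref.size();
  const bool partial = lr < lf;
  const int span = partial ? lr : lf;
  const int max_off = partial ? 0 : lr - lf;
  int best_off = 0, best_score = INT_MIN, best_mm = span;
  for (int off = 0; off <= max_off; ++off) {
    int mm = 0;
    const char* r = read.data() + off;
    for (int i = 0; i < span; ++i) if (r[i] != ref[i]) ++mm;
    int score = (span - mm) * match + mm * mismatch;
    if (score > best_score) { best_score = score; best_off = off; best_mm = mm; }
  }
  // mismatch coordinates (0-based, in ref space) at the winning offset
  std::vector<int> mmpos;
  mmpos.reserve(best_mm);
  const char* r = read.data() + best_off;
  for (int i = 0; i < span; ++i) if (r[i] != ref[i]) mmpos.push_back(i);
  return List::create(
    _["offset"] = best_off, _["score"] = best_score,
    _["n_match"] = span - best_mm, _["n_mismatch"] = best_mm,
    _["mismatch_ref_pos"] = wrap(mmpos), _["span"] = span,
    _["partial"] = partial);
}

static inline char comp(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// Merge one read pair. s2/q2 are the raw reverse-strand mate; the function
// reverse-complements internally. Candidate placements put the mate's
// reverse complement at offset s of read 1 (s >= 0); overlap is scored by
// mismatch count, the placement with the fewest mismatches wins (ties:
// longer overlap, then smaller offset). Disagreements resolve to the
// higher-quality base (read 1 on equal quality); merged quality is the max.
// [[Rcpp::export(name = ".merge_pair_cpp")]]
List merge_pair_cpp(std::string s1, std::string q1,
                    std::string s2, std::string q2,
                    int min_overlap = 30, double max_mismatch_frac = 0.1) {
  const int l1 = s1.size(), l2 = s2.size();
  std::string s2rc(l2, 'N'), q2r(l2, '!');
  for (int i = 0; i < l2; ++i) {
    s2rc[i] = comp(s2[l2 - 1 - i]);
    q2r[i] = q2[l2 - 1 - i];
  }
  int best_s = -1, best_mm = INT_MAX, best_ov = 0;
  for (int s = 0; s <= l1 - min_overlap; ++s) {
    const int ov = std::min(l1 - s, l2);
    if (ov < min_overlap) break;
    int mm = 0;
    const int lim = (int)std::floor(max_mismatch_frac * ov);
    for (int i = 0; i < ov && mm <= lim; ++i)
      if (s1[s + i] != s2rc[i]) ++mm;
    if (mm > lim) continue;
    if (mm < best_mm || (mm == best_mm && ov > best_ov)) {
      best_mm = mm; best_s = s; best_ov = ov;
    }
  }
  if (best_s < 0)
    return List::create(_["merged"] = false);
  const int s = best_s, ov = best_ov;
  const int lm = s + std::max(ov, l2);  // l2 >= ov always; merged len = s + l2
  std::string ms(s + l2, 'N'), mq(s + l2, '!');
  for (int i = 0; i < s; ++i) { ms[i] = s1[i]; mq[i] = q1[i]; }
  for (int i = 0; i < ov; ++i) {
    const char b1 = s1[s + i], b2 = s2rc[i];
    const char c1 = q1[s + i], c2 = q2r[i];
    if (b1 == b2) { ms[s + i] = b1; }
    else { ms[s + i] = (c2 > c1) ? b2 : b1; }
    mq[s + i] = std::max(c1, c2);
  }
  for (int i = ov; i < l2; ++i) { ms[s + i] = s2rc[i]; mq[s + i] = q2r[i]; }
  (void)lm;
  return List::create(
    _["merged"] = true, _["sequence"] = ms, _["quality"] = mq,
    _["offset"] = s, _["overlap"] = ov, _["overlap_mismatches"] = best_mm);
}

// Vectorised merge over read pairs.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector s1, CharacterVector q1,
                     CharacterVector s2, CharacterVector q2,
                     int min_overlap = 30, double max_mismatch_frac = 0.1) {
  const int n = s1.size();
  LogicalVector merged(n);
  CharacterVector ms(n), mq(n);
  IntegerVector ov(n);
  for (int k = 0; k < n; ++k) {
    List r = merge_pair_cpp(as<std::string>(s1[k]), as<std::string>(q1[k]),
                            as<std::string>(s2[k]), as<std::string>(q2[k]),
                            min_overlap, max_mismatch_frac);
    if (as<bool>(r["merged"])) {
      merged[k] = true;
      ms[k] = as<std::string>(r["sequence"]);
      mq[k] = as<std::string>(r["quality"]);
      ov[k] = as<int>(r["overlap"]);
    } else {
      merged[k] = false; ms[k] = NA_STRING; mq[k] = NA_STRING; ov[k] = NA_INTEGER;
    }
  }
  return List::create(_["merged"] = merged, _["sequence"] = ms,
                      _["quality"] = mq, _["overlap"] = ov);
}

// Longest exact common substring between `a` (junction) and `b` (D
// segment). Ties prefer the 5'-most start in `a`, then the 5'-most start
// in `b`. Returns 0-based starts and the length (0 if no common base).
// [[Rcpp::export(name = ".lcs_cpp")]]
IntegerVector lcs_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best_len = 0, best_i = -1, best_j = -1;  // starts, 0-based
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > 0) {
        const int len = cur[j], si = i - len, sj = j - len;
        if (len > best_len ||
            (len == best_len && (si < best_i ||
                                 (si == best_i && sj < best_j)))) {
          best_len = len; best_i = si; best_j = sj;
        }
      }
    }
    std::swap(prev, cur);
  }
  return IntegerVector::create(best_len, best_i, best_j);
}

// Minimum Phred score (offset 33) inside [from, to] (1-based, inclusive)
// of each quality string.
// [[Rcpp::export(name = ".min_phred_cpp")]]
IntegerVector min_phred_cpp(CharacterVector qual, IntegerVector from, IntegerVector to) {
  const int n = qual.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    if (qual[k] == NA_STRING || from[k] == NA_INTEGER) { out[k] = NA_INTEGER; continue; }
    std::string q = as<std::string>(qual[k]);
    int a = from[k] - 1, b = std::min((int)q.size() - 1, to[k] - 1);
    int m = INT_MAX;
    for (int i = std::max(a, 0); i <= b; ++i) m = std::min(m, (int)q[i]);
    out[k] = (m == INT_MAX) ? NA_INTEGER : m - 33;
  }
  return out;
}

// Mean Phred score of each quality string.
// [[Rcpp::export(name = ".mean_phred_cpp")]]
NumericVector mean_phred_cpp(CharacterVector qual) {
  const int n = qual.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string q = as<std::string>(qual[k]);
    double s = 0;
    for (size_t i = 0; i < q.size(); ++i) s += q[i] - 33;
    out[k] = q.empty() ? NA_REAL : s / q.size();
  }
  return out;
}
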