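#include <Rcpp.h>
using namespace Rcpp;

// Greedy leftmost-longest scan for dinucleotide repeat tracts.
//
// At each position the longest run of the dinucleotide unit starting there
// is taken and the scan skips past it; positions that do not start a valid
// unit advance by one. Valid units are the eight orientable heteropolymers
// (GT/TG/AC/CA/CT/TC/AG/GA): units with two identical bases are never
// emitted and palindromic units (AT/TA/GC/CG) cannot be strand-oriented so
// they are excluded as well. N (or any non-ACGT byte) breaks tracts.
//
// Returns 0-based starts, the unit as read on the reference strand, and the
// number of complete units (true count, even beyond max_units; the R side
// flags over_max).

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'C': return 'G';
    case 'G': return 'C';
  }
  return 'N';
}

// [[Rcpp::export(name = ".dinuc_scan")]]
DataFrame dinuc_scan(std::string seq, int min_units) {
  const char *s = seq.c_str();
  const long n = (long) seq.size();
  std::vector<int> starts;
  std::vector<int> units;
  std::string unit_buf;
  std::vector<std::string> unit_out;

  long i = 0;
  while (i + 1 < n) {
    const char a = s[i], b = s[i + 1];
    if (is_acgt(a) && is_acgt(b) && a != b && b != comp(a)) {
      long k = 1;
      while (i + 2 * k + 1 < n && s[i + 2 * k] == a && s[i + 2 * k + 1] == b) ++k;
      if (k >= min_units) {
        starts.push_back((int) i);
        units.push_back((int) k);
        unit_buf.assign(1, a);
        unit_buf.push_back(b);
        unit_out.push_back(unit_buf);
        i += 2 * k;
        continue;
      }
    }
    ++i;
  }
  return DataFrame::create(_["start"] = starts,
                           _["unit"] = unit_out,
                           _["n_units"] = units,
                           _["stringsAsFactors"] = false);
}
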