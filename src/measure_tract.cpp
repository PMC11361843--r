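#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// Return codes for a single read measurement.  Non-negative values are
// measured tract lengths in bases; negative values are rejection codes
// translated to reason strings on the R side.
#define REJ_NOT_SPANNING   -1
#define REJ_FLANK_MISMATCH -2
#define REJ_BOUNDARY_INDEL -3

static inline char upc(char c) {
  return (c >= 'a' && c <= 'z') ? (char)(c - 32) : c;
}

// Walk one alignment and measure the observed tract length of the
// microsatellite at [start0, end0) (0-based half-open reference coords).
//
// The read must align (non-clipped) across the whole window
// [start0 - flank_len, end0 + flank_len); the flank_len read bases on each
// side of the tract must equal the reference flanks exactly; the reference
// bases immediately 5' (start0 - 1) and 3' (end0) of the tract must each be
// aligned to a read base (a deletion swallowing either anchor makes the
// tract boundary ambiguous and rejects the read).  The measured length is
// the number of read bases strictly between the two anchor bases:
// reference tract length plus insertions minus deletions inside the tract.
static int measure_one(int pos1, const std::string &cigar, const std::string &seq,
                       int start0, int end0,
                       const std::string &flank5, const std::string &flank3,
                       int flank_len) {
  long g = (long)pos1 - 1;  // next reference position (0-based)
  long r = 0;               // next read index (0-based)
  const long win_lo = (long)start0 - flank_len;
  const long win_hi = (long)end0 + flank_len - 1;
  long a5 = -1, a3 = -1;    // read indexes of the two anchor bases
  long minref = -1, maxref = -1;

  size_t i = 0;
  while (i < cigar.size()) {
    long len = 0;
    while (i < cigar.size() && std::isdigit((unsigned char)cigar[i])) {
      len = len * 10 + (cigar[i] - '0');
      ++i;
    }
    if (i >= cigar.size() || len <= 0) return REJ_NOT_SPANNING;  // malformed
    char op = cigar[i++];
    switch (op) {
    case 'M': case '=': case 'X':
      if (minref < 0) minref = g;
      maxref = g + len - 1;
      if ((long)start0 - 1 >= g && (long)start0 - 1 < g + len)
        a5 = r + ((long)start0 - 1 - g);
      if ((long)end0 >= g && (long)end0 < g + len)
        a3 = r + ((long)end0 - g);
      g += len; r += len;
      break;
    case 'I': case 'S':
      r += len;
      break;
    case 'D':
      g += len;
      break;
    case 'N':
      // spliced alignment: a skip touching the window cannot provide
      // contiguous tract evidence
      if (g + len - 1 >= win_lo && g <= win_hi) return REJ_NOT_SPANNING;
      g += len;
      break;
    case 'H': case 'P':
      break;
    default:
      return REJ_NOT_SPANNING;
    }
  }

  if (minref < 0 || minref > win_lo || maxref < win_hi) return REJ_NOT_SPANNING;
  // window covered by the aligned span but an anchor base missing: a
  // deletion crossed the flank/tract boundary
  if (a5 < 0 || a3 < 0) return REJ_BOUNDARY_INDEL;
  if (a5 - flank_len + 1 < 0 || a3 + flank_len > (long)seq.size())
    return REJ_NOT_SPANNING;

  for (int k = 0; k < flank_len; ++k) {
    char rb5 = upc(seq[a5 - flank_len + 1 + k]);
    if (rb5 == 'N' || rb5 != upc(flank5[k])) return REJ_FLANK_MISMATCH;
    char rb3 = upc(seq[a3 + k]);
    if (rb3 == 'N' || rb3 != upc(flank3[k])) return REJ_FLANK_MISMATCH;
  }
  return (int)(a3 - a5 - 1);
}

// [[Rcpp::export(name = ".measure_tract_cpp")]]
IntegerVector measure_tract_cpp(IntegerVector pos, CharacterVector cigar,
                                CharacterVector seq, int start0, int end0,
                                std::string flank5, std::string flank3,
                                int flank_len) {
  const R_xlen_t n = pos.size();
  if (cigar.size() != n || seq.size() != n)
    stop("pos, cigar and seq must have equal length");
  if ((int)flank5.size() != flank_len || (int)flank3.size() != flank_len)
    stop("flank sequences must have length flank_len");
  IntegerVector out(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    if (pos[j] == NA_INTEGER || cigar[j] == NA_STRING || seq[j] == NA_STRING) {
      out[j] = REJ_NOT_SPANNING;
      continue;
    }
    out[j] = measure_one(pos[j], as<std::string>(cigar[j]),
                         as<std::string>(seq[j]), start0, end0,
                         flank5, flank3, flank_len);
  }
  return out;
}
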