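// Banded global alignment with affine gaps (Gotoh) for near-identical
// sequences such as a mitogenome against the rCRS. The band is taken around
// the main diagonal: valid cells satisfy |j - i| <= band, which suffices as
// long as the cumulative indel displacement stays below the band width.

#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

// [[Rcpp::export(name = ".bandedAlign")]]
IntegerMatrix bandedAlign(std::string ref, std::string qry, int band,
                          int match, int mismatch, int ambig,
                          int gap_open, int gap_extend) {
  const int n = (int) ref.size();   // rows: reference
  const int m = (int) qry.size();   // cols: query
  if (std::abs(m - n) > band)
    stop("length difference %d exceeds band width %d", std::abs(m - n), band);
  const int W = 2 * band + 1;
  const long NEG = -1000000000L;

  std::vector<long> M((size_t)(n + 1) * W, NEG), X(M), Y(M);
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 0), tbX(tbM), tbY(tbM);
  // tbM: 0=from M, 1=from X, 2=from Y (diagonal predecessor)
  // tbX: 0=open (from M/Y), 1=extend; tbY likewise

  auto idx = [W, band](int i, int j) { return (size_t)i * W + (j - i + band); };
  auto inband = [band, m](int i, int j) { return j >= 0 && j <= m && std::abs(j - i) <= band; };

  M[idx(0, 0)] = 0;
  for (int j = 1; j <= band && j <= m; ++j) {       // leading gap in ref (query overhang)
    Y[idx(0, j)] = -(long)gap_open - (long)gap_extend * (j - 1);
    tbY[idx(0, j)] = j > 1 ? 1 : 0;
  }
  for (int i = 1; i <= n; ++i) {
    if (i <= band) {                                 // leading gap in query
      X[idx(i, 0)] = -(long)gap_open - (long)gap_extend * (i - 1);
      tbX[idx(i, 0)] = i > 1 ? 1 : 0;
    }
    const int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    const char rc = ref[i - 1];
    const int rm = iupac_mask(rc);
    for (int j = jlo; j <= jhi; ++j) {
      const size_t h = idx(i, j);
      // M: diagonal
      {
        const size_t d = idx(i - 1, j - 1);
        long best = M[d]; unsigned char who = 0;
        if (X[d] > best) { best = X[d]; who = 1; }
        if (Y[d] > best) { best = Y[d]; who = 2; }
        if (best > NEG) {
          const char qc = qry[j - 1];
          long s;
          if (qc == rc) s = match;
          else if (iupac_mask(qc) & rm) s = ambig;
          else s = mismatch;
          M[h] = best + s; tbM[h] = who;
        }
      }
      // X: gap in query (reference base deleted), from (i-1, j)
      if (inband(i - 1, j)) {
        const size_t u = idx(i - 1, j);
        long op = std::max(M[u], Y[u]);
        long opn = op > NEG ? op - gap_open : NEG;
        long ext = X[u] > NEG ? X[u] - gap_extend : NEG;
        if (opn >= ext) { X[h] = opn; tbX[h] = 0; } else { X[h] = ext; tbX[h] = 1; }
      }
      // Y: gap in reference (insertion), from (i, j-1)
      if (inband(i, j - 1)) {
        const size_t l = idx(i, j - 1);
        long op = std::max(M[l], X[l]);
        long opn = op > NEG ? op - gap_open : NEG;
        long ext = Y[l] > NEG ? Y[l] - gap_extend : NEG;
        if (opn >= ext) { Y[h] = opn; tbY[h] = 0; } else { Y[h] = ext; tbY[h] = 1; }
      }
    }
  }

  const size_t e = idx(n, m);
  int state = 0; long best = M[e];
  if (X[e] > best) { best = X[e]; state = 1; }
  if (Y[e] > best) { best = Y[e]; state = 2; }
  if (best <= NEG)
    stop("no alignment within band; increase the band width");

  // traceback: op 0 = aligned pair, 1 = deletion (ref consumed), 2 = insertion
  std::vector<int> ops, ripos, qjpos;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t h = idx(i, j);
    if (state == 0) {
      ops.push_back(0); ripos.push_back(i); qjpos.push_back(j);
      state = tbM[h]; --i; --j;
    } else if (state == 1) {
      ops.push_back(1); ripos.push_back(i); qjpos.push_back(0);
      unsigned char t = tbX[h];
      --i;
      if (t == 0) { // opened from M or Y at (i, j)
        const size_t u = idx(i, j);
        state = (M[u] >= Y[u]) ? 0 : 2;
      }
    } else {
      ops.push_back(2); ripos.push_back(i); qjpos.push_back(j);
      unsigned char t = tbY[h];
      --j;
      if (t == 0) {
        const size_t l = idx(i, j);
        state = (M[l] >= X[l]) ? 0 : 1;
      }
    }
  }
  const int L = (int) ops.size();
  IntegerMatrix out(L, 3);
  for (int k = 0; k < L; ++k) {        // reverse into alignment order
    out(k, 0) = ops[L - 1 - k];
    out(k, 1) = ripos[L - 1 - k];
    out(k, 2) = qjpos[L - 1 - k];
  }
  colnames(out) = CharacterVector::create("op", "ref", "qry");
  return out;
}
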