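#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Guide/genome scanner for protospacer homology search.
//
// A candidate site is anchored at a PAM occurrence: 3 genomic bases N[G/A]G
// immediately 3' of the protospacer-homologous window. For each PAM position
// the best alignment of the 20-nt guide to the adjacent window is taken over
//   * no bulge      : 20-nt window
//   * one DNA bulge : 21-nt window, one internal genomic base unpaired
//                     (window positions 2..20)
//   * one RNA bulge : 19-nt window, one internal guide base unpaired
//                     (guide positions 2..19)
// under the lexicographic cost (bulge_size, mismatches); ties prefer no
// bulge, then DNA over RNA bulge, then the leftmost (PAM-distal) gap.
// Windows containing any non-ACGT base never match. At most one bulge total.
//
// Alignment costs for all gap placements at one PAM are evaluated in O(1)
// each from prefix sums of three per-offset mismatch vectors.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
DataFrame scan_guide_cpp(std::string subject, std::string guide,
                         int max_mm, bool allow_bulge, bool include_nag) {
  const int L = (int) subject.size();
  const char* S = subject.c_str();
  if ((int) guide.size() != 20) stop("guide must be 20 nt");
  const char* g = guide.c_str();   // g[0..19], g[19] PAM-proximal

  std::vector<int> out_pam, out_ws, out_wlen, out_mm, out_bulge, out_gap;
  std::vector<int> out_class; // 1 = NGG, 2 = NAG

  // prefix sums; index semantics documented at use sites
  int P0[21], Q1[20], Q2[19];
  long lastN = -1;                 // most recent non-ACGT index seen

  for (int q = 0; q + 2 < L; ++q) {  // q = 0-based PAM start
    if (q > 0 && !is_acgt(S[q - 1])) lastN = q - 1;
    char p1 = S[q], p2 = S[q + 1], p3 = S[q + 2];
    if (!is_acgt(p1) || p3 != 'G') continue;
    int pclass;
    if (p2 == 'G') pclass = 1;
    else if (p2 == 'A' && include_nag) pclass = 2;
    else continue;

    bool ok20 = q >= 20 && lastN < (long) q - 20;
    bool ok21 = q >= 21 && lastN < (long) q - 21;
    bool ok19 = q >= 19 && lastN < (long) q - 19;
    if (!ok20 && !(allow_bulge && (ok21 || ok19))) continue;

    // m0[t]: guide pos 20-t vs S[q-1-t] (right-aligned, offset 0)
    // P0[T] = sum of m0[0..T-1]
    P0[0] = 0;
    if (ok20 || ok21 || ok19) {
      int tmax = ok21 || ok20 ? 20 : 19;
      for (int t = 0; t < tmax; ++t)
        P0[t + 1] = P0[t] + (S[q - 1 - t] != g[19 - t] ? 1 : 0);
      for (int t = tmax; t < 20; ++t) P0[t + 1] = P0[t] + 1; // unused
    }

    int best_mm = -1, best_bulge = 0, best_gap = 0, best_wlen = 0;
    bool have = false;

    if (ok20) {                    // no bulge
      int mm = P0[20];
      if (mm <= max_mm) {
        best_mm = mm; best_bulge = 0; best_gap = 0; best_wlen = 20;
        have = true;
      }
    }
    if (allow_bulge) {
      if (ok21) {
        // DNA bulge, gap at window position j (2..20):
        //   mm(j) = P0[21-j] + Q1[j-1]
        // Q1[I] = mismatches of guide pos 1..I vs S[q-22+i] (i = 1..I)
        Q1[0] = 0;
        for (int i = 1; i <= 19; ++i)
          Q1[i] = Q1[i - 1] + (S[q - 22 + i] != g[i - 1] ? 1 : 0);
        for (int j = 2; j <= 20; ++j) {
          int mm = P0[21 - j] + Q1[j - 1];
          if (mm > max_mm) continue;
          if (!have || (best_bulge != 0 && mm < best_mm)) {
            // no-bulge (bulge_size 0) always beats a bulged alignment;
            // among DNA gaps the leftmost (smallest j) wins ties
            best_mm = mm; best_bulge = 1; best_gap = j; best_wlen = 21;
            have = true;
          }
        }
      }
      if (ok19) {
        // RNA bulge, unpaired guide position k (2..19):
        //   mm(k) = P0[20-k] + Q2[k-1]
        // Q2[I] = mismatches of guide pos 1..I vs S[q-20+i] (i = 1..I)
        Q2[0] = 0;
        for (int i = 1; i <= 18; ++i)
          Q2[i] = Q2[i - 1] + (S[q - 20 + i] != g[i - 1] ? 1 : 0);
        for (int k = 2; k <= 19; ++k) {
          int mm = P0[20 - k] + Q2[k - 1];
          if (mm > max_mm) continue;
          // RNA loses to no-bulge always and to DNA at equal mm
          if (!have ||
              (best_bulge == 1 && mm < best_mm) ||
              (best_bulge == 2 && mm < best_mm)) {
            best_mm = mm; best_bulge = 2; best_gap = k; best_wlen = 19;
            have = true;
          }
        }
      }
    }
    if (!have) continue;
    out_pam.push_back(q + 1);                  // 1-based
    out_ws.push_back(q + 1 - best_wlen);       // 1-based window start
    out_wlen.push_back(best_wlen);
    out_mm.push_back(best_mm);
    out_bulge.push_back(best_bulge);
    out_gap.push_back(best_gap);
    out_class.push_back(pclass);
  }

  // mismatch positions (1-based guide coordinates) for the kept alignments
  int n = (int) out_pam.size();
  CharacterVector mmpos(n);
  for (int r = 0; r < n; ++r) {
    int ws = out_ws[r] - 1, wlen = out_wlen[r];
    int bulge = out_bulge[r];
    int gap0 = out_gap[r] - 1;   // 0-based window pos (DNA) / guide pos (RNA)
    std::string acc;
    for (int i = 0; i < wlen; ++i) {
      int gi;
      if (bulge == 1) {
        if (i == gap0) continue;
        gi = (i < gap0) ? i : i - 1;
      } else if (bulge == 2) {
        gi = (i < gap0) ? i : i + 1;
      } else gi = i;
      if (S[ws + i] != g[gi]) {
        if (!acc.empty()) acc += ",";
        acc += std::to_string(gi + 1);
      }
    }
    mmpos[r] = acc;
  }

  return DataFrame::create(
    Named("pam_start") = out_pam,
    Named("window_start") = out_ws,
    Named("window_len") = out_wlen,
    Named("mismatches") = out_mm,
    Named("bulge") = out_bulge,
    Named("gap_pos") = out_gap,
    Named("pam_class") = out_class,
    Named("mm_positions") = mmpos,
    Named("stringsAsFactors") = false);
}
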