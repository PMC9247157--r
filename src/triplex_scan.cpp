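#include <Rcpp.h>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, T/U=3, masked or ambiguous=4.
// Motif codes: 0 pyrimidine_parallel, 1 purine_antiparallel,
//              2 GT_parallel, 3 GT_antiparallel.
// The third strand (RNA) is compared against the purine strand of the
// duplex; antiparallel motifs read the RNA 3'->5', which is implemented by
// reversing the RNA before the diagonal walk.

static inline bool motif_match(int motif, int r, int d) {
  switch (motif) {
  case 0: return (r == 3 && d == 0) || (r == 1 && d == 2); // U.A, C.G
  case 1: return (r == 0 && d == 0) || (r == 2 && d == 2); // A.A, G.G
  case 2:
  case 3: return (r == 2 && d == 2) || (r == 3 && d == 0); // G.G, U.A
  }
  return false;
}

struct Hit {
  int region, strand /*0 = +, 1 = -*/, motif;
  int rna_start, rna_end;   // 1-based on the original RNA
  int dna_start, dna_end;   // 1-based forward coordinates within the region
  int len, mism, gua;       // gua = guanines on the purine-strand window
};

// Scan one (possibly reversed) RNA against one purine-strand segment for one
// motif.  Reports containment-maximal windows per diagonal satisfying:
// first and last position match, length in [min_len, max_len], mismatch
// count <= max_err * length.  Guanine-rate filtering happens in the caller.
static void scan_pair(const std::vector<int>& R, const std::vector<int>& D,
                      int motif, int min_len, int max_len, double max_err,
                      std::vector<std::array<int, 5> >& out) {
  const int n = (int)R.size(), m = (int)D.size();
  if (n < min_len || m < min_len) return;
  std::vector<int> mism_pref;   // prefix mismatch counts along a diagonal
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i0 = d < 0 ? 1 - d : 1;      // first RNA pos (1-based) on diagonal
    int j0 = d < 0 ? 1 : 1 + d;      // first DNA pos
    int L = std::min(n - i0 + 1, m - j0 + 1);
    if (L < min_len) continue;
    mism_pref.assign(L + 1, 0);
    bool any_match = false;
    for (int k = 1; k <= L; ++k) {
      bool mt = motif_match(motif, R[i0 + k - 2], D[j0 + k - 2]);
      mism_pref[k] = mism_pref[k - 1] + (mt ? 0 : 1);
      if (mt) any_match = true;
    }
    if (!any_match) continue;
    int best_e = 0; // rightmost feasible end seen so far on this diagonal
    for (int s = 1; s + min_len - 1 <= L; ++s) {
      if (mism_pref[s] == mism_pref[s - 1] + 1) continue; // mismatch at s
      int hi = std::min(L, s + max_len - 1);
      int lo = s + min_len - 1;
      int emax = -1;
      for (int e = hi; e >= lo; --e) {
        if (mism_pref[e] == mism_pref[e - 1] + 1) continue; // mismatch at e
        int mm = mism_pref[e] - mism_pref[s - 1];
        int len = e - s + 1;
        if ((double)mm <= max_err * len + 1e-9) { emax = e; break; }
      }
      if (emax < 0 || emax <= best_e) continue;
      best_e = emax;
      int mm = mism_pref[emax] - mism_pref[s - 1];
      out.push_back({i0 + s - 1, i0 + emax - 1, j0 + s - 1, j0 + emax - 1, mm});
    }
  }
}

// Candidate DNA sub-segments on the purine strand: union of min_len windows
// with at most floor(max_err*max_len) non-purine bases.  Any qualifying hit
// window has pyrimidine count <= mismatches <= max_err*len <= that bound and
// is covered by its own min_len sub-windows, so restricting the scan to
// these segments loses nothing.
static void candidate_segments(const std::vector<int>& D, int min_len,
                               int bound,
                               std::vector<std::pair<int, int> >& seg) {
  const int m = (int)D.size();
  seg.clear();
  if (m < min_len) return;
  int pyr = 0;
  for (int i = 0; i < min_len; ++i) pyr += (D[i] != 0 && D[i] != 2);
  int cur_a = -1, cur_b = -1;
  for (int s = 0; s + min_len <= m; ++s) {
    if (s > 0) {
      pyr -= (D[s - 1] != 0 && D[s - 1] != 2);
      pyr += (D[s + min_len - 1] != 0 && D[s + min_len - 1] != 2);
    }
    if (pyr <= bound) {
      int a = s, b = s + min_len - 1;
      if (cur_a < 0) { cur_a = a; cur_b = b; }
      else if (a <= cur_b + 1) { cur_b = b; }
      else { seg.push_back({cur_a, cur_b}); cur_a = a; cur_b = b; }
    }
  }
  if (cur_a >= 0) seg.push_back({cur_a, cur_b});
}

// [[Rcpp::export(name = ".triplex_scan_cpp")]]
DataFrame triplex_scan_cpp(IntegerVector rna, List dna_list, int min_len,
                           int max_len, double max_err, double min_g,
                           IntegerVector motifs) {
  std::vector<int> R(rna.begin(), rna.end());
  std::vector<int> Rrev(R.rbegin(), R.rend());
  const int n = (int)R.size();
  int bound = (int)std::floor(max_err * max_len + 1e-9);
  std::vector<Hit> hits;
  std::vector<std::pair<int, int> > seg;
  std::vector<std::array<int, 5> > raw;

  for (int ri = 0; ri < dna_list.size(); ++ri) {
    IntegerVector dv = dna_list[ri];
    std::vector<int> fwd(dv.begin(), dv.end());
    const int m = (int)fwd.size();
    for (int strand = 0; strand < 2; ++strand) {
      // purine strand: forward sequence (+) or its reverse complement (-)
      std::vector<int> D;
      if (strand == 0) D = fwd;
      else {
        D.resize(m);
        for (int i = 0; i < m; ++i) {
          int c = fwd[m - 1 - i];
          D[i] = (c <= 3) ? 3 - c : 4;
        }
      }
      candidate_segments(D, min_len, bound, seg);
      if (seg.empty()) continue;
      // guanine prefix on the purine strand
      std::vector<int> gpref(m + 1, 0);
      for (int i = 0; i < m; ++i) gpref[i + 1] = gpref[i] + (D[i] == 2);
      for (size_t si = 0; si < seg.size(); ++si) {
        int a = seg[si].first, b = seg[si].second;
        std::vector<int> Dseg(D.begin() + a, D.begin() + b + 1);
        for (int mi = 0; mi < motifs.size(); ++mi) {
          int motif = motifs[mi];
          bool anti = (motif == 1 || motif == 3);
          const std::vector<int>& Ruse = anti ? Rrev : R;
          raw.clear();
          scan_pair(Ruse, Dseg, motif, min_len, max_len, max_err, raw);
          for (size_t h = 0; h < raw.size(); ++h) {
            int rs = raw[h][0], re = raw[h][1];
            int ds = raw[h][2] + a, de = raw[h][3] + a; // 1-based in D
            int len = re - rs + 1, mm = raw[h][4];
            int gua = gpref[de] - gpref[ds - 1];
            if ((double)gua + 1e-9 < min_g * len) continue;
            Hit ht;
            ht.region = ri + 1;
            ht.strand = strand;
            ht.motif = motif;
            if (anti) { ht.rna_start = n - re + 1; ht.rna_end = n - rs + 1; }
            else { ht.rna_start = rs; ht.rna_end = re; }
            if (strand == 0) { ht.dna_start = ds; ht.dna_end = de; }
            else { ht.dna_start = m - de + 1; ht.dna_end = m - ds + 1; }
            ht.len = len; ht.mism = mm; ht.gua = gua;
            hits.push_back(ht);
          }
        }
      }
    }
  }

  const int H = (int)hits.size();
  IntegerVector region(H), motif(H), rs(H), re(H), ds(H), de(H), len(H),
      mm(H), gua(H);
  CharacterVector strand(H);
  for (int i = 0; i < H; ++i) {
    region[i] = hits[i].region;
    strand[i] = hits[i].strand == 0 ? "+" : "-";
    motif[i] = hits[i].motif;
    rs[i] = hits[i].rna_start; re[i] = hits[i].rna_end;
    ds[i] = hits[i].dna_start; de[i] = hits[i].dna_end;
    len[i] = hits[i].len; mm[i] = hits[i].mism; gua[i] = hits[i].gua;
  }
  return DataFrame::create(
      _["region"] = region, _["strand"] = strand, _["motif_code"] = motif,
      _["rna_start"] = rs, _["rna_end"] = re, _["dna_start"] = ds,
      _["dna_end"] = de, _["length"] = len, _["mismatches"] = mm,
      _["guanines"] = gua);
}
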