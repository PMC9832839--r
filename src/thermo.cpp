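#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Unified nearest-neighbor duplex parameters (1 M NaCl reference state).
// dH in kcal/mol, dS in cal/(mol K), indexed by 4*b1 + b2 with
// A=0, C=1, G=2, T=3; values for a dinucleotide equal those of its
// reverse complement.
static const double NN_DH[16] = {
  -7.9, -8.4, -7.8, -7.2,   // AA AC AG AT
  -8.5, -8.0, -10.6, -7.8,  // CA CC CG CT
  -8.2, -9.8, -8.0, -8.4,   // GA GC GG GT
  -7.2, -8.2, -8.5, -7.9    // TA TC TG TT
};
static const double NN_DS[16] = {
  -22.2, -22.4, -21.0, -20.4,
  -22.7, -19.9, -27.2, -21.0,
  -22.2, -24.4, -19.9, -22.4,
  -21.3, -22.2, -22.7, -22.2
};

// terminal initiation terms
static const double INIT_AT_DH = 2.3, INIT_AT_DS = 4.1;
static const double INIT_GC_DH = 0.1, INIT_GC_DS = -2.8;

static const double R_GAS = 1.987; // cal/(mol K)

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Duplex melting temperature (deg C) by nearest-neighbor summation with
// entropic monovalent-salt correction: dS' = dS + 0.368 (n-1) ln[Na+],
// Tm = 1000 dH / (dS' + R ln(Ct/4)) - 273.15 for non-self-complementary
// oligos at total strand concentration Ct.
// [[Rcpp::export]]
NumericVector tm_nn_cpp(CharacterVector seqs, double monovalent_mM,
                        double primer_nM) {
  int n = seqs.size();
  NumericVector out(n);
  double salt_M = monovalent_mM / 1000.0;
  double ct = primer_nM * 1e-9;
  double r_term = R_GAS * std::log(ct / 4.0);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = (int)s.size();
    if (len < 2) { out[i] = NA_REAL; continue; }
    double dh = 0.0, ds = 0.0;
    bool bad = false;
    int prev = base_code(s[0]);
    if (prev < 0) bad = true;
    // terminal initiation, both ends
    for (int e = 0; e < 2 && !bad; ++e) {
      int b = base_code(e == 0 ? s[0] : s[len - 1]);
      if (b < 0) { bad = true; break; }
      if (b == 0 || b == 3) { dh += INIT_AT_DH; ds += INIT_AT_DS; }
      else                  { dh += INIT_GC_DH; ds += INIT_GC_DS; }
    }
    for (int j = 1; j < len && !bad; ++j) {
      int b = base_code(s[j]);
      if (b < 0) { bad = true; break; }
      dh += NN_DH[4 * prev + b];
      ds += NN_DS[4 * prev + b];
      prev = b;
    }
    if (bad) { out[i] = NA_REAL; continue; }
    double ds_salt = ds + 0.368 * (len - 1) * std::log(salt_M);
    out[i] = 1000.0 * dh / (ds_salt + r_term) - 273.15;
  }
  return out;
}
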