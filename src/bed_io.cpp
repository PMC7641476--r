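// Low-level access to PLINK 1 .bed data (variant-major, 2-bit codes).
//
// Bit-pair decode table, reading pairs from the least-significant bits up:
//   00 -> 2 copies of allele1 (dosage 2)
//   01 -> missing
//   10 -> heterozygote (dosage 1)
//   11 -> 0 copies of allele1 (dosage 0)
// Dosages count the BIM A1 allele; effect signs follow A1.

#include <Rcpp.h>
#include <fstream>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const int BED_HEADER = 3;

// dosage by 2-bit code; -1 flags missing
static const double CODE_DOSAGE[4] = {2.0, -1.0, 1.0, 0.0};

static inline std::size_t bytes_per_variant(int n_samples) {
  return (static_cast<std::size_t>(n_samples) + 3) / 4;
}

static void open_bed(std::ifstream& in, const std::string& path) {
  in.open(path.c_str(), std::ios::binary);
  if (!in) stop("cannot open bed file '%s'", path);
}

// Genotype counts per variant over a subset of samples.
// Returns a |var_idx| x 3 matrix with columns (n1, n2, n_missing);
// the count of zeros is |sample_idx| minus the row sum.
// [[Rcpp::export]]
IntegerMatrix cpp_bed_counts(std::string path, int n_samples,
                             IntegerVector var_idx, IntegerVector sample_idx) {
  const std::size_t bpv = bytes_per_variant(n_samples);
  std::ifstream in;
  open_bed(in, path);
  std::vector<char> buf(bpv);
  IntegerMatrix out(var_idx.size(), 3);
  for (R_xlen_t v = 0; v < var_idx.size(); ++v) {
    const std::size_t off = BED_HEADER + static_cast<std::size_t>(var_idx[v]) * bpv;
    in.seekg(off, std::ios::beg);
    in.read(buf.data(), bpv);
    if (!in) stop("read failure at variant %d", var_idx[v]);
    int n1 = 0, n2 = 0, nm = 0;
    for (R_xlen_t s = 0; s < sample_idx.size(); ++s) {
      const int i = sample_idx[s];
      const int code = (static_cast<unsigned char>(buf[i >> 2]) >> ((i & 3) << 1)) & 3;
      if (code == 0) ++n2;
      else if (code == 2) ++n1;
      else if (code == 1) ++nm;
    }
    out(v, 0) = n1;
    out(v, 1) = n2;
    out(v, 2) = nm;
  }
  return out;
}

// Dense block of dosages for the requested variants (all samples, in file
// sample order). Missing entries become impute[j], or NA when raw = true.
// [[Rcpp::export]]
NumericMatrix cpp_bed_block(std::string path, int n_samples,
                            IntegerVector var_idx, NumericVector impute,
                            bool raw) {
  const std::size_t bpv = bytes_per_variant(n_samples);
  std::ifstream in;
  open_bed(in, path);
  std::vector<char> buf(bpv);
  NumericMatrix out(n_samples, var_idx.size());
  for (R_xlen_t v = 0; v < var_idx.size(); ++v) {
    const std::size_t off = BED_HEADER + static_cast<std::size_t>(var_idx[v]) * bpv;
    in.seekg(off, std::ios::beg);
    in.read(buf.data(), bpv);
    if (!in) stop("read failure at variant %d", var_idx[v]);
    const double fill = raw ? NA_REAL : impute[v];
    for (int i = 0; i < n_samples; ++i) {
      const int code = (static_cast<unsigned char>(buf[i >> 2]) >> ((i & 3) << 1)) & 3;
      const double d = CODE_DOSAGE[code];
      out(i, v) = (d < 0.0) ? fill : d;
    }
  }
  return out;
}

// SNP-optimized inner products x_j^T R_c for the requested variants against
// each column of R, in one sequential pass over the variants' bytes.
// Zero-dosage entries contribute nothing; three accumulators per column
// collect the samples with dosage 1, dosage 2, and missing, so that
//   x^T r = 1 * sum_{x=1} r + 2 * sum_{x=2} r + mu * sum_{x=missing} r.
// var_idx must be ascending. chunk_size variants are read per buffered
// block; the result does not depend on chunk_size beyond float ordering.
// [[Rcpp::export]]
NumericMatrix cpp_bed_xtr(std::string path, int n_samples,
                          IntegerVector var_idx, NumericMatrix R,
                          NumericVector impute, int chunk_size) {
  if (R.nrow() != n_samples)
    stop("R has %d rows; expected %d", R.nrow(), n_samples);
  if (chunk_size < 1) stop("chunk_size must be >= 1");
  const std::size_t bpv = bytes_per_variant(n_samples);
  const R_xlen_t p = var_idx.size(), k = R.ncol();
  std::ifstream in;
  open_bed(in, path);
  NumericMatrix out(p, k);
  std::vector<char> buf;
  std::vector<double> s1(k), s2(k), sm(k);
  for (R_xlen_t lo = 0; lo < p; lo += chunk_size) {
    const R_xlen_t hi = std::min(lo + chunk_size, p) - 1;
    // contiguous span covering the chunk's variants
    const std::size_t first = var_idx[lo], last = var_idx[hi];
    const std::size_t span = (last - first + 1) * bpv;
    buf.resize(span);
    in.seekg(BED_HEADER + first * bpv, std::ios::beg);
    in.read(buf.data(), span);
    if (!in) stop("read failure in variant span [%d, %d]", (int)first, (int)last);
    for (R_xlen_t v = lo; v <= hi; ++v) {
      const char* vb = buf.data() + (static_cast<std::size_t>(var_idx[v]) - first) * bpv;
      std::fill(s1.begin(), s1.end(), 0.0);
      std::fill(s2.begin(), s2.end(), 0.0);
      std::fill(sm.begin(), sm.end(), 0.0);
      for (int i = 0; i < n_samples; ++i) {
        const int code = (static_cast<unsigned char>(vb[i >> 2]) >> ((i & 3) << 1)) & 3;
        if (code == 3) continue;                       // dosage 0: skip
        if (code == 2)      for (R_xlen_t c = 0; c < k; ++c) s1[c] += R(i, c);
        else if (code == 0) for (R_xlen_t c = 0; c < k; ++c) s2[c] += R(i, c);
        else                for (R_xlen_t c = 0; c < k; ++c) sm[c] += R(i, c);
      }
      for (R_xlen_t c = 0; c < k; ++c)
        out(v, c) = s1[c] + 2.0 * s2[c] + impute[v] * sm[c];
    }
  }
  return out;
}
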