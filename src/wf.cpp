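#include <Rcpp.h>
using namespace Rcpp;

// Wright-Fisher diploid reproduction with recombination.
//
// Layout: phased haplotypes, rows 2i, 2i+1 (0-based) belong to individual i.
// Phase is re-drawn at chromosome boundaries (free recombination between
// chromosomes); within a chromosome, crossovers occur between adjacent SNPs
// with probability `recomb` per meiosis, drawn by geometric skipping so RNG
// cost scales with crossover count, not loci. All randomness comes from R's
// RNG, so set.seed() governs reproducibility.

static void make_gamete(const int* h0, const int* h1, int* dst,
                        const std::vector<int>& block_start, double recomb) {
  for (size_t b = 0; b + 1 < block_start.size(); ++b) {
    int pos = block_start[b];
    const int end = block_start[b + 1];
    int phase = (unif_rand() < 0.5) ? 1 : 0;
    while (pos < end) {
      int seg_end = end;
      if (recomb > 0.0) {
        // loci until the next crossover: 1 + Geom(recomb)
        double run = 1.0 + R::rgeom(recomb);
        if (pos + run < (double)end) seg_end = pos + (int)run;
      }
      const int* src = phase ? h1 : h0;
      std::copy(src + pos, src + seg_end, dst + pos);
      pos = seg_end;
      phase = 1 - phase;
    }
  }
}

static std::vector<int> chrom_blocks(const IntegerVector& chrom) {
  std::vector<int> bs;
  bs.push_back(0);
  for (int j = 1; j < chrom.size(); ++j)
    if (chrom[j] != chrom[j - 1]) bs.push_back(j);
  bs.push_back(chrom.size());
  return bs;
}

// One generation: `parents` is an M x 2 matrix of 0-based parental
// individual indices; each parent contributes one recombinant gamete.
// [[Rcpp::export]]
IntegerMatrix wf_offspring(const IntegerMatrix& H, const IntegerVector& chrom,
                           const IntegerMatrix& parents, double recomb) {
  const int L = H.ncol();
  const int M = parents.nrow();
  const int nh = H.nrow();
  std::vector<int> cur((size_t)nh * L);
  for (int h = 0; h < nh; ++h)
    for (int j = 0; j < L; ++j) cur[(size_t)h * L + j] = H(h, j);
  std::vector<int> bs = chrom_blocks(chrom);
  std::vector<int> nxt((size_t)2 * M * L);
  for (int k = 0; k < M; ++k) {
    for (int g = 0; g < 2; ++g) {
      const int par = parents(k, g);
      make_gamete(&cur[(size_t)(2 * par) * L], &cur[(size_t)(2 * par + 1) * L],
                  &nxt[(size_t)(2 * k + g) * L], bs, recomb);
    }
  }
  IntegerMatrix out(2 * M, L);
  for (int h = 0; h < 2 * M; ++h)
    for (int j = 0; j < L; ++j) out(h, j) = nxt[(size_t)h * L + j];
  return out;
}

// Multi-generation evolution with optional additive viability selection on
// the focal column (fitness 1, 1+s, 1+2s by dosage). Population size is
// constant at nrow(H)/2. Stops early (lost = TRUE) if the focal allele
// count hits zero after any generation.
// [[Rcpp::export]]
List wf_evolve(const IntegerMatrix& H, const IntegerVector& chrom,
               int n_gens, double recomb, int focal, double s) {
  const int L = H.ncol();
  const int nh = H.nrow();
  const int N = nh / 2;
  std::vector<int> cur((size_t)nh * L), nxt((size_t)nh * L);
  for (int h = 0; h < nh; ++h)
    for (int j = 0; j < L; ++j) cur[(size_t)h * L + j] = H(h, j);
  std::vector<int> bs = chrom_blocks(chrom);
  std::vector<double> cw(N);
  bool lost = false;

  for (int g = 0; g < n_gens && !lost; ++g) {
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = 1.0;
      if (focal >= 0 && s > 0.0)
        w += s * (cur[(size_t)(2 * i) * L + focal] +
                  cur[(size_t)(2 * i + 1) * L + focal]);
      tot += w;
      cw[i] = tot;
    }
    for (int k = 0; k < nh; ++k) {
      double u = unif_rand() * tot;
      int par = std::lower_bound(cw.begin(), cw.end(), u) - cw.begin();
      if (par >= N) par = N - 1;
      make_gamete(&cur[(size_t)(2 * par) * L], &cur[(size_t)(2 * par + 1) * L],
                  &nxt[(size_t)k * L], bs, recomb);
    }
    cur.swap(nxt);
    if (focal >= 0) {
      long total = 0;
      for (int h = 0; h < nh; ++h) total += cur[(size_t)h * L + focal];
      if (total == 0) lost = true;
    }
  }

  IntegerMatrix out(nh, L);
  for (int h = 0; h < nh; ++h)
    for (int j = 0; j < L; ++j) out(h, j) = cur[(size_t)h * L + j];
  return List::create(_["H"] = out, _["lost"] = lost);
}
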