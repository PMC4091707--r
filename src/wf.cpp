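// Forward Wright-Fisher simulation of a single L-bp locus in a haploid
// asexual population of size N.  Each generation: a selection step
// (fitness-weighted multinomial resampling to size N) followed by a
// mutation step (every base mutates with probability mu, uniformly to one
// of the other three bases).  The population is stored as a map from
// unique genotype to count, which keeps the cost per generation near
// O(#unique genotypes) in the monomorphic regime.
#include <Rcpp.h>
#include <map>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<unsigned char> Geno;
typedef std::map<Geno, int> Pop;

static inline double geno_energy(const Geno& g, const NumericMatrix& em) {
  double e = 0.0;
  for (size_t i = 0; i < g.size(); ++i) e += em(g[i], i);
  return e;
}

// fit_type: 0 = Fermi-Dirac (f0, beta, mu); 1 = exponential per-generation
// fitness F = exp(-rate * E) with rate = p1.
static inline double geno_fitness(double E, int fit_type, double p1,
                                  double p2, double p3) {
  if (fit_type == 0) {
    double x = p2 * (E - p3);
    double p = (x > 0.0) ? std::exp(-x) / (1.0 + std::exp(-x))
                         : 1.0 / (1.0 + std::exp(x));
    return p1 + (1.0 - p1) * p;
  }
  return std::exp(-p1 * E);
}

static std::string geno_to_string(const Geno& g) {
  static const char* B = "ACGT";
  std::string s(g.size(), 'A');
  for (size_t i = 0; i < g.size(); ++i) s[i] = B[g[i]];
  return s;
}

// [[Rcpp::export]]
List wf_simulate_cpp(int N, int L, double mu, NumericMatrix em,
                     int fit_type, double p1, double p2, double p3,
                     IntegerVector checkpoints, int n_rep,
                     Nullable<IntegerVector> start_seq) {
  const int nck = checkpoints.size();
  CharacterMatrix seqs(n_rep, nck);
  IntegerMatrix uniq(n_rep, nck);
  std::vector<int> cks(checkpoints.begin(), checkpoints.end());
  int gmax = 0;
  for (int c : cks) if (c > gmax) gmax = c;

  bool fixed_start = start_seq.isNotNull();
  Geno start(L, 0);
  if (fixed_start) {
    IntegerVector sv(start_seq);
    if (sv.size() != L) stop("start_seq must have length L");
    for (int i = 0; i < L; ++i) start[i] = (unsigned char)(sv[i] - 1);
  }

  for (int rep = 0; rep < n_rep; ++rep) {
    Pop pop;
    Geno init = start;
    if (!fixed_start)
      for (int i = 0; i < L; ++i)
        init[i] = (unsigned char)(int)(unif_rand() * 4.0) % 4;
    pop[init] = N;

    int next_ck = 0;
    // record generation-0 checkpoints if requested
    for (int gen = 0; gen <= gmax; ++gen) {
      while (next_ck < nck && cks[next_ck] == gen) {
        // sample one random individual
        int pick = (int)(unif_rand() * N);
        if (pick >= N) pick = N - 1;
        int acc = 0;
        for (Pop::const_iterator it = pop.begin(); it != pop.end(); ++it) {
          acc += it->second;
          if (pick < acc) { seqs(rep, next_ck) = geno_to_string(it->first); break; }
        }
        uniq(rep, next_ck) = (int)pop.size();
        ++next_ck;
      }
      if (gen == gmax) break;

      // selection: multinomial over unique genotypes, weight count * F
      // (a monomorphic population resamples to itself, so skip)
      const size_t k = pop.size();
      if (k > 1) {
      std::vector<const Geno*> gs(k);
      std::vector<double> w(k);
      size_t idx = 0;
      double wsum = 0.0;
      for (Pop::const_iterator it = pop.begin(); it != pop.end(); ++it, ++idx) {
        gs[idx] = &it->first;
        double F = geno_fitness(geno_energy(it->first, em), fit_type, p1, p2, p3);
        w[idx] = it->second * F;
        wsum += w[idx];
      }
      if (!(wsum > 0.0)) stop("total fitness weight is zero");
      Pop newpop;
      int remaining = N;
      double wrem = wsum;
      for (size_t i = 0; i < k && remaining > 0; ++i) {
        int ni;
        if (i + 1 == k) ni = remaining;
        else {
          double pr = w[i] / wrem;
          if (pr > 1.0) pr = 1.0;
          if (pr < 0.0) pr = 0.0;
          ni = (int)R::rbinom((double)remaining, pr);
        }
        if (ni > 0) newpop[*gs[i]] = ni;
        remaining -= ni;
        wrem -= w[i];
        if (wrem <= 0.0) wrem = 0.0;
      }
      pop.swap(newpop);
      }

      // mutation: binomial number of mutated (individual, position) slots,
      // distinct slots sampled by rejection
      if (mu > 0.0) {
        const double slots = (double)N * (double)L;
        int nmut = (int)R::rbinom(slots, mu);
        if (nmut > 0) {
          std::set<long> chosen;
          std::vector< std::pair<int,int> > muts;  // (individual, position)
          while ((int)chosen.size() < nmut) {
            long s = (long)(unif_rand() * slots);
            if (s >= (long)slots) s = (long)slots - 1;
            if (chosen.insert(s).second)
              muts.push_back(std::make_pair((int)(s / L), (int)(s % L)));
          }
          // group mutations by individual (ordering by current pop layout)
          std::map<int, std::vector<int> > by_ind;
          for (size_t i = 0; i < muts.size(); ++i)
            by_ind[muts[i].first].push_back(muts[i].second);
          // snapshot cumulative layout before applying changes
          std::vector<Geno> order_g;
          std::vector<int> order_cum;
          int acc = 0;
          for (Pop::const_iterator it = pop.begin(); it != pop.end(); ++it) {
            acc += it->second;
            order_g.push_back(it->first);
            order_cum.push_back(acc);
          }
          for (std::map<int, std::vector<int> >::iterator mi = by_ind.begin();
               mi != by_ind.end(); ++mi) {
            int ind = mi->first;
            size_t gi = 0;
            while (gi < order_cum.size() && ind >= order_cum[gi]) ++gi;
            Geno g = order_g[gi];
            for (size_t q = 0; q < mi->second.size(); ++q) {
              int posn = mi->second[q];
              int shift = 1 + (int)(unif_rand() * 3.0);
              if (shift > 3) shift = 3;
              g[posn] = (unsigned char)((g[posn] + shift) % 4);
            }
            // move one individual from old genotype to mutant
            Pop::iterator oldit = pop.find(order_g[gi]);
            if (oldit != pop.end()) {
              if (--(oldit->second) == 0) pop.erase(oldit);
              pop[g] += 1;
            }
          }
        }
      }
    }
  }
  return List::create(_["sequences"] = seqs, _["unique_counts"] = uniq);
}

// Permutation test core: two-sided p-value for a difference statistic
// (0 = mean difference, 1 = variance difference) between two groups under
// label permutation preserving group sizes.  Uses R's RNG.
// [[Rcpp::export]]
List perm_group_test_cpp(NumericVector values, IntegerVector group,
                         int stat_type, int n_perm) {
  const int n = values.size();
  int n1 = 0;
  for (int i = 0; i < n; ++i) if (group[i] == 1) ++n1;
  const int n2 = n - n1;
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty");

  double tot = 0.0, tot2 = 0.0;
  for (int i = 0; i < n; ++i) { tot += values[i]; tot2 += values[i] * values[i]; }

  // observed statistic
  double s1 = 0.0, s1sq = 0.0;
  for (int i = 0; i < n; ++i)
    if (group[i] == 1) { s1 += values[i]; s1sq += values[i] * values[i]; }
  double obs;
  if (stat_type == 0) {
    obs = s1 / n1 - (tot - s1) / n2;
  } else {
    double m1 = s1 / n1, m2 = (tot - s1) / n2;
    double v1 = (n1 > 1) ? (s1sq - n1 * m1 * m1) / (n1 - 1) : 0.0;
    double v2 = (n2 > 1) ? ((tot2 - s1sq) - n2 * m2 * m2) / (n2 - 1) : 0.0;
    obs = v1 - v2;
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int count = 0;
  for (int p = 0; p < n_perm; ++p) {
    // partial Fisher-Yates: first n1 entries are the permuted group 1
    for (int i = 0; i < n1; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    double ps1 = 0.0, ps1sq = 0.0;
    for (int i = 0; i < n1; ++i) {
      ps1 += values[idx[i]];
      ps1sq += values[idx[i]] * values[idx[i]];
    }
    double st;
    if (stat_type == 0) {
      st = ps1 / n1 - (tot - ps1) / n2;
    } else {
      double m1 = ps1 / n1, m2 = (tot - ps1) / n2;
      double v1 = (n1 > 1) ? (ps1sq - n1 * m1 * m1) / (n1 - 1) : 0.0;
      double v2 = (n2 > 1) ? ((tot2 - ps1sq) - n2 * m2 * m2) / (n2 - 1) : 0.0;
      st = v1 - v2;
    }
    if (std::fabs(st) >= std::fabs(obs) - 1e-12) ++count;
  }
  return List::create(_["statistic"] = obs,
                      _["p_value"] = (count + 1.0) / (n_perm + 1.0));
}
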