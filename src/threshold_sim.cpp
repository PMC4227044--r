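// Fast Monte-Carlo simulation of the commitment task played by a
// deterministic threshold agent on the current-minus-average decision
// variable. Mirrors the R reference simulator (run_block +
// threshold_policy + dv_config("average", integration = TRUE)); used for
// large behavioural simulations and criterion sweeps where millions of
// blocks are required. Each block owns its RNG stream (seeded from the
// master seed and the block index) so sweeps over the criterion reuse
// common random numbers.
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

struct BlockResult {
  int n_trials;
  int n_commits;
  int first_commit; // 0 = none
  double yield;     // rounded block-end yield
};

// payoffs for ranks 1..4 in pounds per trial
const double PAYOFF[4] = {-15.0 / 24, -5.0 / 24, 5.0 / 24, 15.0 / 24};

inline double round_half(double x) {
  double s = x < 0 ? -1.0 : 1.0;
  return s * std::floor(std::fabs(x) * 2.0 + 0.5) / 2.0;
}

inline std::uint64_t block_seed(std::uint64_t seed, std::uint64_t idx) {
  // splitmix64 over (seed, block index): well-spread per-block streams
  std::uint64_t z = seed + 0x9E3779B97F4A7C15ULL * (idx + 1);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// one block under the threshold agent; rule_out = false means rule-in
BlockResult play_block(bool rule_out, double theta, int context,
                       int max_trials, double v_prior,
                       std::uint64_t seed) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  std::uniform_int_distribution<int> pick4(0, 3);

  // means of ranks 1..4 for context 0/1/2 (short/medium/long)
  double means[4], sds[4] = {0.5, 0.5, 1.0, 1.0};
  for (int r = 0; r < 4; ++r) means[r] = 2.5 + 0.5 * (context + r);
  // shuffle sd assignment to ranks (Fisher-Yates)
  for (int i = 3; i > 0; --i) {
    std::uniform_int_distribution<int> u(0, i);
    std::swap(sds[i], sds[u(rng)]);
  }
  // bandit identity is irrelevant to the agent: work in rank space

  bool active[4] = {true, true, true, true};
  int n_active = 4;
  double vbar[4];
  int nobs[4] = {0, 0, 0, 0};
  BlockResult res = {0, 0, 0, 0.0};
  double yield_sum = 0.0, pool_payoff = 0.0;
  int n_committed = 0;

  for (int t = 1; t <= max_trials && n_active > 0; ++t) {
    // uniform offer among active ranks
    int offer;
    if (n_active == 1) {
      for (offer = 0; !active[offer]; ++offer) {}
    } else {
      do { offer = pick4(rng); } while (!active[offer]);
    }
    // spiral length, redrawn while non-positive
    double s;
    do { s = means[offer] + sds[offer] * norm(rng); } while (s <= 0.0);
    // running average including the current sample
    if (nobs[offer] == 0) {
      vbar[offer] = s;
    } else {
      vbar[offer] += (s - vbar[offer]) / (nobs[offer] + 1);
    }
    ++nobs[offer];
    // current-minus-average DV: reference is v_prior on trial 1, then
    // the mean running average over all presented bandits
    double r;
    if (t == 1) {
      r = v_prior;
    } else {
      double sum = 0.0;
      int n_pres = 0;
      for (int j = 0; j < 4; ++j) {
        if (nobs[j] > 0) { sum += vbar[j]; ++n_pres; }
      }
      r = sum / n_pres;
    }
    double dv = vbar[offer] - r;
    bool commit = rule_out ? (dv <= theta) : (dv >= theta);
    if (commit) {
      active[offer] = false;
      --n_active;
      pool_payoff += PAYOFF[offer];
      ++n_committed;
      ++res.n_commits;
      if (res.first_commit == 0) res.first_commit = t;
    }
    // per-trial yield after the decision
    double y;
    if (rule_out) {
      y = (n_active == 0) ? 0.0 : -pool_payoff / n_active;
      // complement of OUT: total payoff is 0, so pool = -sum(OUT)
    } else {
      y = (n_committed == 0) ? 0.0 : pool_payoff / n_committed;
    }
    yield_sum += y;
    res.n_trials = t;
  }
  res.yield = round_half(yield_sum);
  return res;
}

} // namespace

// [[Rcpp::export(name = ".simulate_threshold_blocks_cpp")]]
DataFrame simulate_threshold_blocks_cpp(int n_blocks, bool rule_out,
                                        double theta,
                                        IntegerVector context,
                                        int max_trials, double v_prior,
                                        double seed) {
  if (context.size() != n_blocks) stop("context must have length n_blocks");
  IntegerVector n_trials(n_blocks), n_commits(n_blocks),
      first_commit(n_blocks);
  NumericVector yield(n_blocks);
  std::uint64_t s0 = (std::uint64_t)seed;
  for (int b = 0; b < n_blocks; ++b) {
    BlockResult r = play_block(rule_out, theta, context[b], max_trials,
                               v_prior, block_seed(s0, b));
    n_trials[b] = r.n_trials;
    n_commits[b] = r.n_commits;
    first_commit[b] = r.first_commit == 0 ? NA_INTEGER : r.first_commit;
    yield[b] = r.yield;
  }
  return DataFrame::create(
      _["context"] = context, _["n_trials"] = n_trials,
      _["n_commits"] = n_commits, _["first_commit"] = first_commit,
      _["yield"] = yield);
}

// [[Rcpp::export(name = ".sweep_threshold_cpp")]]
DataFrame sweep_threshold_cpp(NumericVector theta_grid, bool rule_out,
                              int n_blocks, IntegerVector context,
                              int max_trials, double v_prior,
                              double seed) {
  if (context.size() != n_blocks) stop("context must have length n_blocks");
  int G = theta_grid.size();
  NumericVector mean_yield(G), se(G);
  std::uint64_t s0 = (std::uint64_t)seed;
  for (int g = 0; g < G; ++g) {
    double sum = 0.0, sumsq = 0.0;
    for (int b = 0; b < n_blocks; ++b) {
      // identical per-block seeds across grid points: common random
      // numbers, so adjacent criteria see the same stimulus streams
      BlockResult r = play_block(rule_out, theta_grid[g], context[b],
                                 max_trials, v_prior, block_seed(s0, b));
      sum += r.yield;
      sumsq += r.yield * r.yield;
    }
    double m = sum / n_blocks;
    mean_yield[g] = m;
    double var = (sumsq - n_blocks * m * m) / (n_blocks - 1.0);
    se[g] = std::sqrt(var / n_blocks);
  }
  return DataFrame::create(_["theta"] = theta_grid,
                           _["mean_yield"] = mean_yield, _["se"] = se);
}
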