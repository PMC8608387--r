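// Exact stochastic simulation (direct-method SSA) of the gene-expression
// networks M1-M4 and the multiscale three-state model (MS3), with optional
// delayed maturation (fixed or Erlang delay handled by an event queue
// interleaved with SSA steps) and cell-cycle features (replication with
// dosage compensation, binomial partitioning at division, Erlang phase
// lengths).
//
// Parameter column order (contract with the R side):
//   0 lambda, 1 mu, 2 lambda2, 3 KN, 4 KM, 5 KP, 6 deltaM, 7 deltaP
// Networks: 1 = M1, 2 = M2, 3 = M3, 4 = M4, 5 = MS3.
// Gene-state coding: M1/M2 fixed at 1 (always active); M3/M4: 0 inactive,
// 1 active; MS3: 0 = S0, 1 = S10, 2 = S11.
//
// All randomness comes from R's RNG (unif_rand / exp_rand), so results are
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Net {
  int network;
  bool track_protein;
  int mat_mode;      // 0 first-order rate, 1 fixed delay, 2 Erlang delay
  double mat_p1;     // fixed: delay; erlang: shape
  double mat_p2;     // erlang: rate
};

struct Cell {
  int gene[2];
  int ncopies;
  long N, M, P;
  double lam1_eff;
  std::priority_queue<double, std::vector<double>, std::greater<double> > pend;
};

inline bool has_nascent(int network) {
  return network == 1 || network == 4 || network == 5;
}

inline double erlang_draw(int shape, double rate) {
  double d = 0.0;
  for (int i = 0; i < shape; ++i) d += R::exp_rand() / rate;
  return d;
}

inline double maturation_delay(const Net& net) {
  if (net.mat_mode == 1) return net.mat_p1;
  return erlang_draw((int)net.mat_p1, net.mat_p2);
}

void init_cell(Cell& cell, int network, double lambda) {
  cell.gene[0] = (network <= 2) ? 1 : 0;
  cell.gene[1] = 0;
  cell.ncopies = 1;
  cell.N = cell.M = cell.P = 0;
  cell.lam1_eff = lambda;
  while (!cell.pend.empty()) cell.pend.pop();
}

// Advance one cell from absolute time t0 to t1 (exclusive of events at t1).
void simulate_interval(Cell& cell, const double* p, const Net& net,
                       double t0, double t1) {
  const double lambda2 = p[2], KN = p[3], KM = p[4], KP = p[5];
  const double dM = p[6], dP = p[7], mu = p[1];
  const double INF = std::numeric_limits<double>::infinity();

  double a[16];
  int code[16], cpy[16];
  double t = t0;

  for (;;) {
    int na = 0;
    double a0 = 0.0;
    // gene-state and synthesis channels, per gene copy
    for (int c = 0; c < cell.ncopies; ++c) {
      int g = cell.gene[c];
      switch (net.network) {
      case 1:  // M1: constitutive, nascent synthesis
        a[na] = KN; code[na] = 1; cpy[na] = c; a0 += a[na]; ++na;
        break;
      case 2:  // M2: constitutive, mRNA synthesis
        a[na] = KN; code[na] = 2; cpy[na] = c; a0 += a[na]; ++na;
        break;
      case 3:  // M3: two-state promoter, mRNA synthesis when active
        if (g == 0) { a[na] = cell.lam1_eff; code[na] = 7; }
        else        { a[na] = mu;            code[na] = 8; }
        cpy[na] = c; a0 += a[na]; ++na;
        if (g == 1) { a[na] = KN; code[na] = 2; cpy[na] = c; a0 += a[na]; ++na; }
        break;
      case 4:  // M4: two-state promoter, nascent synthesis when active
        if (g == 0) { a[na] = cell.lam1_eff; code[na] = 7; }
        else        { a[na] = mu;            code[na] = 8; }
        cpy[na] = c; a0 += a[na]; ++na;
        if (g == 1) { a[na] = KN; code[na] = 1; cpy[na] = c; a0 += a[na]; ++na; }
        break;
      case 5:  // MS3: S0 -> S10 (lambda1); S10 -> S0 (mu1), S10 -> S11
               // (lambda2); S11 -> S0 (mu1), S11 -> S10 + nascent (KN)
        if (g == 0) {
          a[na] = cell.lam1_eff; code[na] = 7; cpy[na] = c; a0 += a[na]; ++na;
        } else if (g == 1) {
          a[na] = mu;      code[na] = 8;  cpy[na] = c; a0 += a[na]; ++na;
          a[na] = lambda2; code[na] = 9;  cpy[na] = c; a0 += a[na]; ++na;
        } else {
          a[na] = mu; code[na] = 10; cpy[na] = c; a0 += a[na]; ++na;
          a[na] = KN; code[na] = 1;  cpy[na] = c; a0 += a[na]; ++na;
        }
        break;
      }
    }
    if (has_nascent(net.network) && net.mat_mode == 0 && cell.N > 0) {
      a[na] = KM * cell.N; code[na] = 3; a0 += a[na]; ++na;
    }
    if (cell.M > 0) {
      a[na] = dM * cell.M; code[na] = 4; a0 += a[na]; ++na;
    }
    if (net.track_protein) {
      if (cell.M > 0) { a[na] = KP * cell.M; code[na] = 5; a0 += a[na]; ++na; }
      if (cell.P > 0) { a[na] = dP * cell.P; code[na] = 6; a0 += a[na]; ++na; }
    }

    double tnext = cell.pend.empty() ? INF : cell.pend.top();
    double dt = (a0 > 0.0) ? R::exp_rand() / a0 : INF;
    double tcand = t + dt;

    if (tnext < t1 && tnext <= tcand) {  // scheduled maturation fires first
      t = tnext;
      cell.pend.pop();
      --cell.N; ++cell.M;
      continue;
    }
    if (!(tcand < t1)) break;  // beyond interval, or absorbing state
    t = tcand;

    double u = unif_rand() * a0;
    int k = 0;
    double acc = a[0];
    while (u > acc && k + 1 < na) acc += a[++k];
    switch (code[k]) {
    case 1:  // nascent synthesis
      ++cell.N;
      if (net.mat_mode > 0) cell.pend.push(t + maturation_delay(net));
      if (net.network == 5) cell.gene[cpy[k]] = 1;  // S11 -> S10
      break;
    case 2: ++cell.M; break;                    // mRNA synthesis
    case 3: --cell.N; ++cell.M; break;          // first-order maturation
    case 4: --cell.M; break;                    // mRNA decay
    case 5: ++cell.P; break;                    // translation
    case 6: --cell.P; break;                    // protein decay
    case 7: cell.gene[cpy[k]] = 1; break;       // activation
    case 8: cell.gene[cpy[k]] = 0; break;       // inactivation
    case 9: cell.gene[cpy[k]] = 2; break;       // S10 -> S11
    case 10: cell.gene[cpy[k]] = 0; break;      // S11 -> S0
    }
  }
}

inline long binom_half(long n) {
  if (n <= 0) return 0;
  return (long)R::rbinom((double)n, 0.5);
}

void divide_cell(Cell& cell, const Net& net, double lambda) {
  // binomial partitioning; one daughter followed
  if (net.mat_mode > 0) {
    std::vector<double> keep;
    while (!cell.pend.empty()) {
      if (unif_rand() < 0.5) keep.push_back(cell.pend.top());
      cell.pend.pop();
    }
    for (size_t i = 0; i < keep.size(); ++i) cell.pend.push(keep[i]);
    cell.N = (long)keep.size();
  } else {
    cell.N = binom_half(cell.N);
  }
  cell.M = binom_half(cell.M);
  cell.P = binom_half(cell.P);
  int kept = (unif_rand() < 0.5) ? 0 : 1;
  cell.gene[0] = cell.gene[kept];
  cell.gene[1] = 0;
  cell.ncopies = 1;
  cell.lam1_eff = lambda;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix ssa_population_cpp(int network, NumericMatrix pars,
                                 NumericVector t_end, bool track_protein,
                                 int mat_mode, double mat_p1, double mat_p2,
                                 int n_reporters) {
  const int n_cells = pars.nrow();
  Net net; net.network = network; net.track_protein = track_protein;
  net.mat_mode = mat_mode; net.mat_p1 = mat_p1; net.mat_p2 = mat_p2;
  IntegerMatrix out(n_cells, 4 * n_reporters);
  std::vector<double> p(8);
  Cell cell;
  for (int i = 0; i < n_cells; ++i) {
    for (int j = 0; j < 8; ++j) p[j] = pars(i, j);
    for (int r = 0; r < n_reporters; ++r) {
      init_cell(cell, network, p[0]);
      simulate_interval(cell, p.data(), net, 0.0, t_end[i]);
      out(i, 4 * r + 0) = (int)cell.N;
      out(i, 4 * r + 1) = (int)cell.M;
      out(i, 4 * r + 2) = (int)cell.P;
      out(i, 4 * r + 3) = cell.gene[0];
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix ssa_cellcycle_cpp(int network, NumericMatrix pars,
                                int n_cycles, double cycle_rate,
                                int repl_shape, int div_shape, double dosage,
                                bool track_protein, int mat_mode,
                                double mat_p1, double mat_p2,
                                int n_reporters) {
  const int n_cells = pars.nrow();
  Net net; net.network = network; net.track_protein = track_protein;
  net.mat_mode = mat_mode; net.mat_p1 = mat_p1; net.mat_p2 = mat_p2;
  IntegerMatrix out(n_cells, 4 * n_reporters);
  std::vector<double> p(8), tr(n_cycles), td(n_cycles);
  Cell cell;
  for (int i = 0; i < n_cells; ++i) {
    for (int j = 0; j < 8; ++j) p[j] = pars(i, j);
    // cycle schedule and sampling fraction, shared between reporters
    for (int k = 0; k < n_cycles; ++k) {
      tr[k] = erlang_draw(repl_shape, cycle_rate);
      td[k] = erlang_draw(div_shape, cycle_rate);
    }
    double u = unif_rand();
    for (int r = 0; r < n_reporters; ++r) {
      init_cell(cell, network, p[0]);
      double t = 0.0;
      for (int k = 0; k < n_cycles; ++k) {
        double Tc = tr[k] + td[k];
        bool last = (k == n_cycles - 1);
        double tstop = last ? t + u * Tc : t + Tc;
        double trep = t + tr[k];
        simulate_interval(cell, p.data(), net, t, std::min(trep, tstop));
        if (tstop <= trep) break;
        // replication: gene copies double, inheriting the promoter state;
        // dosage compensation scales the activation rate
        cell.gene[1] = cell.gene[0];
        cell.ncopies = 2;
        cell.lam1_eff = dosage * p[0];
        simulate_interval(cell, p.data(), net, trep, tstop);
        if (last) break;
        divide_cell(cell, net, p[0]);
        t += Tc;
      }
      out(i, 4 * r + 0) = (int)cell.N;
      out(i, 4 * r + 1) = (int)cell.M;
      out(i, 4 * r + 2) = (int)cell.P;
      out(i, 4 * r + 3) = cell.gene[0];
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
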