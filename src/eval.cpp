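// Compiled inner loops for task evaluation.  Desk-scale evolution needs on
// the order of 10^6 brain evaluations (population x generations x
// replicates), each of which replays a full set of lifetimes; these loops
// mirror the interpreted R reference implementations exactly (the tests
// assert bit-identical recordings).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Brain {
  bool markov;
  int n_input, n_output, n_memory, n_t0, n_t1;
  std::vector<int> nin, nout, ins, outs, tab;     // markov, flattened
  std::vector<int> ins_off, outs_off, tab_off;
  std::vector<double> W, bias;                    // rnn, row-major W
};

Brain make_brain(const List& bl) {
  Brain b;
  std::string type = as<std::string>(bl["type"]);
  b.markov = (type == "markov");
  b.n_input = as<int>(bl["n_input"]);
  b.n_output = as<int>(bl["n_output"]);
  b.n_memory = as<int>(bl["n_memory"]);
  b.n_t0 = b.n_input + b.n_memory;
  b.n_t1 = b.n_output + b.n_memory;
  if (b.markov) {
    b.nin = as<std::vector<int>>(bl["gate_nin"]);
    b.nout = as<std::vector<int>>(bl["gate_nout"]);
    b.ins = as<std::vector<int>>(bl["gate_ins"]);
    b.outs = as<std::vector<int>>(bl["gate_outs"]);
    b.tab = as<std::vector<int>>(bl["gate_tab"]);
    int io = 0, oo = 0, to = 0;
    for (size_t g = 0; g < b.nin.size(); ++g) {
      b.ins_off.push_back(io);  io += b.nin[g];
      b.outs_off.push_back(oo); oo += b.nout[g];
      b.tab_off.push_back(to);  to += (1 << b.nin[g]) * b.nout[g];
    }
  } else {
    NumericMatrix W = bl["W"];
    b.W.assign(W.begin(), W.end());               // column-major, n_t1 rows
    b.bias = as<std::vector<double>>(bl["b"]);
  }
  return b;
}

inline void brain_step(const Brain& b, const std::vector<int>& t0,
                       std::vector<int>& t1) {
  std::fill(t1.begin(), t1.end(), 0);
  if (b.markov) {
    for (size_t g = 0; g < b.nin.size(); ++g) {
      int r = 0;
      for (int j = 0; j < b.nin[g]; ++j)
        r |= t0[b.ins[b.ins_off[g] + j]] << j;    // first input = LSB
      int toff = b.tab_off[g] + r * b.nout[g];
      for (int j = 0; j < b.nout[g]; ++j)
        t1[b.outs[b.outs_off[g] + j]] |= b.tab[toff + j];
    }
  } else {
    for (int i = 0; i < b.n_t1; ++i) {
      double s = b.bias[i];
      for (int j = 0; j < b.n_t0; ++j)
        s += b.W[i + (size_t)j * b.n_t1] * t0[j];
      t1[i] = std::tanh(s) > 0 ? 1 : 0;           // discretize: <=0 -> 0
    }
  }
}

}  // namespace

// n-Back: one input bit per update; outputs must echo the input at the
// configured delays; the first `warmup` updates of each lifetime are
// neither scored nor recorded.
// [[Rcpp::export(name = ".cpp_run_nback")]]
List cpp_run_nback(List brain, IntegerMatrix bits, IntegerVector delays,
                   int warmup, bool record) {
  Brain b = make_brain(brain);
  if (b.n_input != 1 || b.n_output != delays.size())
    stop("brain layout does not match the n-Back configuration");
  int n_life = bits.nrow(), L = bits.ncol();
  int scored = L - warmup;
  long correct = 0, total = 0;
  int nrec = record ? n_life * scored : 0;
  IntegerVector r_life(nrec), r_upd(nrec);
  IntegerMatrix r_in(nrec, 1), r_out(nrec, b.n_output),
      r_mb(nrec, b.n_memory), r_ma(nrec, b.n_memory);
  std::vector<int> t0(b.n_t0), t1(b.n_t1);
  int row = 0;
  for (int lt = 0; lt < n_life; ++lt) {
    std::vector<int> mem(b.n_memory, 0);
    for (int u = 0; u < L; ++u) {
      t0[0] = bits(lt, u);
      for (int m = 0; m < b.n_memory; ++m) t0[1 + m] = mem[m];
      brain_step(b, t0, t1);
      if (u >= warmup) {
        for (int k = 0; k < delays.size(); ++k) {
          total++;
          if (t1[k] == bits(lt, u - delays[k])) correct++;
        }
        if (record) {
          r_life[row] = lt + 1;
          r_upd[row] = u + 1;
          r_in(row, 0) = bits(lt, u);
          for (int k = 0; k < b.n_output; ++k) r_out(row, k) = t1[k];
          for (int m = 0; m < b.n_memory; ++m) {
            r_mb(row, m) = mem[m];
            r_ma(row, m) = t1[b.n_output + m];
          }
          row++;
        }
      }
      for (int m = 0; m < b.n_memory; ++m) mem[m] = t1[b.n_output + m];
    }
  }
  List out = List::create(
      _["fitness"] = (double)correct / (double)total);
  if (record) {
    out["lifetime"] = r_life; out["update"] = r_upd;
    out["input"] = r_in; out["output"] = r_out;
    out["mem_before"] = r_mb; out["mem_after"] = r_ma;
  }
  return out;
}

// Block Catch: 120 lifetimes (sizes {2,3,4} x directions {left,right} x 20
// start columns) of `updates` steps in a `width`-column world with lateral
// wraparound.  Per update: read sensors, brain step, move paddle, then the
// block shifts laterally one unit (and descends).  Catch iff any block
// column overlaps the paddle body at landing; catch is correct for size-2
// blocks and right-moving size-3 blocks, avoid for the rest.
// [[Rcpp::export(name = ".cpp_run_blockcatch")]]
List cpp_run_blockcatch(List brain, int width, int updates, bool record) {
  Brain b = make_brain(brain);
  if (b.n_input != 4 || b.n_output != 2)
    stop("brain layout does not match the Block Catch configuration");
  const int sizes[3] = {2, 3, 4};
  const int dirs[2] = {-1, +1};                   // left, right
  const int sensor_off[4] = {0, 1, 4, 5};         // S S _ _ S S
  const int body = 6;                             // paddle = sensor span
  int n_life = 3 * 2 * width;
  int nrec = record ? n_life * updates : 0;
  IntegerVector r_life(nrec), r_upd(nrec);
  IntegerMatrix r_in(nrec, 4), r_out(nrec, 2),
      r_mb(nrec, b.n_memory), r_ma(nrec, b.n_memory), r_world(nrec, 10);
  IntegerVector life_correct(n_life);
  std::vector<int> t0(b.n_t0), t1(b.n_t1);
  long n_correct = 0;
  int lt = 0, row = 0;
  for (int si = 0; si < 3; ++si) {
    for (int di = 0; di < 2; ++di) {
      int size = sizes[si], dir = dirs[di];
      bool should_catch = (size == 2) || (size == 3 && dir == +1);
      int world[10] = {should_catch ? 1 : 0, dir == -1 ? 1 : 0,
                       0, size == 2, size == 3, size == 4,
                       (dir == -1) && should_catch,
                       (dir == -1) && !should_catch,
                       (dir == +1) && should_catch,
                       (dir == +1) && !should_catch};
      for (int start = 0; start < width; ++start, ++lt) {
        int block = start;                        // left edge of the block
        int pad = 0;                              // left edge of the paddle
        std::vector<int> mem(b.n_memory, 0);
        for (int u = 0; u < updates; ++u) {
          int sensors[4];
          for (int s = 0; s < 4; ++s) {
            int col = (pad + sensor_off[s]) % width;
            sensors[s] = 0;
            for (int k = 0; k < size; ++k)
              if ((block + k) % width == col) { sensors[s] = 1; break; }
          }
          for (int s = 0; s < 4; ++s) t0[s] = sensors[s];
          for (int m = 0; m < b.n_memory; ++m) t0[4 + m] = mem[m];
          brain_step(b, t0, t1);
          if (t1[0] == 1 && t1[1] == 0) pad = (pad - 1 + width) % width;
          else if (t1[0] == 0 && t1[1] == 1) pad = (pad + 1) % width;
          if (record) {
            r_life[row] = lt + 1;
            r_upd[row] = u + 1;
            for (int s = 0; s < 4; ++s) r_in(row, s) = sensors[s];
            r_out(row, 0) = t1[0]; r_out(row, 1) = t1[1];
            for (int m = 0; m < b.n_memory; ++m) {
              r_mb(row, m) = mem[m];
              r_ma(row, m) = t1[2 + m];
            }
            for (int w = 0; w < 10; ++w) r_world(row, w) = world[w];
            row++;
          }
          for (int m = 0; m < b.n_memory; ++m) mem[m] = t1[2 + m];
          block = (block + dir + width) % width;  // block falls + drifts
        }
        bool caught = false;
        for (int k = 0; k < size && !caught; ++k) {
          int col = (block + k) % width;
          for (int p = 0; p < body; ++p)
            if ((pad + p) % width == col) { caught = true; break; }
        }
        bool ok = (caught == should_catch);
        life_correct[lt] = ok ? 1 : 0;
        if (ok) n_correct++;
      }
    }
  }
  List out = List::create(
      _["fitness"] = (double)n_correct / (double)n_life,
      _["life_correct"] = life_correct);
  if (record) {
    out["lifetime"] = r_life; out["update"] = r_upd;
    out["input"] = r_in; out["output"] = r_out;
    out["mem_before"] = r_mb; out["mem_after"] = r_ma;
    out["world"] = r_world;
  }
  return out;
}
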