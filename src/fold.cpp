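#include <Rcpp.h>
#include <array>
#include <vector>
#include <string>
using namespace Rcpp;

// Nussinov-style base-pair maximization over Watson-Crick + GU wobble pairs
// with a minimum hairpin loop of 3 nt. Primary objective: number of base
// pairs; secondary objective: number of stacked pairs, i.e. pairs (i,j) whose
// inner neighbour (i+1,j-1) is also paired. Traceback is deterministic
// (outer pair first, then smallest partner index), so identical input always
// yields an identical dot-bracket.

static const int MINLOOP = 3;

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'G': return b == 'C' || b == 'U';
  case 'C': return b == 'G';
  case 'A': return b == 'U';
  case 'U': return b == 'A' || b == 'G';
  default:  return false;
  }
}

struct Val { int pairs; int stacks; };

static inline bool better(const Val &a, const Val &b) {
  return a.pairs > b.pairs || (a.pairs == b.pairs && a.stacks > b.stacks);
}
static inline bool equalv(const Val &a, const Val &b) {
  return a.pairs == b.pairs && a.stacks == b.stacks;
}

class FoldDP {
public:
  int n;
  std::string s;
  // flattened n*n tables; pair_valid flags whether (i,j) can close a helix
  std::vector<Val> vfree, vnof, vpair;
  std::vector<char> pair_valid;

  FoldDP(const std::string &seq) : n((int)seq.size()), s(seq) {
    Val z = {0, 0};
    vfree.assign((size_t)n * n, z);
    vnof.assign((size_t)n * n, z);
    vpair.assign((size_t)n * n, z);
    pair_valid.assign((size_t)n * n, 0);
    fill();
  }

  inline size_t idx(int i, int j) const { return (size_t)i * n + j; }
  inline Val F(int i, int j) const {  // empty interval => zero
    if (i > j) { Val z = {0, 0}; return z; }
    return vfree[idx(i, j)];
  }

  void fill() {
    for (int L = MINLOOP + 1; L < n; ++L) {       // span j - i
      for (int i = 0; i + L < n; ++i) {
        int j = i + L;
        // --- (i,j) paired together ---
        if (can_pair(s[i], s[j])) {
          Val best = {-1, -1};
          // interior without the (i+1,j-1) mutual pair
          Val b = vnof[idx(i + 1, j - 1)];
          Val cand = {b.pairs + 1, b.stacks};
          if (better(cand, best)) best = cand;
          // stacked continuation
          if (j - 1 - (i + 1) > MINLOOP && pair_valid[idx(i + 1, j - 1)]) {
            Val p = vpair[idx(i + 1, j - 1)];
            Val cand2 = {p.pairs + 1, p.stacks + 1};
            if (better(cand2, best)) best = cand2;
          }
          vpair[idx(i, j)] = best;
          pair_valid[idx(i, j)] = 1;
        }
        // --- (i,j) not paired to each other ---
        Val best = F(i + 1, j);                    // i unpaired
        for (int k = i + MINLOOP + 1; k < j; ++k) {
          if (!pair_valid[idx(i, k)]) continue;
          Val p = vpair[idx(i, k)];
          Val r = F(k + 1, j);
          Val cand = {p.pairs + r.pairs, p.stacks + r.stacks};
          if (better(cand, best)) best = cand;
        }
        vnof[idx(i, j)] = best;
        // --- unconstrained ---
        Val bf = best;
        if (pair_valid[idx(i, j)] && better(vpair[idx(i, j)], bf))
          bf = vpair[idx(i, j)];
        vfree[idx(i, j)] = bf;
      }
    }
  }

  // traceback states: 0 = free, 1 = nof, 2 = pair
  void traceback(std::vector<int> &partner) {
    partner.assign(n, -1);
    std::vector<std::array<int, 3>> stack;
    if (n > MINLOOP + 1) stack.push_back({0, n - 1, 0});
    while (!stack.empty()) {
      auto st = stack.back(); stack.pop_back();
      int i = st[0], j = st[1], state = st[2];
      if (i >= j || j - i <= MINLOOP) continue;
      if (state == 0) {
        if (pair_valid[idx(i, j)] && equalv(vpair[idx(i, j)], vfree[idx(i, j)])) {
          stack.push_back({i, j, 2});
        } else {
          stack.push_back({i, j, 1});
        }
      } else if (state == 1) {
        Val target = vnof[idx(i, j)];
        bool done = false;
        for (int k = i + MINLOOP + 1; k < j && !done; ++k) {
          if (!pair_valid[idx(i, k)]) continue;
          Val p = vpair[idx(i, k)];
          Val r = F(k + 1, j);
          Val cand = {p.pairs + r.pairs, p.stacks + r.stacks};
          if (equalv(cand, target)) {
            stack.push_back({i, k, 2});
            if (k + 1 < j) stack.push_back({k + 1, j, 0});
            done = true;
          }
        }
        if (!done) stack.push_back({i + 1, j, 0}); // i unpaired
      } else {
        partner[i] = j; partner[j] = i;
        Val target = vpair[idx(i, j)];
        // prefer the stacked continuation when it attains the optimum
        if (j - 1 - (i + 1) > MINLOOP && pair_valid[idx(i + 1, j - 1)]) {
          Val p = vpair[idx(i + 1, j - 1)];
          Val cand = {p.pairs + 1, p.stacks + 1};
          if (equalv(cand, target)) {
            stack.push_back({i + 1, j - 1, 2});
            continue;
          }
        }
        stack.push_back({i + 1, j - 1, 1});
      }
    }
  }
};

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold_cpp(std::string seq) {
  int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("invalid character '%s' in RNA sequence", std::string(1, c).c_str());
  }
  std::vector<int> partner(n, -1);
  int npairs = 0, nstacks = 0;
  if (n > MINLOOP + 1) {
    FoldDP dp(seq);
    Val top = dp.F(0, n - 1);
    npairs = top.pairs; nstacks = top.stacks;
    dp.traceback(partner);
  }
  std::string db(n, '.');
  IntegerVector part(n);
  for (int i = 0; i < n; ++i) {
    if (partner[i] >= 0) db[i] = (partner[i] > i) ? '(' : ')';
    part[i] = partner[i] + 1;  // 1-based, 0 = unpaired
  }
  return List::create(_["dotbracket"] = db,
                      _["n_pairs"] = npairs,
                      _["n_stacks"] = nstacks,
                      _["partner"] = part);
}
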