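#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Operator codes, canonical order:
// 1 and, 2 or, 3 cond, 4 ncond, 5 bicond, 6 nbicond, 7 nand, 8 nor, 9 not
static inline uint32_t apply_binary(int op, uint32_t a, uint32_t b,
                                    uint32_t full) {
  switch (op) {
  case 1: return a & b;
  case 2: return a | b;
  case 3: return (~a & full) | b;
  case 4: return a & (~b & full);
  case 5: return ~(a ^ b) & full;
  case 6: return a ^ b;
  case 7: return ~(a & b) & full;
  case 8: return ~(a | b) & full;
  }
  return 0;
}

// Size-ordered dynamic program over truth tables.  F[1] holds the n
// literal tables; at size s every table reachable by applying a unary
// operator to a table of size s-1 or a binary operator to an ordered
// pair of tables with sizes summing to s-1 is considered, and a table's
// first (hence minimal) size is final.  Provenance of the first
// derivation is kept so a witness formula can be reconstructed; the
// iteration order (operators in canonical order, left size before right
// size, tables ascending within a size) makes the witness deterministic.
//
// lit_cost is the size charged per literal leaf: 1 for the node-count
// metric (size = operator applications + literal occurrences), 0 for the
// operator-count metric (size = operator applications only).
//
// [[Rcpp::export]]
List cpp_minimal_profile(IntegerVector ops, int n, int cap, int lit_cost) {
  const int nt = 1 << (1 << n);           // number of truth tables
  const uint32_t full = (uint32_t)(nt - 1);

  bool has_not = false;
  std::vector<int> binops;
  for (int i = 0; i < ops.size(); ++i) {
    if (ops[i] == 9) has_not = true; else binops.push_back(ops[i]);
  }

  std::vector<int> len(nt, -1), provOp(nt, 0), provL(nt, -1), provR(nt, -1);
  std::vector< std::vector<uint32_t> > bySize(cap + 1);

  // literal tables: property i true at assignment index k iff bit (n-i)
  // of (2^n-1-k) is set; mask bit for index k is (2^n-1-k)
  int assigned = 0;
  const int nobj = 1 << n;
  for (int i = 1; i <= n; ++i) {
    uint32_t mask = 0;
    for (int k = 0; k < nobj; ++k) {
      int enc = nobj - 1 - k;
      if (enc & (1 << (n - i))) mask |= (1u << enc);
    }
    if (len[mask] < 0) {
      len[mask] = lit_cost; provOp[mask] = -i;  // negative op = literal index
      bySize[lit_cost].push_back(mask);
      ++assigned;
    }
  }
  std::sort(bySize[lit_cost].begin(), bySize[lit_cost].end());

  int maxs = lit_cost;
  for (int s = lit_cost + 1; s <= cap && assigned < nt; ++s) {
    std::vector<uint32_t>& out = bySize[s];
    for (size_t oi = 0; oi < (size_t)ops.size() && assigned < nt; ++oi) {
      int op = ops[oi];
      if (op == 9) {
        if (s - 1 < lit_cost) continue;
        const std::vector<uint32_t>& src = bySize[s - 1];
        for (size_t ai = 0; ai < src.size(); ++ai) {
          uint32_t t = (~src[ai]) & full;
          if (len[t] < 0) {
            len[t] = s; provOp[t] = 9; provL[t] = (int)src[ai];
            out.push_back(t);
            if (++assigned == nt) break;
          }
        }
      } else {
        for (int s1 = lit_cost; s1 <= s - 1 - lit_cost && assigned < nt; ++s1) {
          int s2 = s - 1 - s1;
          const std::vector<uint32_t>& A = bySize[s1];
          const std::vector<uint32_t>& B = bySize[s2];
          for (size_t ai = 0; ai < A.size() && assigned < nt; ++ai) {
            uint32_t a = A[ai];
            for (size_t bi = 0; bi < B.size(); ++bi) {
              uint32_t t = apply_binary(op, a, B[bi], full);
              if (len[t] < 0) {
                len[t] = s; provOp[t] = op;
                provL[t] = (int)a; provR[t] = (int)B[bi];
                out.push_back(t);
                if (++assigned == nt) break;
              }
            }
          }
        }
      }
    }
    std::sort(out.begin(), out.end());
    if (!out.empty()) maxs = s;
  }

  return List::create(_["lengths"] = IntegerVector(len.begin(), len.end()),
                      _["prov_op"] = IntegerVector(provOp.begin(), provOp.end()),
                      _["prov_left"] = IntegerVector(provL.begin(), provL.end()),
                      _["prov_right"] = IntegerVector(provR.begin(), provR.end()),
                      _["n_assigned"] = assigned,
                      _["max_size"] = maxs);
}
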