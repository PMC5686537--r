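#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <vector>
#include <climits>
using namespace Rcpp;

// Product symbols are coded 1..21 at the R level (20 residues in alphabetical
// order, then 21 = stop). Everything here works on 0-based copies.
static const int STOP = 20;

// Codon index: i = 16*b1 + 4*b2 + b3 with T=0, C=1, A=2, G=3 (canonical TCAG
// order, first position slowest). Each codon has 9 Hamming-1 neighbors.
static int NB[64][9];
static bool nb_ready = false;

static void init_nb() {
  if (nb_ready) return;
  for (int i = 0; i < 64; i++) {
    int b[3] = { i / 16, (i / 4) % 4, i % 4 };
    int m = 0;
    for (int pos = 0; pos < 3; pos++) {
      for (int alt = 0; alt < 4; alt++) {
        if (alt == b[pos]) continue;
        int j = 0, mult[3] = { 16, 4, 1 };
        for (int q = 0; q < 3; q++) j += (q == pos ? alt : b[q]) * mult[q];
        NB[i][m++] = j;
      }
    }
  }
  nb_ready = true;
}

// [[Rcpp::export(name = ".neighbor_index_core")]]
IntegerMatrix neighbor_index_core() {
  init_nb();
  IntegerMatrix out(64, 9);
  for (int i = 0; i < 64; i++)
    for (int j = 0; j < 9; j++) out(i, j) = NB[i][j] + 1;
  return out;
}

struct Metrics {
  double fu, fc, ratio, F;
  bool ratio_defined;
};

// cls: 21 class ids (0-based), cls[20] = the STOP pseudo-class.
// chem_distinct = false: calibrated accessibility-diversity rule — per sense
// codon, the number of unique non-stop products differing from its own
// product (one chemical-class instance per accessible amino acid; stop has
// no chemical class and stop codons contribute nothing as sources).
// chem_distinct = true: distinct classes among non-synonymous accessible
// products, stop counted as its own class.
static Metrics eval_metrics(const std::vector<int>& p, const int* cls,
                            bool chem_distinct) {
  Metrics m;
  double fu_sum = 0, fc_sum = 0;
  int tgt[21];
  bool enc[21];
  for (int i = 0; i < 21; i++) { tgt[i] = 0; enc[i] = false; }
  for (int k = 0; k < 64; k++) {
    enc[p[k]] = true;
    bool seen[21] = { false };
    bool seencls[32] = { false };
    int cnt = 0, cntns = 0, ccls = 0;
    for (int j = 0; j < 9; j++) {
      int q = p[NB[k][j]];
      if (q == p[k]) continue;
      if (!seen[q]) {
        seen[q] = true;
        cnt++;
        if (q != STOP) cntns++;
        if (!seencls[cls[q]]) { seencls[cls[q]] = true; ccls++; }
      }
      if (q != STOP && p[k] != STOP) tgt[q]++;
    }
    fu_sum += cnt;
    if (chem_distinct) fc_sum += ccls;
    else fc_sum += (p[k] == STOP) ? 0 : cntns;
  }
  int mn = INT_MAX, mx = 0;
  for (int i = 0; i < 20; i++)
    if (enc[i]) { if (tgt[i] < mn) mn = tgt[i]; if (tgt[i] > mx) mx = tgt[i]; }
  m.fu = fu_sum / 64.0;
  m.fc = fc_sum / 64.0;
  m.ratio_defined = (mx > 0);
  m.ratio = m.ratio_defined ? (double)mn / (double)mx : NA_REAL;
  m.F = m.ratio_defined ? (m.fu / 9.0) * m.ratio * (m.fc / 9.0) : NA_REAL;
  return m;
}

static std::vector<int> to0(const IntegerVector& prod) {
  std::vector<int> p(64);
  for (int k = 0; k < 64; k++) p[k] = prod[k] - 1;
  return p;
}

static std::vector<int> cls0(const IntegerVector& cls) {
  std::vector<int> c(21);
  for (int i = 0; i < 21; i++) c[i] = cls[i] - 1;
  return c;
}

// [[Rcpp::export(name = ".fitness_core")]]
NumericVector fitness_core(IntegerVector prod, IntegerVector cls,
                           bool chem_distinct) {
  init_nb();
  std::vector<int> p = to0(prod), c = cls0(cls);
  Metrics m = eval_metrics(p, c.data(), chem_distinct);
  return NumericVector::create(_["f_combined"] = m.F, _["f_unique"] = m.fu,
                               _["f_ratio"] = m.ratio, _["f_chem"] = m.fc);
}

// [[Rcpp::export(name = ".fitness_batch_core")]]
NumericMatrix fitness_batch_core(IntegerMatrix prods, IntegerVector cls,
                                 bool chem_distinct) {
  init_nb();
  std::vector<int> c = cls0(cls);
  int n = prods.ncol();
  NumericMatrix out(n, 4);
  std::vector<int> p(64);
  for (int i = 0; i < n; i++) {
    for (int k = 0; k < 64; k++) p[k] = prods(k, i) - 1;
    Metrics m = eval_metrics(p, c.data(), chem_distinct);
    out(i, 0) = m.F; out(i, 1) = m.fu; out(i, 2) = m.ratio; out(i, 3) = m.fc;
  }
  colnames(out) = CharacterVector::create("f_combined", "f_unique",
                                          "f_ratio", "f_chem");
  return out;
}

// All single-codon reassignments achieving the maximal strictly positive
// fitness gain. Codons currently assigned to stop are never moved; when
// allow_loss is false a move may not remove the last codon of a residue.
// [[Rcpp::export(name = ".best_moves_core")]]
List best_moves_core(IntegerVector prod, IntegerVector cls, bool chem_distinct,
                     bool allow_loss, double tol) {
  init_nb();
  std::vector<int> p = to0(prod), c = cls0(cls);
  Metrics m0 = eval_metrics(p, c.data(), chem_distinct);
  int cnt[21] = { 0 };
  for (int k = 0; k < 64; k++) cnt[p[k]]++;
  double best = m0.F;
  std::vector<std::pair<int, int> > moves;
  for (int k = 0; k < 64; k++) {
    int old = p[k];
    if (old == STOP) continue;
    if (!allow_loss && cnt[old] == 1) continue;
    for (int r = 0; r < 20; r++) {
      if (r == old) continue;
      p[k] = r;
      Metrics m = eval_metrics(p, c.data(), chem_distinct);
      p[k] = old;
      if (!m.ratio_defined) continue;
      if (m.F > best + tol) {
        best = m.F;
        moves.clear();
        moves.push_back(std::make_pair(k, r));
      } else if (m.F > m0.F + tol && m.F >= best - tol && !moves.empty()) {
        moves.push_back(std::make_pair(k, r));
      }
    }
  }
  IntegerMatrix mv(moves.size(), 2);
  for (size_t i = 0; i < moves.size(); i++) {
    mv(i, 0) = moves[i].first + 1;
    mv(i, 1) = moves[i].second + 1;
  }
  return List::create(_["moves"] = mv, _["fitness"] = best,
                      _["start_fitness"] = m0.F);
}

// Greedy single-path best-move improvement: take the first maximal-gain move
// each round (deterministic loop order: codon index, then product index).
// [[Rcpp::export(name = ".greedy_search_core")]]
List greedy_search_core(IntegerVector prod, IntegerVector cls,
                        bool chem_distinct, bool allow_loss, double tol,
                        int max_rounds) {
  init_nb();
  std::vector<int> p = to0(prod), c = cls0(cls);
  Metrics m = eval_metrics(p, c.data(), chem_distinct);
  double f = m.F;
  std::vector<double> trace;
  trace.push_back(f);
  int depth = 0;
  while (depth < max_rounds) {
    int cnt[21] = { 0 };
    for (int k = 0; k < 64; k++) cnt[p[k]]++;
    double bestf = f;
    int bk = -1, br = -1;
    for (int k = 0; k < 64; k++) {
      int old = p[k];
      if (old == STOP) continue;
      if (!allow_loss && cnt[old] == 1) continue;
      for (int r = 0; r < 20; r++) {
        if (r == old) continue;
        p[k] = r;
        Metrics mm = eval_metrics(p, c.data(), chem_distinct);
        p[k] = old;
        if (mm.ratio_defined && mm.F > bestf + tol) {
          bestf = mm.F; bk = k; br = r;
        }
      }
    }
    if (bk < 0) break;
    p[bk] = br;
    f = bestf;
    depth++;
    trace.push_back(f);
  }
  IntegerVector out(64);
  for (int k = 0; k < 64; k++) out[k] = p[k] + 1;
  return List::create(_["code"] = out, _["depth"] = depth,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

static std::string code_key(const std::vector<int>& p) {
  std::string s(64, 'A');
  for (int k = 0; k < 64; k++) s[k] = 'A' + (char)p[k];
  return s;
}

// Depth-first expansion of all tied maximal-gain moves with memoization on
// the 64-symbol assignment. Terminal codes admit no strictly improving move.
// [[Rcpp::export(name = ".branch_search_core")]]
List branch_search_core(IntegerVector prod, IntegerVector cls,
                        bool chem_distinct, bool allow_loss, double tol,
                        double budget) {
  init_nb();
  std::vector<int> c = cls0(cls);
  std::vector<int> s0 = to0(prod);
  std::unordered_set<std::string> memo, termset;
  struct Node { std::vector<int> p; int depth; };
  std::vector<Node> stack;
  std::vector<std::string> terminals;
  std::vector<int> term_depth;
  std::vector<double> term_fitness;
  stack.push_back(Node());
  stack.back().p = s0;
  stack.back().depth = 0;
  memo.insert(code_key(s0));
  double nodes = 0;
  bool exceeded = false;
  int maxdepth = 0;
  while (!stack.empty()) {
    Node nd = stack.back();
    stack.pop_back();
    nodes += 1;
    if (nodes > budget) { exceeded = true; break; }
    int cnt[21] = { 0 };
    for (int k = 0; k < 64; k++) cnt[nd.p[k]]++;
    Metrics m0 = eval_metrics(nd.p, c.data(), chem_distinct);
    double best = m0.F;
    std::vector<std::pair<int, int> > moves;
    for (int k = 0; k < 64; k++) {
      int old = nd.p[k];
      if (old == STOP) continue;
      if (!allow_loss && cnt[old] == 1) continue;
      for (int r = 0; r < 20; r++) {
        if (r == old) continue;
        nd.p[k] = r;
        Metrics m = eval_metrics(nd.p, c.data(), chem_distinct);
        nd.p[k] = old;
        if (!m.ratio_defined) continue;
        if (m.F > best + tol) {
          best = m.F;
          moves.clear();
          moves.push_back(std::make_pair(k, r));
        } else if (m.F > m0.F + tol && m.F >= best - tol && !moves.empty()) {
          moves.push_back(std::make_pair(k, r));
        }
      }
    }
    if (nd.depth > maxdepth) maxdepth = nd.depth;
    if (moves.empty()) {
      std::string kk = code_key(nd.p);
      if (!termset.count(kk)) {
        termset.insert(kk);
        terminals.push_back(kk);
        term_depth.push_back(nd.depth);
        term_fitness.push_back(m0.F);
      }
      continue;
    }
    for (size_t i = 0; i < moves.size(); i++) {
      std::vector<int> p2 = nd.p;
      p2[moves[i].first] = moves[i].second;
      std::string kk = code_key(p2);
      if (memo.count(kk)) continue;
      memo.insert(kk);
      Node child;
      child.p = p2;
      child.depth = nd.depth + 1;
      stack.push_back(child);
    }
  }
  return List::create(
      _["terminals"] = CharacterVector(terminals.begin(), terminals.end()),
      _["depth"] = IntegerVector(term_depth.begin(), term_depth.end()),
      _["fitness"] = NumericVector(term_fitness.begin(), term_fitness.end()),
      _["visited"] = (double)memo.size(), _["nodes"] = nodes,
      _["max_depth"] = maxdepth, _["exceeded"] = exceeded);
}

// Base-pair maximization folding (Nussinov-style dynamic program) over
// {A,C,G,T}: Watson-Crick pairs plus GU/GT wobble, minimum hairpin loop of 3
// unpaired bases. Energy is -(number of pairs). Ties during traceback are
// resolved deterministically (pairing preferred, earliest split point).
static bool can_pair(char a, char b) {
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return true;
  if ((a == 'C' && b == 'G') || (a == 'G' && b == 'C')) return true;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return true;
  return false;
}

// [[Rcpp::export(name = ".nussinov_core")]]
List nussinov_core(std::string seq, int min_loop) {
  int n = seq.size();
  std::vector<std::vector<int> > D(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; len++) {
    for (int i = 0; i + len - 1 < n; i++) {
      int j = i + len - 1;
      int best = D[i + 1][j];  // i unpaired
      if (can_pair(seq[i], seq[j]) && j - i > min_loop) {
        int v = 1 + (i + 1 <= j - 1 ? D[i + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      for (int k = i + min_loop + 1; k < j; k++) {
        if (!can_pair(seq[i], seq[k]) || k - i <= min_loop) continue;
        int v = 1 + (i + 1 <= k - 1 ? D[i + 1][k - 1] : 0) + D[k + 1][j];
        if (v > best) best = v;
      }
      D[i][j] = best;
    }
  }
  std::string db(n, '.');
  // iterative traceback
  std::vector<std::pair<int, int> > work;
  if (n > 0) work.push_back(std::make_pair(0, n - 1));
  while (!work.empty()) {
    int i = work.back().first, j = work.back().second;
    work.pop_back();
    if (i >= j || D[i][j] == 0) continue;
    if (can_pair(seq[i], seq[j]) && j - i > min_loop &&
        D[i][j] == 1 + (i + 1 <= j - 1 ? D[i + 1][j - 1] : 0)) {
      db[i] = '('; db[j] = ')';
      if (i + 1 <= j - 1) work.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    bool done = false;
    for (int k = i + min_loop + 1; k < j && !done; k++) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (i + 1 <= k - 1 ? D[i + 1][k - 1] : 0) + D[k + 1][j];
      if (v == D[i][j]) {
        db[i] = '('; db[k] = ')';
        if (i + 1 <= k - 1) work.push_back(std::make_pair(i + 1, k - 1));
        work.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) work.push_back(std::make_pair(i + 1, j));
  }
  int pairs = n > 0 ? D[0][n - 1] : 0;
  return List::create(_["structure"] = db, _["pairs"] = pairs);
}

// One GA round: offspring i is a mutant of elite[i mod n_elite] (cyclical
// selection). Each movable codon mutates independently with probability
// rate: it takes the product of another randomly chosen codon (copy) or
// exchanges products with it. Proposals violating constraints, and
// offspring whose f_chem falls below chem_floor, are resampled up to
// max_retries times, then the parent is copied. Uses R's RNG.
static bool constraints_ok(const std::vector<int>& p, bool allow_loss,
                           const int* native_ref, bool native_restriction,
                           bool stopless, int taa) {
  if (!allow_loss) {
    bool enc[21] = { false };
    for (int k = 0; k < 64; k++) enc[p[k]] = true;
    for (int r = 0; r < 20; r++) if (!enc[r]) return false;
  }
  if (stopless) {
    for (int k = 0; k < 64; k++)
      if (k != taa && p[k] == STOP) return false;
  }
  if (native_restriction) {
    bool kept[21] = { false };
    for (int k = 0; k < 64; k++)
      if (p[k] == native_ref[k]) kept[p[k]] = true;
    for (int r = 0; r < 20; r++) {
      bool used = false;
      for (int k = 0; k < 64; k++) if (native_ref[k] == r) used = true;
      if (used && !kept[r]) return false;
    }
  }
  return true;
}

// [[Rcpp::export(name = ".ga_round_core")]]
IntegerMatrix ga_round_core(IntegerMatrix elite, int n_offspring,
                            double rate, int op,  // 0 copy, 1 exchange, 2 uniform product
                            IntegerVector movable_in,
                            IntegerVector native_ref_in,
                            bool native_restriction, bool allow_loss,
                            bool stopless, IntegerVector cls,
                            bool chem_distinct, double chem_floor,
                            int max_retries) {
  init_nb();
  std::vector<int> c = cls0(cls);
  std::vector<int> native_ref(64);
  for (int k = 0; k < 64; k++) native_ref[k] = native_ref_in[k] - 1;
  std::vector<int> movable(movable_in.size());
  for (int i = 0; i < movable_in.size(); i++) movable[i] = movable_in[i] - 1;
  int taa = 2 * 16 + 0 * 4 + 2;  // TAA: T=0, A=2
  int n_elite = elite.ncol();
  IntegerMatrix out(64, n_offspring);
  std::vector<int> parent(64), child(64), cand(64);
  for (int i = 0; i < n_offspring; i++) {
    int pi = i % n_elite;
    for (int k = 0; k < 64; k++) parent[k] = elite(k, pi) - 1;
    child = parent;
    bool accepted = false;
    for (int attempt = 0; attempt <= max_retries && !accepted; attempt++) {
      cand = parent;
      for (size_t m = 0; m < movable.size(); m++) {
        if (R::unif_rand() >= rate) continue;
        int k = movable[m];
        for (int t = 0; t < max_retries; t++) {
          std::vector<int> trial = cand;
          if (op == 2) {
            int r = (int)(R::unif_rand() * 21.0);
            if (r >= 21) r = 20;
            if (r == cand[k]) continue;
            trial[k] = r;
          } else {
            int donor = (int)(R::unif_rand() * 64.0);
            if (donor >= 64) donor = 63;
            if (donor == k) continue;
            if (op == 0) trial[k] = cand[donor];
            else { trial[k] = cand[donor]; trial[donor] = cand[k]; }
          }
          if (constraints_ok(trial, allow_loss, native_ref.data(),
                             native_restriction, stopless, taa)) {
            cand = trial;
            break;
          }
        }
      }
      Metrics mm = eval_metrics(cand, c.data(), chem_distinct);
      if (mm.fc >= chem_floor - 1e-12) {
        child = cand;
        accepted = true;
      }
    }
    for (int k = 0; k < 64; k++) out(k, i) = child[k] + 1;
  }
  return out;
}
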