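// Segment-based forward Wright-Fisher engine.
//
// All stochastic draws come from R's global RNG stream (unif_rand / R::rpois)
// in a fixed, documented order so that runs are reproducible from a single
// set.seed() and so that the pure-R per-site oracle (R/oracle.R) can replay
// the identical decision sequence.  Draw order, per generation, per
// population row (registry order), per offspring slot:
//   [sex-specific sizes only] one Fisher-Yates shuffle of the sex vector
//   (a) offspring sex coin            (dioecious without sex-specific sizes)
//   (b) source draw for parent 1      (mother in dioecious mode)
//   (c) fitness-weighted pick of parent 1
//   (d) source draw for parent 2      (father)
//   (e) fitness-weighted pick of parent 2; in monoecious mode re-drawn
//       until distinct from parent 1
//   (f) per chromosome: maternal gamete  [rpois(genLen); crossover
//       positions; start-haplotype coin; rpois(mu); mutation positions],
//       then paternal gamete likewise (male X: copied, mutation draws only;
//       no paternal X for sons).
//
// Coordinates are 0-based half-open in base pairs; crossovers are drawn on
// the genetic (Morgan) scale and mapped to physical positions through a
// piecewise-linear genetic map.  Mutation positions are integer bp; a second
// hit at an occupied position reverts the allele (two-allele model).

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <string>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {

struct Chrom {
  std::string name;
  double L;
  bool isX;
  std::vector<double> mapPhys, mapGen;  // piecewise-linear genetic map nodes
  double genLen;
  bool uniformMut;
  double muTotal;
  std::vector<double> mutPos, mutCum;  // site-specific mutation targets
  std::vector<double> selPos;          // tracked selected positions (0-based bp)
};

struct Hap {
  std::vector<double> starts;  // segment starts; starts[0] == 0
  std::vector<int> labels;     // founder labels, parallel to starts
  std::vector<double> bps;     // accumulated crossover positions, sorted
  std::vector<double> muts;    // accumulated de novo positions, sorted
  std::vector<int> sel;        // allele state at each Chrom::selPos
};

struct Ind {
  int sex;  // 0 unspecified, 1 male, 2 female
  std::vector<std::vector<Hap> > haps;  // [chrom][hap]; X males carry one
};

struct Pop {
  std::vector<Ind> inds;
};

struct Rule {
  int chrom;
  std::vector<int> posIdx;  // indices into Chrom::selPos
  std::vector<int> allele;  // required state per position
  int pop;                  // registry index, -1 = all populations
  int sex;                  // 0 both, 1 male, 2 female
  int g1, g2;
  double s;
};

struct EventRow {
  int pop;
  int size, sizeM, sizeF;  // sizeM/sizeF = -1 when not sex-specific
  std::vector<int> src, srcF, srcM;
  std::vector<double> prop, propF, propM;
};

double gen2phys(const Chrom& ch, double g) {
  const std::vector<double>& gp = ch.mapGen;
  const std::vector<double>& pp = ch.mapPhys;
  size_t i = std::upper_bound(gp.begin(), gp.end(), g) - gp.begin();
  if (i == 0) return pp.front();
  if (i >= gp.size()) return pp.back();
  double g0 = gp[i - 1], g1 = gp[i], p0 = pp[i - 1], p1 = pp[i];
  if (g1 <= g0) return p0;
  return p0 + (g - g0) / (g1 - g0) * (p1 - p0);
}

// cumulative-threshold cell lookup; a draw equal to a threshold falls in the
// cell to its right
int pickCell(const std::vector<double>& cum, double u) {
  size_t i = std::upper_bound(cum.begin(), cum.end(), u) - cum.begin();
  if (i >= cum.size()) i = cum.size() - 1;
  return static_cast<int>(i);
}

std::vector<double> cumsum(const std::vector<double>& x) {
  std::vector<double> c(x.size());
  double a = 0.0;
  for (size_t i = 0; i < x.size(); ++i) { a += x[i]; c[i] = a; }
  return c;
}

Chrom chromFromR(List cl) {
  Chrom ch;
  ch.name = as<std::string>(cl["name"]);
  ch.L = as<double>(cl["length"]);
  ch.isX = as<bool>(cl["isX"]);
  ch.mapPhys = as<std::vector<double> >(cl["mapPhys"]);
  ch.mapGen = as<std::vector<double> >(cl["mapGen"]);
  ch.genLen = ch.mapGen.back();
  ch.uniformMut = as<bool>(cl["uniformMut"]);
  ch.muTotal = as<double>(cl["muTotal"]);
  if (!ch.uniformMut) {
    ch.mutPos = as<std::vector<double> >(cl["mutPos"]);
    std::vector<double> r = as<std::vector<double> >(cl["mutRates"]);
    ch.mutCum = cumsum(r);
  }
  if (cl.containsElementNamed("selPos"))
    ch.selPos = as<std::vector<double> >(cl["selPos"]);
  return ch;
}

std::vector<Chrom> chromsFromR(List chromsR) {
  std::vector<Chrom> out;
  for (int i = 0; i < chromsR.size(); ++i)
    out.push_back(chromFromR(chromsR[i]));
  return out;
}

std::vector<Rule> rulesFromR(List rulesR) {
  std::vector<Rule> out;
  for (int i = 0; i < rulesR.size(); ++i) {
    List rl = rulesR[i];
    Rule r;
    r.chrom = as<int>(rl["chrom"]);
    r.posIdx = as<std::vector<int> >(rl["posIdx"]);
    r.allele = as<std::vector<int> >(rl["allele"]);
    r.pop = as<int>(rl["pop"]);
    r.sex = as<int>(rl["sex"]);
    r.g1 = as<int>(rl["g1"]);
    r.g2 = as<int>(rl["g2"]);
    r.s = as<double>(rl["s"]);
    out.push_back(r);
  }
  return out;
}

std::vector<EventRow> rowsFromR(List rowsR) {
  std::vector<EventRow> out;
  for (int i = 0; i < rowsR.size(); ++i) {
    List rl = rowsR[i];
    EventRow e;
    e.pop = as<int>(rl["pop"]);
    e.size = as<int>(rl["size"]);
    e.sizeM = as<int>(rl["sizeM"]);
    e.sizeF = as<int>(rl["sizeF"]);
    e.src = as<std::vector<int> >(rl["src"]);
    e.prop = as<std::vector<double> >(rl["prop"]);
    if (rl.containsElementNamed("srcF") && !Rf_isNull(rl["srcF"])) {
      e.srcF = as<std::vector<int> >(rl["srcF"]);
      e.propF = as<std::vector<double> >(rl["propF"]);
    }
    if (rl.containsElementNamed("srcM") && !Rf_isNull(rl["srcM"])) {
      e.srcM = as<std::vector<int> >(rl["srcM"]);
      e.propM = as<std::vector<double> >(rl["propM"]);
    }
    out.push_back(e);
  }
  return out;
}

Hap hapFromR(List hl) {
  Hap h;
  h.starts = as<std::vector<double> >(hl["starts"]);
  h.labels = as<std::vector<int> >(hl["labels"]);
  h.bps = as<std::vector<double> >(hl["breakpoints"]);
  h.muts = as<std::vector<double> >(hl["mutations"]);
  h.sel = as<std::vector<int> >(hl["sel"]);
  return h;
}

List hapToR(const Hap& h) {
  return List::create(_["starts"] = wrap(h.starts), _["labels"] = wrap(h.labels),
                      _["breakpoints"] = wrap(h.bps), _["mutations"] = wrap(h.muts),
                      _["sel"] = wrap(h.sel));
}

Ind indFromR(List il) {
  Ind ind;
  ind.sex = as<int>(il["sex"]);
  List hl = il["haps"];
  for (int c = 0; c < hl.size(); ++c) {
    List hc = hl[c];
    std::vector<Hap> v;
    for (int k = 0; k < hc.size(); ++k) v.push_back(hapFromR(hc[k]));
    ind.haps.push_back(v);
  }
  return ind;
}

List indToR(const Ind& ind) {
  List hl(ind.haps.size());
  for (size_t c = 0; c < ind.haps.size(); ++c) {
    List hc(ind.haps[c].size());
    for (size_t k = 0; k < ind.haps[c].size(); ++k) hc[k] = hapToR(ind.haps[c][k]);
    hl[c] = hc;
  }
  return List::create(_["sex"] = ind.sex, _["haps"] = hl);
}

Pop popFromR(List pl) {
  Pop p;
  for (int i = 0; i < pl.size(); ++i) p.inds.push_back(indFromR(pl[i]));
  return p;
}

List popToR(const Pop& p) {
  List out(p.inds.size());
  for (size_t i = 0; i < p.inds.size(); ++i) out[i] = indToR(p.inds[i]);
  return out;
}

// one meiosis: Poisson crossovers on the genetic scale, segment splicing
Hap recombine(const Hap& A, const Hap& B, const Chrom& ch) {
  int k = ch.genLen > 0 ? static_cast<int>(R::rpois(ch.genLen)) : 0;
  std::vector<double> cx;
  cx.reserve(k);
  for (int i = 0; i < k; ++i) cx.push_back(gen2phys(ch, unif_rand() * ch.genLen));
  std::sort(cx.begin(), cx.end());
  cx.erase(std::unique(cx.begin(), cx.end()), cx.end());
  int cur = (unif_rand() < 0.5) ? 0 : 1;

  Hap G;
  double prev = 0.0;
  int hap = cur;
  for (size_t j = 0; j <= cx.size(); ++j) {
    double end = (j < cx.size()) ? cx[j] : ch.L;
    if (end > prev) {
      const Hap& S = (hap == 0) ? A : B;
      size_t i0 = std::upper_bound(S.starts.begin(), S.starts.end(), prev) -
                  S.starts.begin();
      if (i0 > 0) --i0;
      for (size_t t = i0; t < S.starts.size(); ++t) {
        double s0 = S.starts[t];
        if (s0 >= end) break;
        double segEnd = (t + 1 < S.starts.size()) ? S.starts[t + 1] : ch.L;
        if (segEnd <= prev) continue;
        G.starts.push_back(std::max(s0, prev));
        G.labels.push_back(S.labels[t]);
      }
      std::vector<double>::const_iterator b0 =
          std::lower_bound(S.bps.begin(), S.bps.end(), prev);
      std::vector<double>::const_iterator b1 =
          std::lower_bound(S.bps.begin(), S.bps.end(), end);
      G.bps.insert(G.bps.end(), b0, b1);
      std::vector<double>::const_iterator m0 =
          std::lower_bound(S.muts.begin(), S.muts.end(), prev);
      std::vector<double>::const_iterator m1 =
          std::lower_bound(S.muts.begin(), S.muts.end(), end);
      G.muts.insert(G.muts.end(), m0, m1);
    }
    if (j < cx.size()) {
      G.bps.push_back(cx[j]);
      hap = 1 - hap;
      if (end > prev) prev = end;
    }
  }
  for (size_t q = 0; q < ch.selPos.size(); ++q) {
    size_t nflip = std::upper_bound(cx.begin(), cx.end(), ch.selPos[q]) - cx.begin();
    const Hap& S = (((cur + nflip) % 2) == 0) ? A : B;
    G.sel.push_back(S.sel[q]);
  }
  return G;
}

void mutate(Hap& h, const Chrom& ch) {
  if (ch.muTotal <= 0) return;
  int m = static_cast<int>(R::rpois(ch.muTotal));
  for (int i = 0; i < m; ++i) {
    double q;
    if (ch.uniformMut) {
      q = std::floor(unif_rand() * ch.L);
    } else {
      double u = unif_rand() * ch.mutCum.back();
      size_t idx = std::upper_bound(ch.mutCum.begin(), ch.mutCum.end(), u) -
                   ch.mutCum.begin();
      if (idx >= ch.mutPos.size()) idx = ch.mutPos.size() - 1;
      q = ch.mutPos[idx];
    }
    std::vector<double>::iterator it =
        std::lower_bound(h.muts.begin(), h.muts.end(), q);
    if (it != h.muts.end() && *it == q)
      h.muts.erase(it);  // double hit reverts (two-allele model)
    else
      h.muts.insert(it, q);
  }
}

double fitnessOf(const Ind& ind, int popIdx, int g, const std::vector<Rule>& rules) {
  double f = 1.0;
  for (size_t r = 0; r < rules.size(); ++r) {
    const Rule& R = rules[r];
    if (R.pop >= 0 && R.pop != popIdx) continue;
    if (g < R.g1 || g > R.g2) continue;
    if (R.sex != 0 && R.sex != ind.sex) continue;
    const std::vector<Hap>& hv = ind.haps[R.chrom];
    for (size_t k = 0; k < hv.size(); ++k) {
      bool ok = true;
      for (size_t t = 0; t < R.posIdx.size(); ++t) {
        if (hv[k].sel[R.posIdx[t]] != R.allele[t]) { ok = false; break; }
      }
      if (ok) f += R.s;
    }
  }
  return f < 0.0 ? 0.0 : f;
}

struct ParentPool {
  std::vector<int> idx;      // indices into Pop::inds
  std::vector<double> cum;   // cumulative fitness
};

// sexClass: 0 all, 1 males, 2 females
ParentPool buildPool(const Pop& p, int popIdx, int g, int sexClass,
                     const std::vector<Rule>& rules) {
  ParentPool pool;
  double a = 0.0;
  for (size_t i = 0; i < p.inds.size(); ++i) {
    if (sexClass != 0 && p.inds[i].sex != sexClass) continue;
    a += fitnessOf(p.inds[i], popIdx, g, rules);
    pool.idx.push_back(static_cast<int>(i));
    pool.cum.push_back(a);
  }
  return pool;
}

struct GenContext {
  const std::vector<Chrom>* chroms;
  const std::vector<Rule>* rules;
  CharacterVector popNames;
  bool dioecious;
};

Pop makeOffspring(const EventRow& row, std::map<int, Pop>& prev, int g,
                  const GenContext& cx) {
  const std::vector<Chrom>& chroms = *cx.chroms;
  const std::vector<Rule>& rules = *cx.rules;
  int n = row.size;
  bool sexSized = (row.sizeM >= 0 && row.sizeF >= 0);
  std::vector<int> sexes(n, 0);
  if (sexSized) {
    for (int i = 0; i < row.sizeM; ++i) sexes[i] = 1;
    for (int i = row.sizeM; i < n; ++i) sexes[i] = 2;
    for (int i = n - 1; i >= 1; --i) {  // Fisher-Yates, RNG parity with oracle
      int j = static_cast<int>(std::floor(unif_rand() * (i + 1)));
      std::swap(sexes[i], sexes[j]);
    }
  }

  std::vector<double> cumAll = cumsum(row.prop);
  std::vector<double> cumF = row.srcF.empty() ? cumAll : cumsum(row.propF);
  std::vector<double> cumM = row.srcM.empty() ? cumAll : cumsum(row.propM);
  const std::vector<int>& sF = row.srcF.empty() ? row.src : row.srcF;
  const std::vector<int>& sM = row.srcM.empty() ? row.src : row.srcM;

  // fitness pools built lazily per (source pop, sex class)
  std::map<std::pair<int, int>, ParentPool> pools;
  Pop out;
  out.inds.resize(n);

  for (int o = 0; o < n; ++o) {
    int sex = 0;
    if (cx.dioecious) {
      if (sexSized) sex = sexes[o];
      else sex = (unif_rand() < 0.5) ? 1 : 2;
    }
    int cls1 = cx.dioecious ? 2 : 0;  // parent 1 = mother
    int cls2 = cx.dioecious ? 1 : 0;  // parent 2 = father

    int src1 = sF[pickCell(cumF, unif_rand())];
    std::map<int, Pop>::iterator it1 = prev.find(src1);
    if (it1 == prev.end())
      stop("source population '%s' does not exist at generation %d",
           std::string(cx.popNames[src1]).c_str(), g - 1);
    std::pair<int, int> k1(src1, cls1);
    if (pools.find(k1) == pools.end())
      pools[k1] = buildPool(it1->second, src1, g, cls1, rules);
    ParentPool& P1 = pools[k1];
    if (P1.idx.empty())
      stop("population '%s' has no %s at generation %d",
           std::string(cx.popNames[src1]).c_str(),
           cls1 == 2 ? "females" : "individuals", g - 1);
    if (P1.cum.back() <= 0.0)
      stop("all candidate parents in population '%s' have zero fitness at generation %d",
           std::string(cx.popNames[src1]).c_str(), g - 1);
    int p1 = P1.idx[pickCell(P1.cum, unif_rand() * P1.cum.back())];

    int src2 = sM[pickCell(cumM, unif_rand())];
    std::map<int, Pop>::iterator it2 = prev.find(src2);
    if (it2 == prev.end())
      stop("source population '%s' does not exist at generation %d",
           std::string(cx.popNames[src2]).c_str(), g - 1);
    std::pair<int, int> k2(src2, cls2);
    if (pools.find(k2) == pools.end())
      pools[k2] = buildPool(it2->second, src2, g, cls2, rules);
    ParentPool& P2 = pools[k2];
    if (P2.idx.empty())
      stop("population '%s' has no %s at generation %d",
           std::string(cx.popNames[src2]).c_str(),
           cls2 == 1 ? "males" : "individuals", g - 1);
    if (P2.cum.back() <= 0.0)
      stop("all candidate parents in population '%s' have zero fitness at generation %d",
           std::string(cx.popNames[src2]).c_str(), g - 1);
    int p2 = P2.idx[pickCell(P2.cum, unif_rand() * P2.cum.back())];
    if (!cx.dioecious && src2 == src1) {
      if (static_cast<int>(it1->second.inds.size()) < 2)
        stop("monoecious population '%s' needs at least two individuals to mate (generation %d)",
             std::string(cx.popNames[src1]).c_str(), g - 1);
      while (p2 == p1)
        p2 = P2.idx[pickCell(P2.cum, unif_rand() * P2.cum.back())];
    }

    const Ind& mother = it1->second.inds[p1];
    const Ind& father = it2->second.inds[p2];
    Ind kid;
    kid.sex = sex;
    kid.haps.resize(chroms.size());
    for (size_t c = 0; c < chroms.size(); ++c) {
      const Chrom& ch = chroms[c];
      // maternal gamete (parent 1): always a recombinant meiosis
      Hap g1;
      if (mother.haps[c].size() == 2)
        g1 = recombine(mother.haps[c][0], mother.haps[c][1], ch);
      else
        g1 = recombine(mother.haps[c][0], mother.haps[c][0], ch);
      mutate(g1, ch);
      kid.haps[c].push_back(std::move(g1));
      if (ch.isX && sex == 1) continue;  // sons: maternal X only
      Hap g2;
      if (ch.isX && cx.dioecious) {
        g2 = father.haps[c][0];  // paternal X copied without recombination
      } else if (father.haps[c].size() == 2) {
        g2 = recombine(father.haps[c][0], father.haps[c][1], ch);
      } else {
        g2 = recombine(father.haps[c][0], father.haps[c][0], ch);
      }
      mutate(g2, ch);
      kid.haps[c].push_back(std::move(g2));
    }
    out.inds[o] = std::move(kid);
  }
  return out;
}

struct FreqAcc {
  std::vector<int> gen, pop, chrom;
  std::vector<double> pos, freq;
  std::vector<int> nhap;
};

// records per-position derived-allele frequencies; returns true when every
// tracked position is fixed (0 or 1) in every population
bool recordFreqs(const std::map<int, Pop>& state, int g,
                 const std::vector<Chrom>& chroms, FreqAcc& acc) {
  bool allFixed = true;
  for (std::map<int, Pop>::const_iterator it = state.begin(); it != state.end();
       ++it) {
    for (size_t c = 0; c < chroms.size(); ++c) {
      const Chrom& ch = chroms[c];
      if (ch.selPos.empty()) continue;
      std::vector<int> carrier(ch.selPos.size(), 0);
      int nh = 0;
      for (size_t i = 0; i < it->second.inds.size(); ++i) {
        const std::vector<Hap>& hv = it->second.inds[i].haps[c];
        for (size_t k = 0; k < hv.size(); ++k) {
          ++nh;
          for (size_t q = 0; q < ch.selPos.size(); ++q)
            if (hv[k].sel[q] == 1) ++carrier[q];
        }
      }
      for (size_t q = 0; q < ch.selPos.size(); ++q) {
        double f = nh > 0 ? static_cast<double>(carrier[q]) / nh : NA_REAL;
        if (!(f == 0.0 || f == 1.0)) allFixed = false;
        acc.gen.push_back(g);
        acc.pop.push_back(it->first);
        acc.chrom.push_back(static_cast<int>(c));
        acc.pos.push_back(ch.selPos[q]);
        acc.freq.push_back(f);
        acc.nhap.push_back(nh);
      }
    }
  }
  return allFixed;
}

Pop foundersFromR(List fp, int labelBase, const std::vector<Chrom>& chroms) {
  int n = as<int>(fp["n"]);
  std::vector<int> sexes = as<std::vector<int> >(fp["sexes"]);
  List selL = fp["sel"];  // per chrom: IntegerMatrix 2n x nSelPos (possibly 0 cols)
  Pop p;
  for (int j = 0; j < n; ++j) {
    Ind ind;
    ind.sex = sexes[j];
    ind.haps.resize(chroms.size());
    for (size_t c = 0; c < chroms.size(); ++c) {
      const Chrom& ch = chroms[c];
      IntegerMatrix sm = selL[c];
      int nh = (ch.isX && ind.sex == 1) ? 1 : 2;
      for (int k = 0; k < nh; ++k) {
        Hap h;
        h.starts.push_back(0.0);
        h.labels.push_back(labelBase + 2 * j + k);
        for (size_t q = 0; q < ch.selPos.size(); ++q)
          h.sel.push_back(sm(2 * j + k, static_cast<int>(q)));
        ind.haps[c].push_back(h);
      }
    }
    p.inds.push_back(ind);
  }
  return p;
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(List foundersR, List eventsR, List chromsR, List rulesR,
                  IntegerMatrix retainR, bool dioecious, CharacterVector popNames,
                  bool recordFreq, bool keepFinal, bool stopOnFixation) {
  std::vector<Chrom> chroms = chromsFromR(chromsR);
  std::vector<Rule> rules = rulesFromR(rulesR);
  GenContext cx;
  cx.chroms = &chroms;
  cx.rules = &rules;
  cx.popNames = popNames;
  cx.dioecious = dioecious;

  std::map<int, Pop> state;
  int base = 0;
  for (int i = 0; i < foundersR.size(); ++i) {
    List fp = foundersR[i];
    int n = as<int>(fp["n"]);
    state[i] = foundersFromR(fp, base, chroms);
    base += 2 * n;
  }

  std::multimap<int, int> retain;  // gen -> pop
  for (int i = 0; i < retainR.nrow(); ++i)
    retain.insert(std::make_pair(retainR(i, 0), retainR(i, 1)));

  FreqAcc freqs;
  std::vector<int> cGen, cPop, cSize;
  if (recordFreq) recordFreqs(state, 0, chroms, freqs);

  List kept;
  CharacterVector keptNames;
  {  // generation-0 retention
    std::pair<std::multimap<int, int>::iterator, std::multimap<int, int>::iterator>
        rr = retain.equal_range(0);
    for (std::multimap<int, int>::iterator it = rr.first; it != rr.second; ++it) {
      if (state.find(it->second) == state.end())
        stop("cannot retain population '%s' at generation 0",
             std::string(popNames[it->second]).c_str());
      kept.push_back(List::create(_["gen"] = 0, _["pop"] = it->second,
                                  _["individuals"] = popToR(state[it->second])));
    }
  }

  int G = eventsR.size();
  int lastGen = 0;
  bool haveSel = false;
  for (size_t c = 0; c < chroms.size(); ++c)
    if (!chroms[c].selPos.empty()) haveSel = true;
  for (int g = 1; g <= G; ++g) {
    List rowsL = eventsR[g - 1];
    std::vector<EventRow> rows = rowsFromR(rowsL);
    std::map<int, Pop> next;
    for (size_t r = 0; r < rows.size(); ++r) {
      if (rows[r].size == 0) continue;  // population dies out
      next[rows[r].pop] = makeOffspring(rows[r], state, g, cx);
      cGen.push_back(g);
      cPop.push_back(rows[r].pop);
      cSize.push_back(rows[r].size);
    }
    state.swap(next);  // previous generation discarded here
    lastGen = g;
    bool fixed = false;
    if (recordFreq) fixed = recordFreqs(state, g, chroms, freqs);
    std::pair<std::multimap<int, int>::iterator, std::multimap<int, int>::iterator>
        rr = retain.equal_range(g);
    for (std::multimap<int, int>::iterator it = rr.first; it != rr.second; ++it) {
      if (state.find(it->second) == state.end())
        stop("cannot retain population '%s' at generation %d: not present",
             std::string(popNames[it->second]).c_str(), g);
      kept.push_back(List::create(_["gen"] = g, _["pop"] = it->second,
                                  _["individuals"] = popToR(state[it->second])));
    }
    Rcpp::checkUserInterrupt();
    if (stopOnFixation && haveSel && recordFreq && fixed) break;
  }
  G = lastGen;
  // final generation retained by default (unless already requested)
  if (keepFinal)
  for (std::map<int, Pop>::iterator it = state.begin(); it != state.end(); ++it) {
    bool have = false;
    std::pair<std::multimap<int, int>::iterator, std::multimap<int, int>::iterator>
        rr = retain.equal_range(G);
    for (std::multimap<int, int>::iterator r2 = rr.first; r2 != rr.second; ++r2)
      if (r2->second == it->first) have = true;
    if (!have)
      kept.push_back(List::create(_["gen"] = G, _["pop"] = it->first,
                                  _["individuals"] = popToR(it->second)));
  }

  List freqL = List::create(
      _["gen"] = wrap(freqs.gen), _["pop"] = wrap(freqs.pop),
      _["chrom"] = wrap(freqs.chrom), _["pos"] = wrap(freqs.pos),
      _["freq"] = wrap(freqs.freq), _["nhap"] = wrap(freqs.nhap));
  List censusL = List::create(_["gen"] = wrap(cGen), _["pop"] = wrap(cPop),
                              _["size"] = wrap(cSize));
  return List::create(_["kept"] = kept, _["freq"] = freqL, _["census"] = censusL);
}

// [[Rcpp::export]]
List cpp_step(List prevR, List rowR, List chromsR, List rulesR, int g,
              bool dioecious, CharacterVector popNames) {
  std::vector<Chrom> chroms = chromsFromR(chromsR);
  std::vector<Rule> rules = rulesFromR(rulesR);
  GenContext cx;
  cx.chroms = &chroms;
  cx.rules = &rules;
  cx.popNames = popNames;
  cx.dioecious = dioecious;
  std::map<int, Pop> prev;
  CharacterVector nm = prevR.names();
  for (int i = 0; i < prevR.size(); ++i) {
    std::string s(nm[i]);  // names are registry indices rendered as digits
    int key = 0;
    for (size_t k = 0; k < s.size(); ++k)
      if (s[k] >= '0' && s[k] <= '9') key = key * 10 + (s[k] - '0');
    prev[key] = popFromR(prevR[i]);
  }
  List rows1 = List::create(rowR);
  std::vector<EventRow> rows = rowsFromR(rows1);
  Pop out = makeOffspring(rows[0], prev, g, cx);
  return popToR(out);
}

// [[Rcpp::export]]
List cpp_make_gamete(List hapA, List hapB, List chromR) {
  Chrom ch = chromFromR(chromR);
  Hap A = hapFromR(hapA), B = hapFromR(hapB);
  return hapToR(recombine(A, B, ch));
}

// [[Rcpp::export]]
List cpp_apply_mutations(List hapR, List chromR) {
  Chrom ch = chromFromR(chromR);
  Hap h = hapFromR(hapR);
  mutate(h, ch);
  return hapToR(h);
}

// [[Rcpp::export]]
double cpp_fitness(List indR, int popIdx, int g, List rulesR) {
  std::vector<Rule> rules = rulesFromR(rulesR);
  Ind ind = indFromR(indR);
  return fitnessOf(ind, popIdx, g, rules);
}
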