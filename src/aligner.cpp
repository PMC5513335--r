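// Seeded, banded affine-gap local alignment with BLAST-style scoring.
//
// Two entry points:
//   * cpp_index_build / cpp_index_search: k-mer index over a subject set
//     (typically a reference genome or a read database), seed clustering by
//     diagonal, banded Gotoh extension around each seed cluster.
//   * cpp_align_pair: single query vs single subject; exhaustive DP when the
//     problem is small enough (the band covers every diagonal, so the best
//     HSP score equals full Smith-Waterman), seeded otherwise.
//
// Scoring: match reward +r, mismatch -m, gap of length k costs open + k*ext
// (NCBI -G/-E convention). All coordinates returned are 0-based half-open,
// query coordinates always on the original (forward) query; strand '-'
// means the reverse complement of the query was aligned.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const int NEG = std::numeric_limits<int>::min() / 4;

struct Params {
  int match, mismatch, gap_open, gap_extend;
  int min_score, min_len;
  int k, band_pad, min_seeds, max_seed_gap, diag_jump, max_occ;
  double full_dp_limit;
};

static Params read_params(const List& p) {
  Params par;
  par.match = as<int>(p["match"]);
  par.mismatch = as<int>(p["mismatch"]);
  par.gap_open = as<int>(p["gap_open"]);
  par.gap_extend = as<int>(p["gap_extend"]);
  par.min_score = as<int>(p["min_hsp_score"]);
  par.min_len = as<int>(p["min_hsp_length"]);
  par.k = as<int>(p["k"]);
  par.band_pad = as<int>(p["band_pad"]);
  par.min_seeds = as<int>(p["min_seeds"]);
  par.max_seed_gap = as<int>(p["max_seed_gap"]);
  par.diag_jump = as<int>(p["diag_jump"]);
  par.max_occ = as<int>(p["max_occ"]);
  par.full_dp_limit = as<double>(p["full_dp_limit"]);
  return par;
}

static inline int8_t enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::vector<int8_t> encode(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.size(), 'N');
  size_t n = s.size();
  for (size_t i = 0; i < n; ++i) {
    char c = s[n - 1 - i];
    switch (c) {
      case 'A': case 'a': out[i] = 'T'; break;
      case 'C': case 'c': out[i] = 'G'; break;
      case 'G': case 'g': out[i] = 'C'; break;
      case 'T': case 't': out[i] = 'A'; break;
      default: out[i] = 'N';
    }
  }
  return out;
}

struct Hsp {
  int q_start, q_end, s_start, s_end;
  int score, alncols, matches, gaps;
  char strand;
  int subject;  // 0-based subject index
};

// Banded local affine-gap DP (Gotoh) over query rows [qlo,qhi) and diagonals
// [dlo,dhi] (subject pos j = i + d). Finds the best local alignment in the
// band, appends it if it clears the thresholds, then recurses on the query
// ranges left and right of the reported alignment to pick up co-linear
// secondary HSPs (noisy reads fragment alignments).
static void banded_sw(const std::vector<int8_t>& q, const std::vector<int8_t>& s,
                      int qlo, int qhi, int dlo, int dhi,
                      const Params& par, char strand, int subject,
                      std::vector<Hsp>& out, int depth) {
  const int slen = (int)s.size();
  if (qhi - qlo < 1 || dhi < dlo) return;
  const int w = dhi - dlo + 1;
  const int rows = qhi - qlo;
  if ((double)rows * w > 6e8) return;  // refuse absurd bands

  std::vector<uint8_t> tb((size_t)rows * w, 0);
  // arrays padded by one sentinel cell on each side (always NEG)
  std::vector<int> Hprev(w + 2, NEG), Eprev(w + 2, NEG), Fprev(w + 2, NEG);
  std::vector<int> Hcur(w + 2, NEG), Ecur(w + 2, NEG), Fcur(w + 2, NEG);

  const int oe = par.gap_open + par.gap_extend;
  const int ext = par.gap_extend;
  int best = 0, bi = -1, bd = -1;
  // substitution scores indexed by encoded base + 1 (index 0 = N/other)
  int subtab[5][5];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      subtab[a][b] = (a > 0 && a == b) ? par.match : -par.mismatch;

  for (int i = qlo; i < qhi; ++i) {
    const int r = i - qlo;
    const int* subrow = subtab[(int)q[i] + 1];
    // valid diagonal cells: j = i + dlo + (di-1) must fall in [0, slen)
    int di_lo = std::max(1, 1 - (i + dlo));
    int di_hi = std::min(w, slen - 1 - (i + dlo) + 1);
    std::fill(Hcur.begin() + 1, Hcur.end() - 1, NEG);
    std::fill(Ecur.begin() + 1, Ecur.end() - 1, NEG);
    std::fill(Fcur.begin() + 1, Fcur.end() - 1, NEG);
    uint8_t* tbrow = tb.data() + (size_t)r * w - 1;
    const int8_t* srow = s.data() + i + dlo - 1;
    for (int di = di_lo; di <= di_hi; ++di) {
      int e_open = Hcur[di - 1] - oe;
      int e_ext  = Ecur[di - 1] - ext;
      int E = std::max(e_open, e_ext);
      uint8_t esrc = (e_ext > e_open) ? 1 : 0;
      int f_open = Hprev[di + 1] - oe;
      int f_ext  = Fprev[di + 1] - ext;
      int F = std::max(f_open, f_ext);
      uint8_t fsrc = (f_ext > f_open) ? 1 : 0;
      int prev = 0; uint8_t hsrc = 0;  // 0 = fresh start
      int hp = Hprev[di], ep = Eprev[di], fp = Fprev[di];
      if (hp >= prev) { prev = hp; hsrc = 1; }
      if (ep > prev)  { prev = ep; hsrc = 2; }
      if (fp > prev)  { prev = fp; hsrc = 3; }
      int H = prev + subrow[(int)srow[di] + 1];
      if (H <= 0) { H = 0; hsrc = 0; }  // 0 = no alignment, restart
      Hcur[di] = H; Ecur[di] = E; Fcur[di] = F;
      tbrow[di] = (uint8_t)(hsrc | (esrc << 2) | (fsrc << 3));
      if (H > best) { best = H; bi = i; bd = di - 1; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best < par.min_score || bi < 0) return;

  // traceback from (bi, bd) in state H
  int i = bi, di = bd;
  int matches = 0, alncols = 0, gapcols = 0;
  int q_end = bi + 1, s_end = bi + (dlo + bd) + 1;
  int q_start = bi, s_start = bi + dlo + bd;
  int state = 0;  // 0=H, 1=E, 2=F
  while (true) {
    const int r = i - qlo;
    uint8_t t = tb[(size_t)r * w + di];
    if (state == 0) {
      uint8_t hsrc = t & 3;
      int j = i + dlo + di;
      alncols++;
      if (q[i] >= 0 && q[i] == s[j]) matches++;
      q_start = i; s_start = j;
      if (hsrc == 0) break;          // alignment started here
      if (hsrc == 1) { i -= 1; }     // from H(i-1, d)
      else if (hsrc == 2) { state = 1; i -= 1; }  // from E(i-1, d)
      else { state = 2; i -= 1; }    // from F(i-1, d)
    } else if (state == 1) {         // E: consumed subject, from (i, d-1)
      alncols++; gapcols++;
      uint8_t esrc = (t >> 2) & 1;
      di -= 1;
      s_start = i + dlo + di + 1;    // will be refined as we go
      if (!esrc) state = 0;
    } else {                         // F: consumed query, from (i-1, d+1)
      alncols++; gapcols++;
      uint8_t fsrc = (t >> 3) & 1;
      i -= 1; di += 1;
      if (!fsrc) state = 0;
    }
  }
  // recompute s_start properly: leftmost subject pos consumed.
  // During traceback, substitution and E columns consume subject; the final
  // H column sets s_start = j of the first column, which is correct because
  // a local alignment always starts on a substitution column.
  Hsp h;
  h.q_start = q_start; h.q_end = q_end;
  h.s_start = s_start; h.s_end = s_end;
  h.score = best; h.alncols = alncols; h.matches = matches; h.gaps = gapcols;
  h.strand = strand; h.subject = subject;
  if (h.score >= par.min_score && h.alncols >= par.min_len) out.push_back(h);

  if (depth < 5) {
    if (q_start - qlo >= std::max(par.min_len, 1))
      banded_sw(q, s, qlo, q_start, dlo, dhi, par, strand, subject, out, depth + 1);
    if (qhi - q_end >= std::max(par.min_len, 1))
      banded_sw(q, s, q_end, qhi, dlo, dhi, par, strand, subject, out, depth + 1);
  }
}

// ---------------------------------------------------------------------------
// k-mer index over a subject set

struct Entry { uint32_t code; uint32_t sid; uint32_t pos; };

struct SeqIndex {
  int k;
  int max_occ;
  std::vector<std::string> names;
  std::vector<std::vector<int8_t>> seqs;
  std::vector<Entry> entries;  // sorted by code, then sid, then pos
};

static void collect_kmers(const std::vector<int8_t>& s, int k, uint32_t sid,
                          std::vector<Entry>& out) {
  const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  uint32_t code = 0; int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)s[i]) & mask;
    if (++run >= k) out.push_back(Entry{code, sid, (uint32_t)(i + 1 - k)});
  }
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector names, CharacterVector seqs, int k, int max_occ) {
  if (k < 4 || k > 15) stop("k must be between 4 and 15");
  SeqIndex* idx = new SeqIndex();
  idx->k = k; idx->max_occ = max_occ;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(encode(as<std::string>(seqs[i])));
    collect_kmers(idx->seqs.back(), k, (uint32_t)i, idx->entries);
  }
  std::sort(idx->entries.begin(), idx->entries.end(),
            [](const Entry& a, const Entry& b) {
              if (a.code != b.code) return a.code < b.code;
              if (a.sid != b.sid) return a.sid < b.sid;
              return a.pos < b.pos;
            });
  XPtr<SeqIndex> p(idx, true);
  return p;
}

struct SeedHit { uint32_t sid; int qpos; int spos; };

static void query_seeds(const SeqIndex& idx, const std::vector<int8_t>& q,
                        std::vector<SeedHit>& hits) {
  const int k = idx.k;
  const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  uint32_t code = 0; int run = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (q[i] < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)q[i]) & mask;
    if (++run < k) continue;
    int qpos = (int)(i + 1 - k);
    auto lo = std::lower_bound(idx.entries.begin(), idx.entries.end(), code,
                               [](const Entry& e, uint32_t c) { return e.code < c; });
    auto hi = std::upper_bound(lo, idx.entries.end(), code,
                               [](uint32_t c, const Entry& e) { return c < e.code; });
    if (hi - lo > idx.max_occ) continue;  // repeat-like k-mer, skip
    for (auto it = lo; it != hi; ++it)
      hits.push_back(SeedHit{it->sid, qpos, (int)it->pos});
  }
}

static const int SEED_MARGIN = 100;
static const int DIAG_BIN = 512;  // diagonal band width for seed binning

// Cluster seeds by (subject, diagonal band, query locality) and run banded
// extension on each cluster. Fixed diagonal bands keep random seed
// coincidences apart even on very long reads (their density within one band
// is far too thin to pass the query-locality and count filters), while a
// genuine alignment's diagonal drift (a random indel walk, sd ~ sqrt(0.03 L))
// stays within one or two bands; a band-straddling alignment is recovered
// from either band's extension since the DP band extends band_pad beyond
// the member seeds, and co-linear fragments are rejoined by chain_blocks().
static void extend_clusters(const SeqIndex& idx, const std::vector<int8_t>& q,
                            std::vector<SeedHit>& hits, const Params& par,
                            char strand, std::vector<Hsp>& out) {
  if (hits.empty()) return;
  const int64_t DIAG0 = 1 << 30;  // bias so bucket division rounds uniformly
  std::sort(hits.begin(), hits.end(), [&](const SeedHit& a, const SeedHit& b) {
    if (a.sid != b.sid) return a.sid < b.sid;
    int64_t ba = (DIAG0 + a.spos - a.qpos) / DIAG_BIN;
    int64_t bb = (DIAG0 + b.spos - b.qpos) / DIAG_BIN;
    if (ba != bb) return ba < bb;
    return a.qpos < b.qpos;
  });
  const int qlen = (int)q.size();
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i + 1;
    int64_t bi = (DIAG0 + hits[i].spos - hits[i].qpos) / DIAG_BIN;
    while (j < hits.size() && hits[j].sid == hits[i].sid &&
           (DIAG0 + hits[j].spos - hits[j].qpos) / DIAG_BIN == bi)
      ++j;
    // one diagonal band [i, j), already sorted by query position
    std::vector<SeedHit> cl(hits.begin() + i, hits.begin() + j);
    size_t a = 0;
    while (a < cl.size()) {
      size_t b = a + 1;
      while (b < cl.size() && cl[b].qpos - cl[b - 1].qpos <= par.max_seed_gap) ++b;
      // genuine alignment blocks produce dense seeds (one error-free k-mer
      // every few bases even at 13% error); random seed coincidences spread
      // thin over long spans and are rejected by a span-scaled count
      int span = cl[b - 1].qpos - cl[a].qpos + idx.k;
      int minq = cl[a].qpos, maxq = cl[b - 1].qpos;
      int dmin = INT32_MAX, dmax = INT32_MIN;
      for (size_t t = a; t < b; ++t) {
        int d = cl[t].spos - cl[t].qpos;
        dmin = std::min(dmin, d); dmax = std::max(dmax, d);
      }
      // a genuine cluster is seed-dense relative to both its query span and
      // its diagonal spread (indel drift adds ~1 diagonal per 10-15 bases at
      // worst); sparse wide clusters are random coincidences
      int need = std::max(par.min_seeds,
                          std::max(span / 300, (dmax - dmin) / 10));
      if ((int)(b - a) >= need) {
        const std::vector<int8_t>& s = idx.seqs[cl[a].sid];
        // margins and band scale with the seed span so that the frequent
        // short random exact matches stay cheap to dismiss
        int margin = std::min(SEED_MARGIN, span / 2 + 30);
        int dpad = std::min(par.band_pad, span / 4 + 20);
        int qlo = std::max(0, minq - margin);
        int qhi = std::min(qlen, maxq + idx.k + margin);
        int dlo = dmin - dpad, dhi = dmax + dpad;
        if (dhi - dlo + 1 > 3000) {  // cap band width on noisy repeat piles
          int dmid = (dmin + dmax) / 2;
          dlo = std::max(dlo, dmid - 1500); dhi = std::min(dhi, dmid + 1500);
        }
        dlo = std::max(dlo, -(qhi - 1));
        dhi = std::min(dhi, (int)s.size() - 1 - qlo);
        banded_sw(q, s, qlo, qhi, dlo, dhi, par, strand, (int)cl[a].sid, out, 0);
      }
      a = b;
    }
    i = j;
  }
}

// drop HSPs mostly contained (>=80% on both axes) in a better-scoring HSP
static void dedupe(std::vector<Hsp>& hsps) {
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.q_start != b.q_start) return a.q_start < b.q_start;
    if (a.subject != b.subject) return a.subject < b.subject;
    if (a.s_start != b.s_start) return a.s_start < b.s_start;
    return a.strand < b.strand;
  });
  std::vector<Hsp> kept;
  for (const Hsp& h : hsps) {
    bool dup = false;
    for (const Hsp& k : kept) {
      if (k.subject != h.subject || k.strand != h.strand) continue;
      int qov = std::min(k.q_end, h.q_end) - std::max(k.q_start, h.q_start);
      int sov = std::min(k.s_end, h.s_end) - std::max(k.s_start, h.s_start);
      int qlen = h.q_end - h.q_start, slen = h.s_end - h.s_start;
      if (qov > 0 && sov > 0 && qov >= 0.8 * qlen && sov >= 0.8 * slen) { dup = true; break; }
    }
    if (!dup) kept.push_back(h);
  }
  hsps.swap(kept);
}

static DataFrame hsps_to_df(const std::vector<Hsp>& hsps) {
  int n = (int)hsps.size();
  IntegerVector subject(n), q_start(n), q_end(n), s_start(n), s_end(n),
      score(n), alncols(n), matches(n), gaps(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    const Hsp& h = hsps[i];
    subject[i] = h.subject + 1;
    q_start[i] = h.q_start; q_end[i] = h.q_end;
    s_start[i] = h.s_start; s_end[i] = h.s_end;
    score[i] = h.score; alncols[i] = h.alncols;
    matches[i] = h.matches; gaps[i] = h.gaps;
    strand[i] = std::string(1, h.strand);
  }
  return DataFrame::create(
      _["subject"] = subject, _["strand"] = strand,
      _["q_start"] = q_start, _["q_end"] = q_end,
      _["s_start"] = s_start, _["s_end"] = s_end,
      _["score"] = score, _["aligned_cols"] = alncols,
      _["matches"] = matches, _["gaps"] = gaps,
      _["stringsAsFactors"] = false);
}

// map HSPs found on the reverse-complemented query back to forward-query coords
static void flip_query_coords(std::vector<Hsp>& hsps, int qlen, size_t from) {
  for (size_t i = from; i < hsps.size(); ++i) {
    int a = hsps[i].q_start, b = hsps[i].q_end;
    hsps[i].q_start = qlen - b;
    hsps[i].q_end = qlen - a;
  }
}

// [[Rcpp::export]]
DataFrame cpp_index_search(SEXP xp, std::string query, List params) {
  XPtr<SeqIndex> idx(xp);
  Params par = read_params(params);
  std::vector<Hsp> hsps;
  std::vector<int8_t> qf = encode(query);
  {
    std::vector<SeedHit> hits;
    query_seeds(*idx, qf, hits);
    extend_clusters(*idx, qf, hits, par, '+', hsps);
  }
  {
    std::string rc = cpp_revcomp(query);
    std::vector<int8_t> qr = encode(rc);
    std::vector<SeedHit> hits;
    query_seeds(*idx, qr, hits);
    size_t before = hsps.size();
    extend_clusters(*idx, qr, hits, par, '-', hsps);
    flip_query_coords(hsps, (int)qf.size(), before);
  }
  dedupe(hsps);
  return hsps_to_df(hsps);
}

// [[Rcpp::export]]
DataFrame cpp_align_pair(std::string query, std::string subject, List params) {
  Params par = read_params(params);
  std::vector<int8_t> sv = encode(subject);
  std::vector<int8_t> qf = encode(query);
  const int qlen = (int)qf.size(), slen = (int)sv.size();
  std::vector<Hsp> hsps;
  if ((double)qlen * (double)slen <= par.full_dp_limit) {
    // exhaustive: band covers every diagonal -> best HSP == Smith-Waterman
    banded_sw(qf, sv, 0, qlen, -(qlen - 1), slen - 1, par, '+', 0, hsps, 0);
    std::string rc = cpp_revcomp(query);
    std::vector<int8_t> qr = encode(rc);
    size_t before = hsps.size();
    banded_sw(qr, sv, 0, qlen, -(qlen - 1), slen - 1, par, '-', 0, hsps, 0);
    flip_query_coords(hsps, qlen, before);
  } else {
    SeqIndex idx;
    idx.k = par.k; idx.max_occ = par.max_occ;
    idx.names.push_back("subject");
    idx.seqs.push_back(sv);
    collect_kmers(sv, par.k, 0, idx.entries);
    std::sort(idx.entries.begin(), idx.entries.end(),
              [](const Entry& a, const Entry& b) {
                if (a.code != b.code) return a.code < b.code;
                return a.pos < b.pos;
              });
    {
      std::vector<SeedHit> hits;
      query_seeds(idx, qf, hits);
      extend_clusters(idx, qf, hits, par, '+', hsps);
    }
    {
      std::string rc = cpp_revcomp(query);
      std::vector<int8_t> qr = encode(rc);
      std::vector<SeedHit> hits;
      query_seeds(idx, qr, hits);
      size_t before = hsps.size();
      extend_clusters(idx, qr, hits, par, '-', hsps);
      flip_query_coords(hsps, qlen, before);
    }
  }
  dedupe(hsps);
  return hsps_to_df(hsps);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeqIndex> idx(xp);
  CharacterVector names(idx->names.size());
  IntegerVector lens(idx->names.size());
  for (size_t i = 0; i < idx->names.size(); ++i) {
    names[i] = idx->names[i];
    lens[i] = (int)idx->seqs[i].size();
  }
  return List::create(_["names"] = names, _["lengths"] = lens,
                      _["k"] = idx->k, _["n_kmers"] = (double)idx->entries.size());
}
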