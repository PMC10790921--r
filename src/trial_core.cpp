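// Discrete-event core of the closed-loop trial runner.
//
// The R level pre-draws every open-loop stream (flicker onsets, operator
// macro presses, center alert contents/ratings, right-screen false-alarm
// times) and hands them to this core, which merges them in time order,
// maintains the trial state (flicker FIFO, frequency-chart columns, open
// breaches, AI near-critical top-ups) and classifies every signal into
// exactly one hit/miss/false-alarm outcome. Closed-loop randomness (AI column
// choice, the operator's response to a breach) is drawn from R's RNG, so a
// single R-level seed makes the whole trial reproducible.
//
// Screens are coded 1/2/3 (left/center/right), outcomes 1/2/3
// (hit/miss/false_alarm), signal-id namespaces 0/1/2/3 (none/L/C/B).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

struct Outcomes {
  std::vector<double> t;
  std::vector<int> screen, outcome, idtype, idnum;
  void add(double tt, int sc, int out, int ity, int inum) {
    t.push_back(tt); screen.push_back(sc); outcome.push_back(out);
    idtype.push_back(ity); idnum.push_back(inum);
  }
};

struct Core {
  // configuration
  int n_types, ip_pool, icon_count;
  std::vector<int> th;
  double flicker_timeout, breach_timeout, dur_s;
  bool ai_enabled, strict_miss, increment_by_rating;
  double prc0, prc1, prc2, clamp_lo, clamp_hi;
  double lat_meanlog, lat_sdlog;

  // state
  std::vector<bool> flicker_active;
  std::vector<double> fq_t; std::vector<int> fq_icon, fq_id;
  size_t fq_head = 0;
  int next_left_id = 0, dropped = 0;

  std::vector<int> counts;          // n_types x ip_pool, column-major by ip
  std::vector<bool> breach_open;
  std::vector<double> breach_t;
  std::vector<int> breach_id;
  std::vector<int> open_idx;
  int next_breach_id = 0, nc_count = 0;

  std::vector<double> step_t; std::vector<int> step_v;
  size_t step_i = 1; int target = 0;

  Outcomes out;
  std::vector<double> inj_t; std::vector<int> inj_chart, inj_ip, inj_amt, inj_nc;
  std::vector<double> adm_t; std::vector<int> adm_chart, adm_ip;
  std::vector<double> pend_t; std::vector<int> pend_col;

  int thr(int col) const { return th[col % n_types]; }

  double p_right(double t_s) const {
    double tm = (t_s < dur_s ? t_s : dur_s) / 60.0;
    double p = prc0 + prc1 * tm + prc2 * tm * tm;
    if (p < clamp_lo) p = clamp_lo;
    if (p > clamp_hi) p = clamp_hi;
    return p;
  }

  void ai_topup(double t) {
    if (!ai_enabled) return;
    while (nc_count < target) {
      std::vector<int> elig;
      int n_cols = n_types * ip_pool;
      for (int c = 0; c < n_cols; ++c) {
        if (!breach_open[c] && counts[c] <= thr(c) - 2) elig.push_back(c);
      }
      if (elig.empty()) break;
      int k = (int)std::floor(unif_rand() * elig.size());
      if (k >= (int)elig.size()) k = elig.size() - 1;
      int col = elig[k];
      int amt = (thr(col) - 1) - counts[col];
      counts[col] = thr(col) - 1;
      ++nc_count;
      inj_t.push_back(t);
      inj_chart.push_back(col % n_types + 1);
      inj_ip.push_back(col / n_types + 1);
      inj_amt.push_back(amt);
      inj_nc.push_back(nc_count);
    }
  }

  void close_breach(int col) {
    breach_open[col] = false;
    counts[col] = 0;
    breach_t[col] = NA_REAL;
    for (size_t i = 0; i < open_idx.size(); ++i) {
      if (open_idx[i] == col) { open_idx.erase(open_idx.begin() + i); break; }
    }
  }

  // returns the column index (0-based) of a breach opened by this increment,
  // or -1
  int increment_column(double t, int chart, int ip, int amount, bool from_ai) {
    int col = (chart - 1) + (ip - 1) * n_types;
    int old = counts[col];
    int now = old + amount;
    counts[col] = now;
    int tth = th[chart - 1];
    int opened = -1;
    if (!breach_open[col]) {
      if (now >= tth) {
        if (old == tth - 1) --nc_count;
        breach_open[col] = true;
        breach_t[col] = t;
        breach_id[col] = ++next_breach_id;
        open_idx.push_back(col);
        opened = col;
      } else if (now == tth - 1 && old != tth - 1) {
        ++nc_count;
      } else if (old == tth - 1 && now != tth - 1) {
        --nc_count;
      }
    }
    if (!from_ai) ai_topup(t);
    return opened;
  }

  void advance(double to) {
    const double inf = std::numeric_limits<double>::infinity();
    for (;;) {
      double t_f = (fq_head < fq_t.size()) ? fq_t[fq_head] + flicker_timeout : inf;
      double t_b = inf; int b_col = -1;
      for (size_t i = 0; i < open_idx.size(); ++i) {
        double tt = breach_t[open_idx[i]] + breach_timeout;
        if (tt < t_b) { t_b = tt; b_col = open_idx[i]; }
      }
      double t_s = (step_i < step_t.size()) ? step_t[step_i] : inf;
      double t_next = std::min(t_f, std::min(t_b, t_s));
      if (t_next > to) break;
      if (t_f <= t_b && t_f <= t_s) {
        out.add(t_f, 1, 2, 1, fq_id[fq_head]);
        flicker_active[fq_icon[fq_head]] = false;
        ++fq_head;
      } else if (t_b <= t_s) {
        out.add(t_b, 3, 2, 3, breach_id[b_col]);
        close_breach(b_col);
        ai_topup(t_b);
      } else {
        target = step_v[step_i];
        ++step_i;
        ai_topup(t_s);
      }
    }
  }

  int onset(double t, double icon_u) {
    std::vector<int> greens;
    for (int i = 0; i < icon_count; ++i) if (!flicker_active[i]) greens.push_back(i);
    ++next_left_id;
    if (greens.empty()) { ++dropped; return NA_INTEGER; }
    int k = (int)std::floor(icon_u * greens.size());
    if (k >= (int)greens.size()) k = greens.size() - 1;
    int icon = greens[k];
    fq_t.push_back(t); fq_icon.push_back(icon); fq_id.push_back(next_left_id);
    flicker_active[icon] = true;
    return icon + 1;
  }

  void macro(double t) {
    if (fq_head < fq_t.size()) {
      out.add(t, 1, 1, 1, fq_id[fq_head]);
      flicker_active[fq_icon[fq_head]] = false;
      ++fq_head;
    } else {
      out.add(t, 1, 3, 0, 0);
    }
  }

  void strict_check(double t) {
    if (strict_miss && fq_head < fq_t.size()) out.add(t, 1, 2, 0, 0);
  }

  void admin(double t, int col) {
    strict_check(t);
    if (breach_open[col]) {
      out.add(t, 3, 1, 3, breach_id[col]);
      close_breach(col);
      ai_topup(t);
    } else {
      out.add(t, 3, 3, 0, 0);
    }
    adm_t.push_back(t);
    adm_chart.push_back(col % n_types + 1);
    adm_ip.push_back(col / n_types + 1);
  }

  void flush_pending(double upto) {
    for (;;) {
      if (pend_t.empty()) return;
      size_t best = 0;
      for (size_t i = 1; i < pend_t.size(); ++i) {
        if (pend_t[i] < pend_t[best]) best = i;
      }
      if (pend_t[best] > upto) return;
      double tt = pend_t[best];
      int col = pend_col[best];
      pend_t.erase(pend_t.begin() + best);
      pend_col.erase(pend_col.begin() + best);
      advance(tt);
      admin(tt, col);
    }
  }

  void respond_to_breach(int col, double t) {
    if (unif_rand() < p_right(t)) {
      double lat = R::rlnorm(lat_meanlog, lat_sdlog);
      if (lat <= breach_timeout) {
        pend_t.push_back(t + lat);
        pend_col.push_back(col);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".run_trial_core")]]
List run_trial_core(NumericVector onset_t, NumericVector icon_u,
                    NumericVector press_t,
                    NumericVector rate_t, IntegerVector rate_score,
                    IntegerVector rate_pri, IntegerVector rate_ip,
                    NumericVector fa_t, NumericVector fa_u,
                    int n_types, int ip_pool, int icon_count,
                    IntegerVector thresholds,
                    double flicker_timeout, double breach_timeout, double dur_s,
                    NumericVector step_t_min, IntegerVector step_v,
                    bool ai_enabled, bool strict_miss, bool increment_by_rating,
                    NumericVector p_right_coefs, NumericVector clamp,
                    double lat_meanlog, double lat_sdlog) {
  Core S;
  S.n_types = n_types; S.ip_pool = ip_pool; S.icon_count = icon_count;
  S.th = as<std::vector<int>>(thresholds);
  S.flicker_timeout = flicker_timeout; S.breach_timeout = breach_timeout;
  S.dur_s = dur_s;
  S.ai_enabled = ai_enabled; S.strict_miss = strict_miss;
  S.increment_by_rating = increment_by_rating;
  S.prc0 = p_right_coefs[0]; S.prc1 = p_right_coefs[1]; S.prc2 = p_right_coefs[2];
  S.clamp_lo = clamp[0]; S.clamp_hi = clamp[1];
  S.lat_meanlog = lat_meanlog; S.lat_sdlog = lat_sdlog;

  S.flicker_active.assign(icon_count, false);
  S.counts.assign(n_types * ip_pool, 0);
  S.breach_open.assign(n_types * ip_pool, false);
  S.breach_t.assign(n_types * ip_pool, NA_REAL);
  S.breach_id.assign(n_types * ip_pool, 0);
  for (R_xlen_t i = 0; i < step_t_min.size(); ++i) S.step_t.push_back(step_t_min[i] * 60.0);
  S.step_v = as<std::vector<int>>(step_v);
  S.target = S.step_v[0];
  S.ai_topup(0.0);

  IntegerVector icon_assigned(onset_t.size(), NA_INTEGER);
  const double inf = std::numeric_limits<double>::infinity();
  R_xlen_t ia = 0, ib = 0, ic = 0, id = 0;
  for (;;) {
    double ta = ia < onset_t.size() ? onset_t[ia] : inf;
    double tb = ib < press_t.size() ? press_t[ib] : inf;
    double tc = ic < rate_t.size() ? rate_t[ic] : inf;
    double td = id < fa_t.size() ? fa_t[id] : inf;
    double t = std::min(std::min(ta, tb), std::min(tc, td));
    if (t == inf) break;
    S.flush_pending(t);
    S.advance(t);
    if (ta <= t) {  // stimulus before action; left first
      icon_assigned[ia] = S.onset(t, icon_u[ia]);
      ++ia;
    } else if (tb <= t) {
      S.macro(t);
      ++ib;
    } else if (tc <= t) {
      S.strict_check(t);
      int pri = rate_pri[ic], score = rate_score[ic], ip = rate_ip[ic];
      int outcome = score == pri ? 1 : (score < pri ? 3 : 2);
      S.out.add(t, 2, outcome, 2, (int)(ic + 1));
      int chart = S.increment_by_rating ? score : pri;
      int opened = S.increment_column(t, chart, ip, 1, false);
      if (opened >= 0) S.respond_to_breach(opened, t);
      ++ic;
    } else {
      // spurious admin alert on a column without an open breach
      std::vector<int> elig;
      for (int c = 0; c < n_types * ip_pool; ++c) {
        if (!S.breach_open[c]) elig.push_back(c);
      }
      if (!elig.empty()) {
        int k = (int)std::floor(fa_u[id] * elig.size());
        if (k >= (int)elig.size()) k = elig.size() - 1;
        S.admin(t, elig[k]);
      }
      ++id;
    }
  }
  S.flush_pending(inf);
  double t_end = dur_s + std::max(flicker_timeout, breach_timeout) + 1.0;
  S.advance(t_end);

  return List::create(
    _["outcomes"] = List::create(
      _["t"] = wrap(S.out.t), _["screen"] = wrap(S.out.screen),
      _["outcome"] = wrap(S.out.outcome), _["idtype"] = wrap(S.out.idtype),
      _["idnum"] = wrap(S.out.idnum)),
    _["injections"] = List::create(
      _["t"] = wrap(S.inj_t), _["chart"] = wrap(S.inj_chart),
      _["ip"] = wrap(S.inj_ip), _["amount"] = wrap(S.inj_amt),
      _["nc_after"] = wrap(S.inj_nc)),
    _["admin"] = List::create(
      _["t"] = wrap(S.adm_t), _["chart"] = wrap(S.adm_chart),
      _["ip"] = wrap(S.adm_ip)),
    _["icon_assigned"] = icon_assigned,
    _["dropped"] = S.dropped);
}
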