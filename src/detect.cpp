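#include <Rcpp.h>
using namespace Rcpp;

// Confirmed-event scan over one or many EDSS trajectories.
//
// Semantics (shared with the R-level documentation in detect_events):
//  * the reference ("baseline") starts at the first visit and roves: it is
//    reset to the confirmation visit of every confirmed worsening or
//    improvement event;
//  * a candidate worsening at visit v needs edss(v) - ref >= thr(ref), where
//    thr is 1.0 for ref <= 5.5 and 0.5 above; improvements mirror the rule;
//  * the candidate is confirmed by the first visit c with
//    day(c) - day(v) >= confirmation_days that is not within
//    exclusion_days after any relapse onset (closed window, 0 <= gap <=
//    exclusion_days); every visit strictly between v and c, and c itself,
//    must sustain the change relative to the reference. Relapse-tainted
//    visits are only barred from the confirmation role; they still have to
//    sustain the change;
//  * after a confirmed event the scan resumes at the confirmation visit;
//  * scheme 1 additionally resets the reference at the first visit 30+ days
//    after each relapse onset whose value is not below the original (day-0)
//    baseline; a reset is applied once, when the scan reaches its visit, and
//    is skipped if it would move the reference back in time.

static const double EPS = 1e-9;

static inline double thr_at(double ref) { return ref <= 5.5 + EPS ? 1.0 : 0.5; }

static inline bool visit_excluded(double day, const double* rel, int nrel,
                                  double excl) {
  for (int k = 0; k < nrel; ++k) {
    double gap = day - rel[k];
    if (gap >= -EPS && gap <= excl + EPS) return true;
  }
  return false;
}

// [[Rcpp::export]]
DataFrame detect_events_cpp(NumericVector day, NumericVector edss,
                            IntegerVector visit_ptr, NumericVector relapse_day,
                            IntegerVector relapse_ptr, double confirmation_days,
                            double exclusion_days, int scheme) {
  int npat = visit_ptr.size() - 1;
  std::vector<int> out_pat, out_kind;
  std::vector<double> out_onset_day, out_onset_val, out_ref_day, out_ref_val,
      out_conf_day, out_conf_val;

  for (int p = 0; p < npat; ++p) {
    int v0 = visit_ptr[p], v1 = visit_ptr[p + 1];
    int n = v1 - v0;
    if (n < 2) continue;
    const double* d = &day[v0];
    const double* e = &edss[v0];
    int r0 = relapse_ptr[p], r1 = relapse_ptr[p + 1];
    int nrel = r1 - r0;
    const double* rel = nrel > 0 ? &relapse_day[r0] : (const double*)nullptr;

    // relapse-rebaseline resets: (visit index, relapse order)
    std::vector<int> reset_idx;
    if (scheme == 1 && nrel > 0) {
      double orig = e[0];
      for (int k = 0; k < nrel; ++k) {
        for (int j = 0; j < n; ++j) {
          if (d[j] >= rel[k] + exclusion_days - EPS && e[j] >= orig - EPS) {
            reset_idx.push_back(j);
            break;
          }
        }
      }
    }
    size_t next_reset = 0;

    double ref_day = d[0], ref_val = e[0];
    int i = 1;
    while (i < n) {
      if (scheme == 1) {
        while (next_reset < reset_idx.size() && reset_idx[next_reset] <= i) {
          int j = reset_idx[next_reset];
          if (d[j] > ref_day + EPS) {
            ref_day = d[j];
            ref_val = e[j];
          }
          ++next_reset;
        }
      }
      double thr = thr_at(ref_val);
      double diff = e[i] - ref_val;
      int kind = 0;
      if (diff >= thr - EPS)
        kind = 1;  // worsening
      else if (-diff >= thr - EPS)
        kind = 2;  // improvement
      if (kind != 0) {
        int conf = -1;
        for (int j = i + 1; j < n; ++j) {
          double dj = e[j] - ref_val;
          bool sustained = (kind == 1) ? (dj >= thr - EPS) : (-dj >= thr - EPS);
          if (!sustained) break;
          if (d[j] - d[i] >= confirmation_days - EPS &&
              !visit_excluded(d[j], rel, nrel, exclusion_days)) {
            conf = j;
            break;
          }
        }
        if (conf >= 0) {
          out_pat.push_back(p + 1);
          out_kind.push_back(kind);
          out_onset_day.push_back(d[i]);
          out_onset_val.push_back(e[i]);
          out_ref_day.push_back(ref_day);
          out_ref_val.push_back(ref_val);
          out_conf_day.push_back(d[conf]);
          out_conf_val.push_back(e[conf]);
          ref_day = d[conf];
          ref_val = e[conf];
          i = conf + 1;
          continue;
        }
      }
      ++i;
    }
  }

  return DataFrame::create(
      Named("patient") = wrap(out_pat), Named("kind_code") = wrap(out_kind),
      Named("onset_day") = wrap(out_onset_day),
      Named("onset_value") = wrap(out_onset_val),
      Named("reference_day") = wrap(out_ref_day),
      Named("reference_value") = wrap(out_ref_val),
      Named("confirmation_day") = wrap(out_conf_day),
      Named("confirmation_value") = wrap(out_conf_val));
}
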