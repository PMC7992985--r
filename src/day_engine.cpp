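// Intraday discrete-event executor.
//
// One call executes a single calendar day: the frozen room schedules are run
// against realized (pre-sampled) durations, very-urgent and emergency
// break-ins are inserted at notice time into the room with the earliest
// projected availability, end-of-day rules decide which pending cases still
// start (buffer window, cross-room migration) and which are deferred, and
// the dedicated emergency room / the two night rooms stay open around the
// clock. All randomness lives on the R side; given its inputs this executor
// is fully deterministic, which is what makes common-random-number scenario
// comparisons and the degenerate-determinism checks exact.
//
// Times are minutes from the day's midnight; activity may run past 1440
// (overtime, night cases); per-room carry-over to the next day is handled
// by the caller through `avail_from`.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double INF = 1e18;
const double EPS = 1e-7;

enum EvType { EV_ROOM_FREE = 0, EV_BREAKIN = 1, EV_IND_DONE = 2, EV_SWEEP = 3 };

struct Ev {
  double t;
  long seq;
  int type;
  int a;  // room index or patient index
};
struct EvCmp {
  bool operator()(const Ev& x, const Ev& y) const {
    if (x.t != y.t) return x.t > y.t;
    return x.seq > y.seq;
  }
};

struct Engine {
  // parameters
  int R, N;
  double reg_open, reg_close, eff_close, night_open, night_end;
  bool parallel, weekend;
  int extra_teams, max_ind_rooms;

  // room state
  std::vector<int> open_, is_er, is_night, dept_r;
  std::vector<double> avail_from;
  std::vector<int> cur;
  std::vector<double> cur_clean_end, last_end;
  std::vector<char> closed;
  std::vector<std::deque<int> > q;
  int er_idx;
  int er_inbound;

  // patient state
  std::vector<int> ptype, dept_p, sched_room;
  std::vector<double> notice, ready, deadline, ind, occ, cln, plen;
  std::vector<int> pstate;  // 0 pending, 1 ind running, 2 ind done, 3 started, 4 deferred
  std::vector<char> ind_requested, ind_cancelled;
  std::vector<double> ind_end_t;
  std::vector<int> retries;

  // outputs
  std::vector<int> dispo, room_of;
  std::vector<double> o_ind_start, o_enter, o_proc, o_exit, o_clean;

  // induction token pool
  int in_use;
  std::deque<int> ind_queue;

  // event queue
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> ev;
  long seq_ctr;

  void push_ev(double t, int type, int a) {
    Ev e; e.t = t; e.seq = seq_ctr++; e.type = type; e.a = a;
    ev.push(e);
  }

  bool room_open(int r) const { return open_[r] == 1 && !closed[r]; }

  // projected entry time for a break-in: current case (plus any break-ins
  // already queued ahead) since an inserted break-in preempts the rest
  double avail_for_breakin(int r, double now, bool emerg = false) const {
    double base;
    if (closed[r]) {
      // a closed night room reopens with the 22:00 night shift
      if (!(is_night[r] && now < night_open)) return INF;
      base = night_open;
    } else {
      base = (cur[r] >= 0) ? cur_clean_end[r] : now;
      if (!is_er[r] && !is_night[r] && base < reg_open) base = reg_open;
    }
    // queued break-ins ahead of the insertion point; emergencies jump
    // waiting very-urgents
    for (size_t i = 0; i < q[r].size(); ++i) {
      int p = q[r][i];
      if (ptype[p] == 0) break;
      if (emerg && ptype[p] != 3) break;
      base += plen[p];
    }
    return base;
  }

  // projected time a room finishes everything currently queued
  double proj_free(int r, double now) const {
    double base = (cur[r] >= 0) ? cur_clean_end[r] : now;
    if (base < reg_open && !q[r].empty()) base = reg_open;
    for (size_t i = 0; i < q[r].size(); ++i) base += plen[q[r][i]];
    return base;
  }

  bool lendable() const {
    return er_idx >= 0 && open_[er_idx] == 1 && !closed[er_idx] &&
           cur[er_idx] < 0 && er_inbound == 0;
  }
  int capacity() const { return extra_teams + (lendable() ? 1 : 0); }

  void try_grant(double t) {
    while (!ind_queue.empty()) {
      int p = ind_queue.front();
      if (ind_cancelled[p] || pstate[p] != 0) { ind_queue.pop_front(); continue; }
      if (in_use >= capacity() || in_use >= max_ind_rooms) break;
      ind_queue.pop_front();
      ++in_use;
      pstate[p] = 1;
      o_ind_start[p] = t;
      ind_end_t[p] = t + ind[p];
      push_ev(ind_end_t[p], EV_IND_DONE, p);
    }
  }

  void request_induction(int p, double t) {
    if (!parallel || ptype[p] != 0) return;
    if (ind_requested[p]) return;
    ind_requested[p] = 1;
    ind_queue.push_back(p);
    try_grant(t);
  }

  void after_start(int r, double t) {
    // in parallel mode, the successor's induction may begin once the
    // current patient has entered the room
    if (!parallel) return;
    if (!q[r].empty()) {
      int nxt = q[r].front();
      if (ptype[nxt] == 0 && pstate[nxt] == 0) request_induction(nxt, t);
    }
  }

  void start_inroom(int p, int r, double t) {
    o_ind_start[p] = t;
    o_enter[p] = t;
    o_proc[p] = t + ind[p];
    o_exit[p] = o_proc[p] + occ[p];
    o_clean[p] = o_exit[p] + cln[p];
    finish_start(p, r, t);
  }

  void start_overlap(int p, int r, double t) {
    // induction already completed in an induction room
    if (ind[p] <= 0) o_ind_start[p] = t;  // zero-length induction: at entry
    o_enter[p] = t;
    o_proc[p] = t;
    o_exit[p] = t + occ[p];
    o_clean[p] = o_exit[p] + cln[p];
    finish_start(p, r, t);
  }

  void finish_start(int p, int r, double t) {
    dispo[p] = 1;
    room_of[p] = r;
    pstate[p] = 3;
    cur[r] = p;
    cur_clean_end[r] = o_clean[p];
    if (o_clean[p] > last_end[r]) last_end[r] = o_clean[p];
    if (r == er_idx && ptype[p] == 3 && er_inbound > 0) --er_inbound;
    push_ev(o_clean[p], EV_ROOM_FREE, r);
    after_start(r, t);
    try_grant(t);  // ER team may have just become unavailable/available
  }

  void defer_patient(int p, double t) {
    if (pstate[p] == 1) { --in_use; try_grant(t); }  // free the team
    dispo[p] = 2;
    pstate[p] = 4;
    ind_cancelled[p] = 1;
    o_ind_start[p] = NA_REAL;  // a pre-induction does not count as treatment
  }

  // try to move pending case p into another room that can still finish it
  // inside the buffer window; returns true when migrated
  bool try_migrate(int p, int from, double now) {
    if (eff_close <= reg_close + EPS) return false;
    int best = -1;
    double best_free = INF;
    for (int r = 0; r < R; ++r) {
      if (r == from || r == er_idx) continue;
      if (!room_open(r)) continue;
      double f = proj_free(r, now);
      if (f < reg_open) f = reg_open;
      if (f + plen[p] <= eff_close + EPS && f < best_free) {
        best_free = f;
        best = r;
      }
    }
    if (best < 0) return false;
    q[best].push_back(p);
    if (cur[best] < 0) push_ev(now, EV_ROOM_FREE, best);
    return true;
  }

  void on_room_free(int r, double t) {
    if (is_night[r] && closed[r] && t >= night_open - EPS) {
      closed[r] = 0;  // night shift takes over
    }
    if (!room_open(r)) return;
    if (cur[r] >= 0) {
      if (t + EPS < cur_clean_end[r]) return;  // wake-up before case done
      cur[r] = -1;
      if (r == er_idx) try_grant(t);  // ER team became lendable again
    }
    while (true) {
      if (q[r].empty()) {
        if (is_er[r]) return;  // staffed around the clock
        if (is_night[r]) {
          // night shift 22:00-06:00 (around the clock on weekends); the
          // day program in these rooms is ordinary elective service
          if (weekend) return;
          if (t < night_end - EPS) { push_ev(night_end, EV_ROOM_FREE, r); return; }
          if (t >= night_open - EPS) return;
          if (eff_close > reg_close + EPS && t < eff_close - EPS) {
            push_ev(eff_close, EV_ROOM_FREE, r);
            return;
          }
          closed[r] = 1;
          push_ev(night_open, EV_ROOM_FREE, r);
          return;
        }
        // program finished: staff are released and the room closes; only
        // rooms deliberately staffed as end-of-day buffer stay open and
        // on stand-by until the extended close
        if (eff_close <= reg_close + EPS || t >= eff_close - EPS) {
          closed[r] = 1;
        } else {
          push_ev(eff_close, EV_ROOM_FREE, r);
        }
        return;
      }
      int p = q[r].front();
      if (ptype[p] != 0) {  // break-in: always treated, waits only for ready
        double s = std::max(t, ready[p]);
        if (!is_er[r] && !is_night[r]) s = std::max(s, reg_open);
        if (s > t + EPS) { push_ev(s, EV_ROOM_FREE, r); return; }
        q[r].pop_front();
        start_inroom(p, r, s);
        return;
      }
      double s = std::max(t, reg_open);
      if (s > t + EPS) { push_ev(s, EV_ROOM_FREE, r); return; }
      bool may_start = (s < reg_close - EPS) ||
                       (s + plen[p] <= eff_close + EPS);
      if (may_start) {
        if (parallel && pstate[p] == 1) {  // induction still running
          push_ev(ind_end_t[p], EV_ROOM_FREE, r);
          return;
        }
        q[r].pop_front();
        if (parallel && pstate[p] == 2) start_overlap(p, r, s);
        else { ind_cancelled[p] = 1; start_inroom(p, r, s); }
        return;
      }
      // cannot start here anymore: migrate into the buffer elsewhere or defer
      q[r].pop_front();
      if (!try_migrate(p, r, t)) defer_patient(p, t);
    }
  }

  void route_breakin(int p, double t) {
    int chosen = -1;
    if (ptype[p] == 3) {  // emergency
      if (er_idx >= 0 && room_open(er_idx) && cur[er_idx] < 0 &&
          er_inbound == 0) {
        chosen = er_idx;
        ++er_inbound;
      } else {
        // next available room: any staffed room (including a queued ER and
        // night rooms about to reopen), earliest projected entry first
        chosen = argmin_avail(t, SET_ANY, -1, true);
      }
    } else {
      // very-urgent: own specialty while the 6 h window allows, then the
      // night rooms (their purpose), then any room including an idle ER
      chosen = argmin_avail(t, SET_DEPT, dept_p[p]);
      if (chosen < 0 || avail_for_breakin(chosen, t) > deadline[p]) {
        int c2 = argmin_avail(t, SET_NIGHT, -1);
        if (c2 >= 0 && avail_for_breakin(c2, t) <= deadline[p]) {
          chosen = c2;
        } else {
          int c3 = argmin_avail(t, SET_ANY_IDLE_ER, -1);
          if (c3 >= 0 &&
              (chosen < 0 || avail_for_breakin(c3, t) <
                               avail_for_breakin(chosen, t))) chosen = c3;
        }
      }
    }
    if (chosen < 0) {
      // nothing staffed right now (only possible in stripped-down layouts):
      // retry, eventually force the earliest room that opens today
      if (++retries[p] <= 3) { push_ev(t + 60, EV_BREAKIN, p); return; }
      chosen = argmin_forced(t);
      if (chosen < 0) { defer_patient(p, t); return; }
      closed[chosen] = 0;  // staff called back in
    }
    insert_breakin(p, chosen, t);
  }

  enum CandSet { SET_ANY, SET_ANY_IDLE_ER, SET_DEPT, SET_NIGHT };

  int argmin_avail(double t, int set, int want_dept, bool emerg = false) {
    int best = -1;
    double best_a = INF;
    for (int r = 0; r < R; ++r) {
      if (open_[r] != 1) continue;
      if (r == er_idx) {
        if (set == SET_DEPT || set == SET_NIGHT) continue;
        // non-emergencies may use the ER only when it is idle and free of
        // inbound emergencies; emergencies may also queue at it
        if (set == SET_ANY_IDLE_ER && (cur[r] >= 0 || er_inbound > 0))
          continue;
      } else {
        if (set == SET_DEPT && dept_r[r] != want_dept) continue;
        if (set == SET_NIGHT && is_night[r] != 1) continue;
      }
      double a = avail_for_breakin(r, t, emerg);
      if (a < best_a - EPS) { best_a = a; best = r; }
    }
    return best;
  }

  int argmin_forced(double t) {
    int best = -1;
    double best_a = INF;
    for (int r = 0; r < R; ++r) {
      if (open_[r] != 1) continue;
      double a = (cur[r] >= 0) ? cur_clean_end[r] : t;
      if (a < best_a - EPS) { best_a = a; best = r; }
    }
    return best;
  }

  void insert_breakin(int p, int r, double t) {
    // ahead of the elective plan; emergencies also jump waiting
    // very-urgents (emergencies first, then FIFO)
    size_t pos = 0;
    if (ptype[p] == 3) {
      while (pos < q[r].size() && ptype[q[r][pos]] == 3) ++pos;
    } else {
      while (pos < q[r].size() && ptype[q[r][pos]] != 0) ++pos;
    }
    q[r].insert(q[r].begin() + pos, p);
    room_of[p] = r;
    if (cur[r] < 0) push_ev(t, EV_ROOM_FREE, r);
  }

  void sweep(double t) {
    // regular close: decide the fate of everything not yet started
    for (int r = 0; r < R; ++r) {
      if (!room_open(r)) continue;
      double proj = (cur[r] >= 0) ? cur_clean_end[r] : t;
      if (proj < reg_open) proj = reg_open;
      std::deque<int> keep;
      while (!q[r].empty()) {
        int p = q[r].front();
        q[r].pop_front();
        if (ptype[p] != 0) {  // break-ins always stay
          keep.push_back(p);
          proj += plen[p];
          continue;
        }
        if (proj + plen[p] <= eff_close + EPS) {
          keep.push_back(p);
          proj += plen[p];
        } else if (!try_migrate(p, r, t)) {
          defer_patient(p, t);
        }
      }
      q[r] = keep;
      if (q[r].empty() && cur[r] < 0 && !is_er[r] && !is_night[r] &&
          eff_close <= reg_close + EPS) {
        closed[r] = 1;
      }
    }
  }

  void run() {
    while (!ev.empty()) {
      Ev e = ev.top();
      ev.pop();
      switch (e.type) {
        case EV_ROOM_FREE: on_room_free(e.a, e.t); break;
        case EV_BREAKIN: route_breakin(e.a, e.t); break;
        case EV_IND_DONE: {
          int p = e.a;
          if (pstate[p] == 1) {
            --in_use;
            pstate[p] = 2;
            int r = sched_room[p];
            if (r >= 0 && cur[r] < 0 && room_open(r) &&
                !q[r].empty() && q[r].front() == p) {
              push_ev(e.t, EV_ROOM_FREE, r);
            }
            try_grant(e.t);
          }
          break;
        }
        case EV_SWEEP: sweep(e.t); break;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".exec_day_cpp")]]
List exec_day_cpp(List rooms, List patients, List params) {
  Engine E;
  E.seq_ctr = 0;
  E.in_use = 0;
  E.er_inbound = 0;

  IntegerVector r_open = rooms["open"], r_er = rooms["is_er"],
                r_night = rooms["is_night"], r_dept = rooms["dept"];
  NumericVector r_avail = rooms["avail_from"];
  E.R = r_open.size();
  E.open_.assign(r_open.begin(), r_open.end());
  E.is_er.assign(r_er.begin(), r_er.end());
  E.is_night.assign(r_night.begin(), r_night.end());
  E.dept_r.assign(r_dept.begin(), r_dept.end());
  E.avail_from.assign(r_avail.begin(), r_avail.end());
  E.cur.assign(E.R, -1);
  E.cur_clean_end.assign(E.R, 0.0);
  E.last_end.assign(E.R, 0.0);
  E.closed.assign(E.R, 0);
  E.q.resize(E.R);
  E.er_idx = -1;
  for (int r = 0; r < E.R; ++r) {
    if (E.is_er[r] == 1 && E.open_[r] == 1) E.er_idx = r;
  }

  IntegerVector p_type = patients["ptype"], p_dept = patients["dept"],
                p_room = patients["sched_room"];
  NumericVector p_notice = patients["notice"], p_ready = patients["ready"],
                p_deadline = patients["deadline"], p_ind = patients["induction"],
                p_occ = patients["occupation"], p_cln = patients["cleaning"],
                p_plen = patients["planned_len"];
  E.N = p_type.size();
  E.ptype.assign(p_type.begin(), p_type.end());
  E.dept_p.assign(p_dept.begin(), p_dept.end());
  E.sched_room.assign(p_room.begin(), p_room.end());
  E.notice.assign(p_notice.begin(), p_notice.end());
  E.ready.assign(p_ready.begin(), p_ready.end());
  E.deadline.assign(p_deadline.begin(), p_deadline.end());
  E.ind.assign(p_ind.begin(), p_ind.end());
  E.occ.assign(p_occ.begin(), p_occ.end());
  E.cln.assign(p_cln.begin(), p_cln.end());
  E.plen.assign(p_plen.begin(), p_plen.end());
  E.pstate.assign(E.N, 0);
  E.ind_requested.assign(E.N, 0);
  E.ind_cancelled.assign(E.N, 0);
  E.ind_end_t.assign(E.N, 0.0);
  E.retries.assign(E.N, 0);
  E.dispo.assign(E.N, 0);
  E.room_of.assign(E.N, -1);
  E.o_ind_start.assign(E.N, NA_REAL);
  E.o_enter.assign(E.N, NA_REAL);
  E.o_proc.assign(E.N, NA_REAL);
  E.o_exit.assign(E.N, NA_REAL);
  E.o_clean.assign(E.N, NA_REAL);

  E.reg_open = as<double>(params["reg_open"]);
  E.reg_close = as<double>(params["reg_close"]);
  E.eff_close = as<double>(params["eff_close"]);
  E.night_open = as<double>(params["night_open"]);
  E.night_end = as<double>(params["night_end"]);
  E.parallel = as<int>(params["parallel"]) == 1;
  E.weekend = as<int>(params["weekend"]) == 1;
  E.extra_teams = as<int>(params["extra_teams"]);
  E.max_ind_rooms = as<int>(params["max_ind_rooms"]);

  // build room queues in input order (already sorted by planned start)
  for (int p = 0; p < E.N; ++p) {
    if (E.ptype[p] == 0) {
      int r = E.sched_room[p];
      if (r < 0 || r >= E.R) stop("scheduled patient without a valid room");
      E.q[r].push_back(p);
    }
  }
  // initial events
  for (int r = 0; r < E.R; ++r) {
    if (E.open_[r] != 1) continue;
    double t0 = E.avail_from[r];
    if (!E.is_er[r] && !E.is_night[r] && t0 < E.reg_open) t0 = E.reg_open;
    if (t0 < 0) t0 = 0;
    E.push_ev(t0, EV_ROOM_FREE, r);
  }
  E.push_ev(E.reg_close, EV_SWEEP, 0);
  for (int p = 0; p < E.N; ++p) {
    if (E.ptype[p] != 0) E.push_ev(E.notice[p], EV_BREAKIN, p);
  }

  E.run();

  return List::create(
      _["disposition"] = wrap(E.dispo),
      _["room"] = wrap(E.room_of),
      _["ind_start"] = wrap(E.o_ind_start),
      _["room_enter"] = wrap(E.o_enter),
      _["proc_start"] = wrap(E.o_proc),
      _["room_exit"] = wrap(E.o_exit),
      _["clean_end"] = wrap(E.o_clean),
      _["room_last_end"] = wrap(E.last_end));
}
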