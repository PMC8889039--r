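// Planar articulated-chain dynamics for the treadmill walking model.
//
// Reduced generalized coordinates: a floating planar base (x, y, theta of the
// root body) plus one revolute coordinate per non-root body, all rotations
// CCW-positive in the sagittal plane (world x anterior, y up).  Mass matrix
// and bias terms are assembled from per-body Jacobians; the bias uses the
// accelerations obtained by propagating the chain with qdd = 0 (planar bodies
// carry no gyroscopic term, so only centripetal COM accelerations remain).

#include <RcppArmadillo.h>
using namespace Rcpp;

struct Vec2 { double x, y; };
static inline Vec2 v2(double x, double y) { Vec2 v; v.x = x; v.y = y; return v; }
static inline Vec2 operator+(Vec2 a, Vec2 b) { return v2(a.x + b.x, a.y + b.y); }
static inline Vec2 operator-(Vec2 a, Vec2 b) { return v2(a.x - b.x, a.y - b.y); }
static inline Vec2 operator*(double s, Vec2 a) { return v2(s * a.x, s * a.y); }
static inline Vec2 perp(Vec2 a) { return v2(-a.y, a.x); }   // z-hat cross a
static inline double cross2(Vec2 a, Vec2 b) { return a.x * b.y - a.y * b.x; }
static inline double dot2(Vec2 a, Vec2 b) { return a.x * b.x + a.y * b.y; }
static inline double norm2(Vec2 a) { return std::sqrt(a.x * a.x + a.y * a.y); }

struct Chain {
  int nb;                       // number of bodies
  bool floating;                // root has (x,y,theta) dofs; else pinned revolute
  std::vector<int> parent;      // -1 for root
  std::vector<Vec2> jpos;       // joint anchor in parent frame (root+fixed: world)
  std::vector<double> mass, icom;
  std::vector<Vec2> com;        // COM in body frame (origin at proximal joint)
  double gravity;               // magnitude, acts along -y

  std::vector<std::vector<int>> anc;  // ancestor body indices (self first, up to root)

  int nq() const { return floating ? nb + 2 : nb; }
  // generalized-coordinate column of body i's own joint
  int col_of(int i) const { return floating ? (i == 0 ? 2 : i + 2) : i; }

  void finalize() {
    anc.assign(nb, {});
    for (int i = 0; i < nb; ++i)
      for (int b = i; b >= 0; b = parent[b]) anc[i].push_back(b);
  }
};

struct KinState {
  std::vector<double> th, w;        // body orientation, angular velocity
  std::vector<Vec2> o, vo;          // body origin (proximal joint) pos/vel
  std::vector<Vec2> c, vc, a0c;     // COM pos/vel and accel with qdd = 0
};

static void forward_kin(const Chain& ch, const double* q, const double* qd,
                        KinState& ks) {
  int nb = ch.nb;
  ks.th.resize(nb); ks.w.resize(nb);
  ks.o.resize(nb); ks.vo.resize(nb);
  ks.c.resize(nb); ks.vc.resize(nb); ks.a0c.resize(nb);
  std::vector<Vec2> ao(nb);  // origin accel with qdd = 0
  for (int i = 0; i < nb; ++i) {
    if (ch.parent[i] < 0) {
      if (ch.floating) {
        ks.o[i] = v2(q[0], q[1]);  ks.vo[i] = v2(qd[0], qd[1]);
        ks.th[i] = q[2];           ks.w[i] = qd[2];
      } else {
        ks.o[i] = ch.jpos[i];      ks.vo[i] = v2(0, 0);
        ks.th[i] = q[0];           ks.w[i] = qd[0];
      }
      ao[i] = v2(0, 0);
    } else {
      int p = ch.parent[i], cq = ch.col_of(i);
      double ct = std::cos(ks.th[p]), st = std::sin(ks.th[p]);
      Vec2 r = v2(ct * ch.jpos[i].x - st * ch.jpos[i].y,
                  st * ch.jpos[i].x + ct * ch.jpos[i].y);
      ks.o[i]  = ks.o[p] + r;
      ks.vo[i] = ks.vo[p] + ks.w[p] * perp(r);
      ao[i]    = ao[p] - (ks.w[p] * ks.w[p]) * r;
      ks.th[i] = ks.th[p] + q[cq];
      ks.w[i]  = ks.w[p] + qd[cq];
    }
    double ct = std::cos(ks.th[i]), st = std::sin(ks.th[i]);
    Vec2 rc = v2(ct * ch.com[i].x - st * ch.com[i].y,
                 st * ch.com[i].x + ct * ch.com[i].y);
    ks.c[i]   = ks.o[i] + rc;
    ks.vc[i]  = ks.vo[i] + ks.w[i] * perp(rc);
    ks.a0c[i] = ao[i] - (ks.w[i] * ks.w[i]) * rc;
  }
}

// Accumulate the generalized force of a point force F applied at world point P
// on body b:  Q += J_P^T F.
static void add_point_force(const Chain& ch, const KinState& ks, int b,
                            Vec2 P, Vec2 F, double* Q) {
  if (ch.floating) {
    Q[0] += F.x;  Q[1] += F.y;
    Q[2] += cross2(P - ks.o[0], F);
    for (int a : ch.anc[b])
      if (a != 0) Q[ch.col_of(a)] += cross2(P - ks.o[a], F);
  } else {
    for (int a : ch.anc[b]) Q[ch.col_of(a)] += cross2(P - ks.o[a], F);
  }
}

// Mass matrix via sum over bodies of Jc^T m Jc + Jth^T I Jth.
static arma::mat mass_matrix(const Chain& ch, const KinState& ks) {
  int nq = ch.nq();
  arma::mat M(nq, nq, arma::fill::zeros);
  std::vector<int> cols; std::vector<Vec2> jc;
  for (int b = 0; b < ch.nb; ++b) {
    cols.clear(); jc.clear();
    if (ch.floating) {
      cols.push_back(0); jc.push_back(v2(1, 0));
      cols.push_back(1); jc.push_back(v2(0, 1));
      cols.push_back(2); jc.push_back(perp(ks.c[b] - ks.o[0]));
      for (int a : ch.anc[b]) if (a != 0) {
        cols.push_back(ch.col_of(a)); jc.push_back(perp(ks.c[b] - ks.o[a]));
      }
    } else {
      for (int a : ch.anc[b]) {
        cols.push_back(ch.col_of(a)); jc.push_back(perp(ks.c[b] - ks.o[a]));
      }
    }
    int n = (int)cols.size();
    for (int u = 0; u < n; ++u) {
      // angular jacobian entry: 1 for every rotational column (all but base x,y)
      bool rotu = !(ch.floating && cols[u] < 2);
      for (int v = u; v < n; ++v) {
        bool rotv = !(ch.floating && cols[v] < 2);
        double m = ch.mass[b] * dot2(jc[u], jc[v]);
        if (rotu && rotv) m += ch.icom[b];
        M(cols[u], cols[v]) += m;
        if (u != v) M(cols[v], cols[u]) += m;
      }
    }
  }
  return M;
}

// bias[k] = sum_b m_b a0c_b . Jc_col_k   (planar: no angular bias term)
static void bias_forces(const Chain& ch, const KinState& ks, double* bias) {
  for (int k = 0; k < ch.nq(); ++k) bias[k] = 0;
  for (int b = 0; b < ch.nb; ++b)
    add_point_force(ch, ks, b, ks.c[b], ch.mass[b] * ks.a0c[b], bias);
}

static void gravity_forces(const Chain& ch, const KinState& ks, double* Q) {
  for (int b = 0; b < ch.nb; ++b)
    add_point_force(ch, ks, b, ks.c[b], v2(0, -ch.mass[b] * ch.gravity), Q);
}

static arma::vec solve_accel(const Chain& ch, const KinState& ks,
                             const std::vector<double>& Q) {
  arma::mat M = mass_matrix(ch, ks);
  int nq = ch.nq();
  std::vector<double> bias(nq);
  bias_forces(ch, ks, bias.data());
  arma::vec rhs(nq);
  for (int k = 0; k < nq; ++k) rhs(k) = Q[k] - bias[k];
  arma::vec qdd;
  bool ok = arma::solve(qdd, M, rhs, arma::solve_opts::likely_sympd);
  if (!ok) stop("singular mass matrix: check inertial configuration");
  return qdd;
}

static Chain chain_from_list(const List& spec) {
  Chain ch;
  IntegerVector parent = spec["parent"];
  NumericMatrix jpos = spec["jpos"], com = spec["com"];
  NumericVector mass = spec["mass"], icom = spec["icom"];
  ch.nb = parent.size();
  ch.floating = as<bool>(spec["floating"]);
  ch.gravity = as<double>(spec["gravity"]);
  int nroot = 0;
  for (int i = 0; i < ch.nb; ++i) {
    ch.parent.push_back(parent[i]);
    if (parent[i] < 0) ++nroot;
    else if (parent[i] >= i) stop("parent indices must precede children");
    ch.jpos.push_back(v2(jpos(i, 0), jpos(i, 1)));
    ch.com.push_back(v2(com(i, 0), com(i, 1)));
    if (mass[i] <= 0) stop("nonpositive segment mass");
    ch.mass.push_back(mass[i]);
    if (icom[i] < 0) stop("negative segment inertia");
    ch.icom.push_back(icom[i]);
  }
  if (nroot != 1) stop("chain must have exactly one root (disconnected topology?)");
  ch.finalize();
  return ch;
}

// [[Rcpp::export]]
NumericVector planar_chain_accel(List spec, NumericVector q, NumericVector qd,
                                 NumericVector tau, Nullable<NumericMatrix> pointforces) {
  Chain ch = chain_from_list(spec);
  int nq = ch.nq();
  if ((int)q.size() != nq || (int)qd.size() != nq || (int)tau.size() != nq)
    stop("q, qd and tau must have length %d", nq);
  KinState ks;
  forward_kin(ch, q.begin(), qd.begin(), ks);
  std::vector<double> Q(nq);
  for (int k = 0; k < nq; ++k) Q[k] = tau[k];
  gravity_forces(ch, ks, Q.data());
  if (pointforces.isNotNull()) {
    NumericMatrix pf(pointforces);   // body (1-based), lx, ly, fx, fy
    for (int r = 0; r < pf.nrow(); ++r) {
      int b = (int)pf(r, 0) - 1;
      double ct = std::cos(ks.th[b]), st = std::sin(ks.th[b]);
      Vec2 P = ks.o[b] + v2(ct * pf(r, 1) - st * pf(r, 2),
                            st * pf(r, 1) + ct * pf(r, 2));
      add_point_force(ch, ks, b, P, v2(pf(r, 3), pf(r, 4)), Q.data());
    }
  }
  arma::vec qdd = solve_accel(ch, ks, Q);
  return NumericVector(qdd.begin(), qdd.end());
}

// ---------------------------------------------------------------------------
// Walker-specific context: 10-segment model + contact + control + exoskeleton
// ---------------------------------------------------------------------------

struct ContactSphere { int body; Vec2 local; double r; };

struct JointCtl {
  int mode;        // 0 = PID on reference, 1 = HAT-upright PD, 2 = passive spring
  int refset;      // Fourier set index (0 hip, 1 knee, 2 ankle) for mode 0
  double phoff;    // stride-phase offset (0.5 for the contralateral leg)
  int integ;       // integrator slot, -1 if none
  double kp, ki, kd;
  double kp2, kd2; // mode 1: pelvis-pitch stabilization gains
};

struct WalkerCtx {
  Chain ch;
  double belt_speed;
  // contact
  bool contact_on;
  std::vector<ContactSphere> spheres;
  double kc, cc, mu, vsmooth, hc_exp;
  // reference (truncated Fourier per joint set)
  double T_cycle;
  arma::vec a0;            // 3
  arma::mat A, B;          // 3 x K
  // control (indexed by generalized coordinate 3..11)
  std::vector<JointCtl> ctl;   // length nq, entries 0..2 unused
  double integ_limit;
  bool control_on;
  // exoskeleton
  bool exo_engaged;
  double exo_ratio, exo_kperkg, body_mass;
  Vec2 anchor, spool_local, shank_local;
  int foot_body, shank_body;
  double snap_d0, snap_l0;
  int n_integ;
};

static void ref_eval(const WalkerCtx& cx, int set, double t, double phoff,
                     double* ang, double* vel) {
  double ph = t / cx.T_cycle + phoff;
  ph -= std::floor(ph);
  double a = cx.a0(set), v = 0.0;
  int K = cx.A.n_cols;
  for (int k = 1; k <= K; ++k) {
    double w = 2.0 * M_PI * k;
    double cw = std::cos(w * ph), sw = std::sin(w * ph);
    a += cx.A(set, k - 1) * cw + cx.B(set, k - 1) * sw;
    v += (w / cx.T_cycle) * (-cx.A(set, k - 1) * sw + cx.B(set, k - 1) * cw);
  }
  *ang = a; *vel = v;
}

struct WalkerForces {
  std::vector<double> tau;          // joint torques by coordinate
  std::vector<double> ie_dot;       // integrator derivatives
  double grf[2][2];                 // [side][x,y], side 0 = right
  std::vector<double> sphereFn;
  double F_el, elong, tau_exo, P_exo;
  std::vector<double> Q;            // total generalized applied force
};

// Shared force computation for both the RHS and the output recorder.
static void compute_forces(const WalkerCtx& cx, double t, const double* y,
                           WalkerForces& wf, KinState& ks) {
  const Chain& ch = cx.ch;
  int nq = ch.nq();
  const double* q = y;
  const double* qd = y + nq;
  const double* ie = y + 2 * nq;
  forward_kin(ch, q, qd, ks);

  wf.tau.assign(nq, 0.0);
  wf.ie_dot.assign(cx.n_integ, 0.0);
  wf.Q.assign(nq, 0.0);
  wf.grf[0][0] = wf.grf[0][1] = wf.grf[1][0] = wf.grf[1][1] = 0.0;
  wf.sphereFn.assign(cx.spheres.size(), 0.0);
  wf.F_el = wf.elong = wf.tau_exo = wf.P_exo = 0.0;

  gravity_forces(ch, ks, wf.Q.data());

  // contact: Hunt-Crossley normal force + regularized Coulomb belt friction
  if (cx.contact_on) {
    for (size_t s = 0; s < cx.spheres.size(); ++s) {
      const ContactSphere& sp = cx.spheres[s];
      int b = sp.body;
      double ct = std::cos(ks.th[b]), st = std::sin(ks.th[b]);
      Vec2 rl = v2(ct * sp.local.x - st * sp.local.y,
                   st * sp.local.x + ct * sp.local.y);
      Vec2 P = ks.o[b] + rl;
      Vec2 V = ks.vo[b] + ks.w[b] * perp(rl);
      double pen = sp.r - P.y;
      if (pen <= 0) continue;
      double pendot = -V.y;
      double Fn = cx.kc * std::pow(pen, cx.hc_exp) * (1.0 + cx.cc * pendot);
      if (Fn < 0) Fn = 0;
      double vrel = V.x + cx.belt_speed;   // belt surface moves at -belt_speed
      double Ft = -cx.mu * Fn * std::tanh(vrel / cx.vsmooth);
      Vec2 F = v2(Ft, Fn);
      add_point_force(ch, ks, b, v2(P.x, P.y - sp.r), F, wf.Q.data());
      wf.sphereFn[s] = Fn;
      int side = (b <= 5) ? 0 : 1;        // bodies 2..5 right leg, 6..9 left
      wf.grf[side][0] += F.x; wf.grf[side][1] += F.y;
    }
  }

  // joint torques
  if (cx.control_on) {
    for (int j = 3; j < nq; ++j) {
      const JointCtl& c = cx.ctl[j];
      double tau = 0.0;
      if (c.mode == 0 || c.mode == 3) {
        double ang, vel;
        ref_eval(cx, c.refset, t, c.phoff, &ang, &vel);
        // mode 3 (hips): track the thigh orientation relative to the
        // vertical (reference pelvis posture), i.e. in the world frame --
        // this carries the pelvis-posture feedback that hip musculature
        // provides; mode 0: plain joint-space tracking
        double qj = q[j], qdj = qd[j];
        if (c.mode == 3) { qj += q[2]; qdj += qd[2]; }
        double e = ang - qj, edot = vel - qdj;
        double ti = c.ki * ie[c.integ];
        if (ti > cx.integ_limit) ti = cx.integ_limit;
        if (ti < -cx.integ_limit) ti = -cx.integ_limit;
        tau = c.kp * e + ti + c.kd * edot;
        double ied = e;   // conditional anti-windup
        double raw = c.ki * ie[c.integ];
        if ((raw >= cx.integ_limit && e > 0) || (raw <= -cx.integ_limit && e < 0))
          ied = 0.0;
        wf.ie_dot[c.integ] = ied;
      } else if (c.mode == 1) {
        // trunk posture: PD keeping the HAT world-upright, plus a PD that
        // rights the pelvis by pushing against the (stabilized) HAT
        tau = -c.kp * ks.th[1] - c.kd * ks.w[1]
              + c.kp2 * q[2] + c.kd2 * qd[2];
      } else {                             // passive metatarsophalangeal spring
        tau = -c.kp * q[j] - c.kd * qd[j];
      }
      wf.tau[j] = tau;
      wf.Q[j] += tau;
    }
  }

  // exoskeleton: elastic tendon toward the anchor + rigid-tendon pair
  if (cx.exo_engaged) {
    int fb = cx.foot_body, sb = cx.shank_body;
    double ctf = std::cos(ks.th[fb]), stf = std::sin(ks.th[fb]);
    Vec2 rsp = v2(ctf * cx.spool_local.x - stf * cx.spool_local.y,
                  stf * cx.spool_local.x + ctf * cx.spool_local.y);
    Vec2 Psp = ks.o[fb] + rsp;
    Vec2 Vsp = ks.vo[fb] + ks.w[fb] * perp(rsp);
    double cts = std::cos(ks.th[sb]), sts = std::sin(ks.th[sb]);
    Vec2 rsh = v2(cts * cx.shank_local.x - sts * cx.shank_local.y,
                  sts * cx.shank_local.x + cts * cx.shank_local.y);
    Vec2 Psh = ks.o[sb] + rsh;
    Vec2 Vsh = ks.vo[sb] + ks.w[sb] * perp(rsh);
    double d = norm2(cx.anchor - Psp);
    double l = norm2(Psh - Psp);
    double e = (d - cx.snap_d0) + cx.exo_ratio * (l - cx.snap_l0);
    if (e > 0) {
      double Fel = cx.body_mass * cx.exo_kperkg * e;
      Vec2 u_anchor = (1.0 / d) * (cx.anchor - Psp);
      Vec2 u_shank = (1.0 / l) * (Psh - Psp);
      double Frig = cx.exo_ratio * Fel;
      Vec2 F1 = Fel * u_anchor;            // elastic tendon on foot spool point
      Vec2 F2 = Frig * u_shank;            // rigid tendon pulls spool toward shank
      Vec2 F3 = v2(-F2.x, -F2.y);          // reaction on shank attachment
      std::vector<double> Qexo(nq, 0.0);
      add_point_force(ch, ks, fb, Psp, F1, Qexo.data());
      add_point_force(ch, ks, fb, Psp, F2, Qexo.data());
      add_point_force(ch, ks, sb, Psh, F3, Qexo.data());
      for (int k = 0; k < nq; ++k) wf.Q[k] += Qexo[k];
      wf.F_el = Fel; wf.elong = e;
      wf.tau_exo = Qexo[ch.col_of(fb)];    // equivalent ankle torque
      wf.P_exo = dot2(F1, Vsp) + dot2(F2, Vsp) + dot2(F3, Vsh);
    }
  }
}

// [[Rcpp::export]]
SEXP walker_context(List spec) {
  WalkerCtx* cx = new WalkerCtx();
  cx->ch = chain_from_list(spec["chain"]);
  cx->belt_speed = as<double>(spec["belt_speed"]);

  List con = spec["contact"];
  cx->contact_on = as<bool>(con["enabled"]);
  NumericMatrix sph = con["spheres"];    // body(1-based), lx, ly, r
  for (int i = 0; i < sph.nrow(); ++i) {
    ContactSphere s; s.body = (int)sph(i, 0) - 1;
    s.local = v2(sph(i, 1), sph(i, 2)); s.r = sph(i, 3);
    cx->spheres.push_back(s);
  }
  cx->kc = as<double>(con["normal_stiffness"]);
  cx->cc = as<double>(con["normal_damping"]);
  cx->mu = as<double>(con["friction_coefficient"]);
  cx->vsmooth = as<double>(con["velocity_smoothing"]);
  cx->hc_exp = as<double>(con["exponent"]);

  List ref = spec["reference"];
  cx->T_cycle = as<double>(ref["cycle_duration"]);
  cx->a0 = as<arma::vec>(ref["a0"]);
  cx->A = as<arma::mat>(ref["A"]);
  cx->B = as<arma::mat>(ref["B"]);

  List ctl = spec["control"];
  cx->control_on = as<bool>(ctl["enabled"]);
  cx->integ_limit = as<double>(ctl["integrator_limit"]);
  NumericMatrix cm = ctl["joints"];  // rows by coordinate: mode refset phoff integ kp ki kd
  cx->ctl.assign(cx->ch.nq(), JointCtl());
  int ni = 0;
  for (int i = 0; i < cm.nrow(); ++i) {
    JointCtl c;
    int coord = (int)cm(i, 0) - 1;
    c.mode = (int)cm(i, 1); c.refset = (int)cm(i, 2); c.phoff = cm(i, 3);
    c.integ = (int)cm(i, 4) - 1; c.kp = cm(i, 5); c.ki = cm(i, 6); c.kd = cm(i, 7);
    c.kp2 = cm.ncol() > 8 ? cm(i, 8) : 0.0; c.kd2 = cm.ncol() > 9 ? cm(i, 9) : 0.0;
    if (c.integ + 1 > ni) ni = c.integ + 1;
    cx->ctl[coord] = c;
  }
  cx->n_integ = ni;

  List exo = spec["exo"];
  cx->exo_engaged = false;
  cx->exo_ratio = as<double>(exo["spool_ratio"]);
  cx->exo_kperkg = as<double>(exo["stiffness"]);
  cx->body_mass = as<double>(exo["body_mass"]);
  NumericVector an = exo["anchor"], spl = exo["spool_local"], shl = exo["shank_local"];
  cx->anchor = v2(an[0], an[1]);
  cx->spool_local = v2(spl[0], spl[1]);
  cx->shank_local = v2(shl[0], shl[1]);
  cx->foot_body = as<int>(exo["foot_body"]) - 1;
  cx->shank_body = as<int>(exo["shank_body"]) - 1;
  cx->snap_d0 = cx->snap_l0 = 0.0;

  XPtr<WalkerCtx> ptr(cx, true);
  return ptr;
}

// [[Rcpp::export]]
int walker_n_integ(SEXP xp) { return XPtr<WalkerCtx>(xp)->n_integ; }

// [[Rcpp::export]]
void walker_set_brake(SEXP xp, bool engaged, double d0, double l0) {
  XPtr<WalkerCtx> cx(xp);
  cx->exo_engaged = engaged; cx->snap_d0 = d0; cx->snap_l0 = l0;
}

// [[Rcpp::export]]
NumericVector walker_exo_dist(SEXP xp, NumericVector y) {
  XPtr<WalkerCtx> cx(xp);
  KinState ks;
  forward_kin(cx->ch, y.begin(), y.begin() + cx->ch.nq(), ks);
  int fb = cx->foot_body, sb = cx->shank_body;
  double ctf = std::cos(ks.th[fb]), stf = std::sin(ks.th[fb]);
  Vec2 Psp = ks.o[fb] + v2(ctf * cx->spool_local.x - stf * cx->spool_local.y,
                           stf * cx->spool_local.x + ctf * cx->spool_local.y);
  double cts = std::cos(ks.th[sb]), sts = std::sin(ks.th[sb]);
  Vec2 Psh = ks.o[sb] + v2(cts * cx->shank_local.x - sts * cx->shank_local.y,
                           sts * cx->shank_local.x + cts * cx->shank_local.y);
  return NumericVector::create(norm2(cx->anchor - Psp), norm2(Psh - Psp));
}

// [[Rcpp::export]]
NumericVector walker_rhs(SEXP xp, double t, NumericVector y) {
  XPtr<WalkerCtx> cx(xp);
  const Chain& ch = cx->ch;
  int nq = ch.nq();
  WalkerForces wf; KinState ks;
  compute_forces(*cx, t, y.begin(), wf, ks);
  arma::vec qdd = solve_accel(ch, ks, wf.Q);
  NumericVector dy(2 * nq + cx->n_integ);
  for (int k = 0; k < nq; ++k) { dy[k] = y[nq + k]; dy[nq + k] = qdd(k); }
  for (int k = 0; k < cx->n_integ; ++k) dy[2 * nq + k] = wf.ie_dot[k];
  return dy;
}

// Recompute reported signals (torques, GRFs, tendon force, ...) on a grid of
// stored states.  One row per time sample.
// [[Rcpp::export]]
NumericMatrix walker_outputs(SEXP xp, NumericVector times, NumericMatrix Y,
                             NumericVector engaged_flags, NumericMatrix snaps) {
  XPtr<WalkerCtx> cx(xp);
  int nq = cx->ch.nq();
  int nout = 9 + 4 + (int)cx->spheres.size() + 4 + 2;
  NumericMatrix out(times.size(), nout);
  WalkerForces wf; KinState ks;
  std::vector<double> yrow(Y.ncol());
  bool saved = cx->exo_engaged;
  double sd0 = cx->snap_d0, sl0 = cx->snap_l0;
  for (int i = 0; i < times.size(); ++i) {
    for (int j = 0; j < Y.ncol(); ++j) yrow[j] = Y(i, j);
    cx->exo_engaged = engaged_flags[i] > 0.5;
    cx->snap_d0 = snaps(i, 0); cx->snap_l0 = snaps(i, 1);
    compute_forces(*cx, times[i], yrow.data(), wf, ks);
    int k = 0;
    for (int j = 3; j < nq; ++j) out(i, k++) = wf.tau[j];
    out(i, k++) = wf.grf[0][0]; out(i, k++) = wf.grf[0][1];
    out(i, k++) = wf.grf[1][0]; out(i, k++) = wf.grf[1][1];
    for (size_t s = 0; s < cx->spheres.size(); ++s) out(i, k++) = wf.sphereFn[s];
    out(i, k++) = wf.F_el;  out(i, k++) = wf.elong;
    out(i, k++) = wf.tau_exo; out(i, k++) = wf.P_exo;
    out(i, k++) = ks.th[1];                       // HAT world orientation
    out(i, k++) = ks.c[0].y;                      // pelvis COM height
  }
  cx->exo_engaged = saved;
  cx->snap_d0 = sd0; cx->snap_l0 = sl0;
  return out;
}

// Total mechanical energy (kinetic + gravitational), for conservation audits.
// [[Rcpp::export]]
double walker_energy(SEXP xp, NumericVector y) {
  XPtr<WalkerCtx> cx(xp);
  const Chain& ch = cx->ch;
  KinState ks;
  forward_kin(ch, y.begin(), y.begin() + ch.nq(), ks);
  double E = 0;
  for (int b = 0; b < ch.nb; ++b) {
    E += 0.5 * ch.mass[b] * dot2(ks.vc[b], ks.vc[b]);
    E += 0.5 * ch.icom[b] * ks.w[b] * ks.w[b];
    E += ch.mass[b] * ch.gravity * ks.c[b].y;
  }
  return E;
}

// [[Rcpp::export]]
NumericMatrix walker_mass_matrix(SEXP xp, NumericVector q) {
  XPtr<WalkerCtx> cx(xp);
  std::vector<double> qd(cx->ch.nq(), 0.0);
  KinState ks;
  forward_kin(cx->ch, q.begin(), qd.data(), ks);
  arma::mat M = mass_matrix(cx->ch, ks);
  return wrap(M);
}

// World position and velocity of a body-fixed point.
// [[Rcpp::export]]
NumericVector walker_point_state(SEXP xp, int body, NumericVector local,
                                 NumericVector y) {
  XPtr<WalkerCtx> cx(xp);
  const Chain& ch = cx->ch;
  KinState ks;
  forward_kin(ch, y.begin(), y.begin() + ch.nq(), ks);
  int b = body - 1;
  double ct = std::cos(ks.th[b]), st = std::sin(ks.th[b]);
  Vec2 rl = v2(ct * local[0] - st * local[1], st * local[0] + ct * local[1]);
  Vec2 P = ks.o[b] + rl;
  Vec2 V = ks.vo[b] + ks.w[b] * perp(rl);
  return NumericVector::create(P.x, P.y, V.x, V.y, ks.th[b], ks.w[b]);
}
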