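// Fixed-step RK4 engine for the closed-loop cardiopulmonary model.
//
// State vector (23 entries):
//   0  V_sa   systemic arteries (ml)
//   1  V_sp   splanchnic peripheral
//   2  V_ep   extrasplanchnic peripheral
//   3  V_sv   splanchnic venous
//   4  V_ev   extrasplanchnic venous
//   5  V_vc   thoracic venae cavae (referenced to pleural pressure)
//   6  V_ra   right atrium
//   7  V_rv   right ventricle
//   8  V_pa   pulmonary arteries
//   9  V_pal  pulmonary arterioles
//   10 V_pc   pulmonary capillaries (referenced to alveolar pressure)
//   11 V_pv   pulmonary veins
//   12 V_la   left atrium
//   13 V_lv   left ventricle
//   14 Q_pa   inertance flow, pa -> pal branch (ml/s)
//   15 V_A    alveolar volume (l)
//   16 u      cardiac cycle clock in [0,1)
//   17 xPsa   low-pass filtered arterial pressure (baroafferent input)
//   18 sTs    filtered delayed sympathetic drive (heart period)
//   19 sTv    filtered delayed vagal firing (heart period)
//   20 sE     filtered delayed sympathetic drive (elastances)
//   21 sR     filtered delayed sympathetic drive (resistances)
//   22 sVu    filtered delayed sympathetic drive (venous unstressed vol.)
//
// Blood pressures in mmHg, airway pressures in cmH2O (converted with
// 1 mmHg = 1.35951 cmH2O), volumes ml (blood) / l (gas), time s.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NS = 23;
static const double CMH2O_PER_MMHG = 1.35951;

static inline double sq(double x) { return x * x; }
static inline double pmod(double x, double y) { return x - std::floor(x / y) * y; }
static inline double cexp(double x) { return std::exp(std::min(x, 50.0)); }

struct Params {
  // heart walls
  double E_max_lvf0, E_max_rvf0, E_max_spt0;
  double k_E_lvf, k_E_rvf, k_E_spt;
  double P_0_lvf, P_0_rvf, P_0_spt;
  double V_u_lvf, V_u_rvf, V_u_spt;
  double T_sys0, k_sys, k_R_lv, k_R_rv, R_mv, R_tv;
  // atria
  double E_ra_min, E_ra_max, V_u_ra, E_la_min, E_la_max, V_u_la;
  double atrial_lead;
  // pericardium
  double P_0_pcd, k_E_pcd, V_u_pcd, V_peri;
  // pulmonary
  double C_pa, V_u_pa, R_pa, L_pa, C_pal, C_pc, V_u_pal, V_u_pc;
  double C_pv, V_u_pv, R_pv, R_pp_tot, sh, FRC_nom;
  // systemic
  double C_sa, V_u_sa, C_sp, V_u_sp, C_ep, V_u_ep;
  double R_sa, R_sp0, R_ep0;
  double C_sv, V_u_sv0, C_ev, V_u_ev0, R_sv, R_ev;
  double C_vc, V_u_vc, R_vc, V_blood, BSA, cap_margin;
  // respiratory
  double R_aw, C_L, C_cw, V_u_L, V_u_cw, amp_mus, RR_spont;
  // ventilator
  int vent_mode; // 0 none, 1 PCV/PSV, 2 VCV
  double PEEP, support, RR, IE_ratio, end_insp_pause, vent_ramp;
  // control
  double T_0, tau_p, P_n, k_a, f_ab_min, f_ab_max;
  double f_es_inf, f_es_0, k_es, f_es_min, f_ev_0, f_ev_inf, f_ab_0, k_ev;
  double G_Ts, tau_Ts, D_Ts, G_Tv, tau_Tv, D_Tv;
  double G_E_lvf, G_E_rvf, G_E_spt, tau_E, D_E;
  double G_R_sp, G_R_ep, tau_R, D_R;
  double G_Vu_sv, G_Vu_ev, tau_Vu, D_Vu;
  bool ans_frozen;
  double ve_volume, ve_start, ve_duration;
};

static double getd(const List& p, const char* nm) {
  return as<double>(p[nm]);
}

static Params read_params(const List& p) {
  Params q;
  q.E_max_lvf0 = getd(p, "E_max_lvf0"); q.E_max_rvf0 = getd(p, "E_max_rvf0");
  q.E_max_spt0 = getd(p, "E_max_spt0");
  q.k_E_lvf = getd(p, "k_E_lvf"); q.k_E_rvf = getd(p, "k_E_rvf");
  q.k_E_spt = getd(p, "k_E_spt");
  q.P_0_lvf = getd(p, "P_0_lvf"); q.P_0_rvf = getd(p, "P_0_rvf");
  q.P_0_spt = getd(p, "P_0_spt");
  q.V_u_lvf = getd(p, "V_u_lvf"); q.V_u_rvf = getd(p, "V_u_rvf");
  q.V_u_spt = getd(p, "V_u_spt");
  q.T_sys0 = getd(p, "T_sys0"); q.k_sys = getd(p, "k_sys");
  q.k_R_lv = getd(p, "k_R_lv"); q.k_R_rv = getd(p, "k_R_rv");
  q.R_mv = getd(p, "R_mv"); q.R_tv = getd(p, "R_tv");
  q.E_ra_min = getd(p, "E_ra_min"); q.E_ra_max = getd(p, "E_ra_max");
  q.V_u_ra = getd(p, "V_u_ra");
  q.E_la_min = getd(p, "E_la_min"); q.E_la_max = getd(p, "E_la_max");
  q.V_u_la = getd(p, "V_u_la"); q.atrial_lead = getd(p, "atrial_lead");
  q.P_0_pcd = getd(p, "P_0_pcd"); q.k_E_pcd = getd(p, "k_E_pcd");
  q.V_u_pcd = getd(p, "V_u_pcd"); q.V_peri = getd(p, "V_peri");
  q.C_pa = getd(p, "C_pa"); q.V_u_pa = getd(p, "V_u_pa");
  q.R_pa = getd(p, "R_pa"); q.L_pa = getd(p, "L_pa");
  q.C_pal = getd(p, "C_pal"); q.C_pc = getd(p, "C_pc");
  q.V_u_pal = getd(p, "V_u_pal"); q.V_u_pc = getd(p, "V_u_pc");
  q.C_pv = getd(p, "C_pv"); q.V_u_pv = getd(p, "V_u_pv");
  q.R_pv = getd(p, "R_pv"); q.R_pp_tot = getd(p, "R_pp_tot");
  q.sh = getd(p, "sh"); q.FRC_nom = getd(p, "FRC_nom");
  q.C_sa = getd(p, "C_sa"); q.V_u_sa = getd(p, "V_u_sa");
  q.C_sp = getd(p, "C_sp"); q.V_u_sp = getd(p, "V_u_sp");
  q.C_ep = getd(p, "C_ep"); q.V_u_ep = getd(p, "V_u_ep");
  q.R_sa = getd(p, "R_sa");
  q.R_sp0 = getd(p, "R_sp0"); q.R_ep0 = getd(p, "R_ep0");
  q.C_sv = getd(p, "C_sv"); q.V_u_sv0 = getd(p, "V_u_sv0");
  q.C_ev = getd(p, "C_ev"); q.V_u_ev0 = getd(p, "V_u_ev0");
  q.R_sv = getd(p, "R_sv"); q.R_ev = getd(p, "R_ev");
  q.C_vc = getd(p, "C_vc"); q.V_u_vc = getd(p, "V_u_vc");
  q.R_vc = getd(p, "R_vc");
  q.V_blood = getd(p, "V_blood"); q.BSA = getd(p, "BSA");
  q.cap_margin = getd(p, "cap_margin");
  q.R_aw = getd(p, "R_aw"); q.C_L = getd(p, "C_L"); q.C_cw = getd(p, "C_cw");
  q.V_u_L = getd(p, "V_u_L"); q.V_u_cw = getd(p, "V_u_cw");
  q.amp_mus = getd(p, "amp_mus"); q.RR_spont = getd(p, "RR_spont");
  std::string vm = as<std::string>(p["vent_mode"]);
  q.vent_mode = (vm == "none") ? 0 : (vm == "VCV" ? 2 : 1);
  q.PEEP = getd(p, "PEEP"); q.support = getd(p, "support");
  q.RR = getd(p, "RR"); q.IE_ratio = getd(p, "IE_ratio");
  q.end_insp_pause = getd(p, "end_insp_pause");
  q.vent_ramp = getd(p, "vent_ramp");
  q.T_0 = getd(p, "T_0"); q.tau_p = getd(p, "tau_p");
  q.P_n = getd(p, "P_n"); q.k_a = getd(p, "k_a");
  q.f_ab_min = getd(p, "f_ab_min"); q.f_ab_max = getd(p, "f_ab_max");
  q.f_es_inf = getd(p, "f_es_inf"); q.f_es_0 = getd(p, "f_es_0");
  q.k_es = getd(p, "k_es"); q.f_es_min = getd(p, "f_es_min");
  q.f_ev_0 = getd(p, "f_ev_0"); q.f_ev_inf = getd(p, "f_ev_inf");
  q.f_ab_0 = getd(p, "f_ab_0"); q.k_ev = getd(p, "k_ev");
  q.G_Ts = getd(p, "G_Ts"); q.tau_Ts = getd(p, "tau_Ts");
  q.D_Ts = getd(p, "D_Ts");
  q.G_Tv = getd(p, "G_Tv"); q.tau_Tv = getd(p, "tau_Tv");
  q.D_Tv = getd(p, "D_Tv");
  q.G_E_lvf = getd(p, "G_E_lvf"); q.G_E_rvf = getd(p, "G_E_rvf");
  q.G_E_spt = getd(p, "G_E_spt");
  q.tau_E = getd(p, "tau_E"); q.D_E = getd(p, "D_E");
  q.G_R_sp = getd(p, "G_R_sp"); q.G_R_ep = getd(p, "G_R_ep");
  q.tau_R = getd(p, "tau_R"); q.D_R = getd(p, "D_R");
  q.G_Vu_sv = getd(p, "G_Vu_sv"); q.G_Vu_ev = getd(p, "G_Vu_ev");
  q.tau_Vu = getd(p, "tau_Vu"); q.D_Vu = getd(p, "D_Vu");
  q.ans_frozen = as<bool>(p["ans_frozen"]);
  q.ve_volume = getd(p, "ve_volume"); q.ve_start = getd(p, "ve_start");
  q.ve_duration = getd(p, "ve_duration");
  return q;
}

// ---- waveforms -----------------------------------------------------------

static double vent_pressure(double t, const Params& p) {
  if (p.vent_mode == 0) return 0.0;
  double Tb = 60.0 / p.RR;
  double Ti = Tb * p.IE_ratio / (1.0 + p.IE_ratio);
  double r = p.vent_ramp;
  double plateau_end = std::min(Ti + p.end_insp_pause, Tb - 2.0 * r);
  double tb = pmod(t, Tb);
  double up;
  if (p.vent_mode == 2)
    up = std::min(tb / std::max(Ti, r), 1.0);
  else
    up = (tb < r) ? (1.0 - std::cos(M_PI * tb / r)) / 2.0 : 1.0;
  double frac;
  if (tb < plateau_end) frac = up;
  else if (tb < plateau_end + r)
    frac = (1.0 + std::cos(M_PI * (tb - plateau_end) / r)) / 2.0;
  else frac = 0.0;
  return p.PEEP + p.support * frac;
}

static double mus_pressure(double t, const Params& p) {
  if (p.amp_mus == 0.0) return 0.0;
  double Tr = 60.0 / p.RR_spont;
  double Ti = Tr / 3.0;
  double tb = pmod(t, Tr);
  return (tb < Ti) ? p.amp_mus * std::sin(M_PI * tb / Ti) : 0.0;
}

// ---- baroreflex static maps ---------------------------------------------

struct Reflex { double f_ab, f_es, f_ev, L; };

static Reflex reflex_static(double P, const Params& p) {
  Reflex r;
  double ex = cexp((P - p.P_n) / p.k_a);
  r.f_ab = (p.f_ab_min + p.f_ab_max * ex) / (1.0 + ex);
  r.f_es = p.f_es_inf + (p.f_es_0 - p.f_es_inf) * cexp(-p.k_es * r.f_ab);
  double exv = cexp((r.f_ab - p.f_ab_0) / p.k_ev);
  r.f_ev = (p.f_ev_0 + p.f_ev_inf * exv) / (1.0 + exv);
  r.L = std::log(std::max(r.f_es - p.f_es_min, 0.0) + 1.0);
  return r;
}

// ---- septal volume (algebraic) ------------------------------------------

static inline double wallP(double V, double phi, double Emax, double Vu,
                           double P0, double kE) {
  return phi * Emax * (V - Vu) + (1.0 - phi) * P0 * (cexp(kE * V) - 1.0);
}
static inline double wallPd(double V, double phi, double Emax,
                            double P0, double kE) {
  return phi * Emax + (1.0 - phi) * P0 * kE * cexp(kE * V);
}

static double solve_vspt(double Vlv, double Vrv, double phi,
                         double Elvf, double Ervf, double Espt,
                         const Params& p, double warm) {
  double lo = -Vrv - 100.0, hi = Vlv + 100.0;
  double vs = warm;
  if (vs <= lo || vs >= hi) vs = 0.0;
  for (int it = 0; it < 100; ++it) {
    double g = wallP(vs, phi, Espt, p.V_u_spt, p.P_0_spt, p.k_E_spt)
             - wallP(Vlv - vs, phi, Elvf, p.V_u_lvf, p.P_0_lvf, p.k_E_lvf)
             + wallP(Vrv + vs, phi, Ervf, p.V_u_rvf, p.P_0_rvf, p.k_E_rvf);
    if (std::fabs(g) < 1e-9) return vs;
    if (g > 0) hi = vs; else lo = vs;
    double gp = wallPd(vs, phi, Espt, p.P_0_spt, p.k_E_spt)
              + wallPd(Vlv - vs, phi, Elvf, p.P_0_lvf, p.k_E_lvf)
              + wallPd(Vrv + vs, phi, Ervf, p.P_0_rvf, p.k_E_rvf);
    double vn = vs - g / gp;
    if (!std::isfinite(vn) || vn <= lo || vn >= hi) vn = 0.5 * (lo + hi);
    vs = vn;
  }
  return vs;
}

// ---- derived signals -----------------------------------------------------

struct Derived {
  double Psa, Ppa, Ppal, Ppc, Ppv, Pla, Pra, Plv, Prv, Pperi;
  double Ppl_cm, PA_cm, Pao_cm, Pmus_cm;
  double Vspt, phi;
  double Qav, Qmv, Qtv, Qrvo, Qpal, Qpc, Qps, Qpv, Qvc;
  double Emax_lvf, Emax_rvf, Emax_spt, Rsp, Rep, Vusv, Vuev, Rpal;
  double Vblood;
};

struct DelayedIn { double L_Ts, L_E, L_R, L_Vu, fev; };

// Evaluates algebra + derivatives at (t, y) given beat-constant heart
// period T and delayed sympathetic/vagal inputs.
static void derivs(double t, const double* y, double T,
                   const DelayedIn& din, const Params& p,
                   double* dy, Derived& d, double& vspt_warm) {
  // effective (ANS-modulated) values
  d.Emax_lvf = std::max(0.01, p.E_max_lvf0 + p.G_E_lvf * y[20]);
  d.Emax_rvf = std::max(0.01, p.E_max_rvf0 + p.G_E_rvf * y[20]);
  d.Emax_spt = std::max(0.01, p.E_max_spt0 + p.G_E_spt * y[20]);
  d.Rsp = std::max(1e-4, p.R_sp0 + p.G_R_sp * y[21]);
  d.Rep = std::max(1e-4, p.R_ep0 + p.G_R_ep * y[21]);
  d.Vusv = std::max(0.0, p.V_u_sv0 + p.G_Vu_sv * y[22]);
  d.Vuev = std::max(0.0, p.V_u_ev0 + p.G_Vu_ev * y[22]);

  // respiratory mechanics (cmH2O, l)
  double VA = y[15];
  d.Pao_cm = vent_pressure(t, p);
  d.Pmus_cm = mus_pressure(t, p);
  d.Ppl_cm = (VA - p.V_u_cw) / p.C_cw - d.Pmus_cm;
  d.PA_cm = d.Ppl_cm + (VA - p.V_u_L) / p.C_L;
  double dVA = (d.Pao_cm - d.PA_cm) / p.R_aw;
  double Ppl = d.Ppl_cm / CMH2O_PER_MMHG;
  double PA = d.PA_cm / CMH2O_PER_MMHG;

  // activation
  double Tsys = p.T_sys0 - p.k_sys / T;
  double tc = y[16] * T;
  d.phi = (tc >= 0 && tc <= Tsys) ? sq(std::sin(M_PI * tc / Tsys)) : 0.0;
  double Tsys_a = 2.0 * p.atrial_lead * T;
  double ta = pmod(y[16] + p.atrial_lead, 1.0) * T;
  double phia = (Tsys_a > 0 && ta <= Tsys_a)
    ? sq(std::sin(M_PI * ta / Tsys_a)) : 0.0;

  // pericardium
  double Vtot = y[12] + y[6] + y[13] + y[7] + p.V_peri;
  double Ppcd = p.P_0_pcd * (cexp(p.k_E_pcd * (Vtot - p.V_u_pcd)) - 1.0);
  d.Pperi = Ppl + Ppcd;

  // septum and free-wall pressures
  double Vlv = y[13], Vrv = y[7];
  d.Vspt = solve_vspt(Vlv, Vrv, d.phi, d.Emax_lvf, d.Emax_rvf, d.Emax_spt,
                      p, vspt_warm);
  vspt_warm = d.Vspt;
  double Vlvf = Vlv - d.Vspt, Vrvf = Vrv + d.Vspt;
  double Pmaxlvf = wallP(Vlvf, d.phi, d.Emax_lvf, p.V_u_lvf,
                         p.P_0_lvf, p.k_E_lvf);
  double Pmaxrvf = wallP(Vrvf, d.phi, d.Emax_rvf, p.V_u_rvf,
                         p.P_0_rvf, p.k_E_rvf);
  double Pmaxlv = Pmaxlvf + d.Pperi;
  double Pmaxrv = Pmaxrvf + d.Pperi;

  // atria (variable elastance, no inter-atrial interaction)
  double Era = p.E_ra_min + phia * (p.E_ra_max - p.E_ra_min);
  double Ela = p.E_la_min + phia * (p.E_la_max - p.E_la_min);
  d.Pra = Era * (y[6] - p.V_u_ra) + d.Pperi;
  d.Pla = Ela * (y[12] - p.V_u_la) + d.Pperi;

  // node pressures
  d.Psa = (y[0] - p.V_u_sa) / p.C_sa;
  double Psp = (y[1] - p.V_u_sp) / p.C_sp;
  double Pep = (y[2] - p.V_u_ep) / p.C_ep;
  double Psv = (y[3] - d.Vusv) / p.C_sv;
  double Pev = (y[4] - d.Vuev) / p.C_ev;
  double Pvc = (y[5] - p.V_u_vc) / p.C_vc + Ppl;
  d.Ppa = (y[8] - p.V_u_pa) / p.C_pa + Ppl;
  d.Ppal = (y[9] - p.V_u_pal) / p.C_pal + Ppl;
  d.Ppc = (y[10] - p.V_u_pc) / p.C_pc + PA;
  d.Ppv = (y[11] - p.V_u_pv) / p.C_pv + Ppl;

  // valves (ideal diodes with flow-proportional viscous resistance)
  d.Qav = 0.0;
  if (Pmaxlv > d.Psa && Pmaxlv > 0)
    d.Qav = (Pmaxlv - d.Psa) / (p.k_R_lv * Pmaxlv);
  d.Plv = Pmaxlv - p.k_R_lv * Pmaxlv * d.Qav;
  d.Qrvo = 0.0;
  if (Pmaxrv > d.Ppa && Pmaxrv > 0)
    d.Qrvo = (Pmaxrv - d.Ppa) / (p.k_R_rv * Pmaxrv);
  d.Prv = Pmaxrv - p.k_R_rv * Pmaxrv * d.Qrvo;
  d.Qmv = (d.Pla > d.Plv) ? (d.Pla - d.Plv) / p.R_mv : 0.0;
  d.Qtv = (d.Pra > d.Prv) ? (d.Pra - d.Prv) / p.R_tv : 0.0;

  // systemic flows: small arterial resistance feeds both peripheral
  // beds; the ANS-controlled peripheral resistances drain them into the
  // venous compartments
  double Qsp = (d.Psa - Psp) / (2.0 * p.R_sa);
  double Qep = (d.Psa - Pep) / (2.0 * p.R_sa);
  double Qspv = (Psp - Psv) / d.Rsp;
  double Qepv = (Pep - Pev) / d.Rep;
  double Qsv = (Psv - Pvc) / p.R_sv;
  double Qev = (Pev - Pvc) / p.R_ev;
  d.Qvc = (Pvc - d.Pra) / p.R_vc;

  // pulmonary flows
  d.Rpal = p.R_pp_tot / (2.0 * (1.0 - p.sh)) * sq(VA / p.FRC_nom);
  double Rpc = p.R_pp_tot / (2.0 * (1.0 - p.sh));
  // capillary squeeze: once the bed is compressed below a critical
  // volume (transmural reserve cap_margin above unstressed) the
  // post-capillary resistance rises as 1/V^2 (Poiseuille), throttling
  // further emptying; inactive at the resting operating point
  double Vpc_ = std::max(y[10], 1.0);
  double Vcrit = p.V_u_pc + p.cap_margin * p.C_pc;
  if (Vpc_ < Vcrit) Rpc *= sq(Vcrit / Vpc_);
  d.Qpal = (d.Ppal - d.Ppc) / d.Rpal;
  d.Qpc = (d.Ppc - d.Ppv) / Rpc;
  d.Qps = (p.sh > 0) ? (d.Ppal - d.Ppv) * p.sh / p.R_pp_tot : 0.0;
  d.Qpv = (d.Ppv - d.Pla) / p.R_pv;

  // volume expansion infusion into extrasplanchnic veins
  double ve = 0.0;
  if (p.ve_volume > 0 && t >= p.ve_start && t < p.ve_start + p.ve_duration)
    ve = p.ve_volume / p.ve_duration;

  dy[0] = d.Qav - Qsp - Qep;
  dy[1] = Qsp - Qspv;
  dy[2] = Qep - Qepv;
  dy[3] = Qspv - Qsv;
  dy[4] = Qepv - Qev + ve;
  dy[5] = Qsv + Qev - d.Qvc;
  dy[6] = d.Qvc - d.Qtv;
  dy[7] = d.Qtv - d.Qrvo;
  dy[8] = d.Qrvo - y[14];
  dy[9] = y[14] - d.Qpal - d.Qps;
  dy[10] = d.Qpal - d.Qpc;
  dy[11] = d.Qpc + d.Qps - d.Qpv;
  dy[12] = d.Qpv - d.Qmv;
  dy[13] = d.Qmv - d.Qav;
  dy[14] = (d.Ppa - d.Ppal - p.R_pa * y[14]) / p.L_pa;
  dy[15] = dVA;
  dy[16] = 1.0 / T;
  dy[17] = (d.Psa - y[17]) / p.tau_p;
  dy[18] = (din.L_Ts - y[18]) / p.tau_Ts;
  dy[19] = (din.fev - y[19]) / p.tau_Tv;
  dy[20] = (din.L_E - y[20]) / p.tau_E;
  dy[21] = (din.L_R - y[21]) / p.tau_R;
  dy[22] = (din.L_Vu - y[22]) / p.tau_Vu;

  double vb = 0.0;
  for (int i = 0; i < 14; ++i) vb += y[i];
  d.Vblood = vb;
}

// ---- history ring buffer for delayed reflex signals ----------------------

struct History {
  std::vector<double> L, fev;
  int n, head; // head = index of the slot for the *current* step
  double dt;
  void init(int size, double L0, double f0, double dt_) {
    n = size; head = 0; dt = dt_;
    L.assign(n, L0); fev.assign(n, f0);
  }
  void push(double Lv, double fv) {
    head = (head + 1) % n;
    L[head] = Lv; fev[head] = fv;
  }
  double lookL(double delay) const {
    int k = (int)std::lround(delay / dt);
    if (k >= n) k = n - 1;
    return L[(head - k % n + n) % n];
  }
  double lookF(double delay) const {
    int k = (int)std::lround(delay / dt);
    if (k >= n) k = n - 1;
    return fev[(head - k % n + n) % n];
  }
};

static const char* TS_COLS[] = {
  "t", "P_sa", "P_pa", "P_pal", "P_pc", "P_pv", "P_la", "P_ra", "P_lv",
  "P_rv", "P_peri", "P_pl", "P_A", "P_ao", "P_mus", "V_A", "V_lv", "V_rv",
  "V_la", "V_ra", "V_spt", "Q_av", "Q_mv", "Q_tv", "Q_rvo", "Q_pa",
  "Q_pal", "Q_pc", "Q_ps", "Q_pv", "Q_vc", "u", "T", "phi",
  "E_max_lvf", "E_max_rvf", "E_max_spt", "R_sp", "R_ep", "V_blood"
};
static const int NTS = 40;

static void fill_row(double* row, double t, const double* y, double T,
                     const Derived& d) {
  row[0] = t; row[1] = d.Psa; row[2] = d.Ppa; row[3] = d.Ppal;
  row[4] = d.Ppc; row[5] = d.Ppv; row[6] = d.Pla; row[7] = d.Pra;
  row[8] = d.Plv; row[9] = d.Prv; row[10] = d.Pperi; row[11] = d.Ppl_cm;
  row[12] = d.PA_cm; row[13] = d.Pao_cm; row[14] = d.Pmus_cm;
  row[15] = y[15]; row[16] = y[13]; row[17] = y[7]; row[18] = y[12];
  row[19] = y[6]; row[20] = d.Vspt; row[21] = d.Qav; row[22] = d.Qmv;
  row[23] = d.Qtv; row[24] = d.Qrvo; row[25] = y[14]; row[26] = d.Qpal;
  row[27] = d.Qpc; row[28] = d.Qps; row[29] = d.Qpv; row[30] = d.Qvc;
  row[31] = y[16]; row[32] = T; row[33] = d.phi; row[34] = d.Emax_lvf;
  row[35] = d.Emax_rvf; row[36] = d.Emax_spt; row[37] = d.Rsp;
  row[38] = d.Rep; row[39] = d.Vblood;
}

static const char* BEAT_COLS[] = {
  "t_start", "t_end", "T", "EDV_lv", "ESV_lv", "EDV_rv", "ESV_rv",
  "P_sa_max", "P_sa_min", "P_sa_mean", "P_pa_mean", "P_lv_max", "P_rv_max",
  "P_lv_ed", "P_rv_ed", "P_la_mean", "P_ra_mean", "V_spt_mean",
  "Ptm_es_lv", "Ptm_es_rv", "P_pl_start", "P_ao_start", "V_A_start",
  "P_peri_mean", "E_max_lvf", "E_max_rvf", "P_pa_max", "P_pa_min"
};
static const int NBEAT = 28;

struct BeatAcc {
  double t_start, T;
  double edv_lv, esv_lv, edv_rv, esv_rv;
  double psa_max, psa_min, psa_sum, ppa_sum, ppa_max, ppa_min;
  double plv_max, prv_max, plv_ed, prv_ed;
  double pla_sum, pra_sum, vspt_sum, pperi_sum;
  double ptm_es_lv, ptm_es_rv;
  double ppl_start, pao_start, va_start;
  double emax_lvf, emax_rvf;
  int nsum;
  void start(double t, double Tbeat, const double* y, const Derived& d) {
    t_start = t; T = Tbeat;
    edv_lv = y[13]; esv_lv = y[13]; edv_rv = y[7]; esv_rv = y[7];
    psa_max = psa_min = d.Psa;
    ppa_max = ppa_min = d.Ppa;
    psa_sum = ppa_sum = pla_sum = pra_sum = vspt_sum = pperi_sum = 0.0;
    plv_max = d.Plv; prv_max = d.Prv; plv_ed = d.Plv; prv_ed = d.Prv;
    ptm_es_lv = d.Plv - d.Pperi; ptm_es_rv = d.Prv - d.Pperi;
    ppl_start = d.Ppl_cm; pao_start = d.Pao_cm; va_start = y[15];
    emax_lvf = d.Emax_lvf; emax_rvf = d.Emax_rvf;
    nsum = 0;
  }
  void add(const double* y, const Derived& d) {
    if (y[13] < esv_lv) { esv_lv = y[13]; ptm_es_lv = d.Plv - d.Pperi; }
    if (y[7] < esv_rv) { esv_rv = y[7]; ptm_es_rv = d.Prv - d.Pperi; }
    if (d.Psa > psa_max) psa_max = d.Psa;
    if (d.Psa < psa_min) psa_min = d.Psa;
    if (d.Ppa > ppa_max) ppa_max = d.Ppa;
    if (d.Ppa < ppa_min) ppa_min = d.Ppa;
    if (d.Plv > plv_max) plv_max = d.Plv;
    if (d.Prv > prv_max) prv_max = d.Prv;
    psa_sum += d.Psa; ppa_sum += d.Ppa; pla_sum += d.Pla; pra_sum += d.Pra;
    vspt_sum += d.Vspt; pperi_sum += d.Pperi;
    ++nsum;
  }
  void finish(double t_end, std::vector<double>& out) const {
    double inv = nsum > 0 ? 1.0 / nsum : 0.0;
    double row[NBEAT] = {
      t_start, t_end, T, edv_lv, esv_lv, edv_rv, esv_rv,
      psa_max, psa_min, psa_sum * inv, ppa_sum * inv, plv_max, prv_max,
      plv_ed, prv_ed, pla_sum * inv, pra_sum * inv, vspt_sum * inv,
      ptm_es_lv, ptm_es_rv, ppl_start, pao_start, va_start,
      pperi_sum * inv, emax_lvf, emax_rvf, ppa_max, ppa_min
    };
    out.insert(out.end(), row, row + NBEAT);
  }
};

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector y0, double T_beat, List params,
                double duration, double dt, double record_dt) {
  if (y0.size() != NS) stop("state vector must have %d entries", NS);
  Params p = read_params(params);
  if (dt <= 0) stop("dt must be positive");
  long nsteps = (long)std::llround(duration / dt);
  int record_every = std::max(1, (int)std::lround(record_dt / dt));

  double y[NS], yt[NS];
  double k1[NS], k2[NS], k3[NS], k4[NS];
  for (int i = 0; i < NS; ++i) y[i] = y0[i];
  double T = T_beat > 0 ? T_beat : p.T_0;

  // delayed-signal history, primed with the signal implied by y0
  Reflex r0 = reflex_static(y[17], p);
  Reflex rb = reflex_static(p.P_n, p);
  double maxD = std::max(std::max(p.D_Ts, p.D_Tv),
                std::max(std::max(p.D_E, p.D_R), p.D_Vu));
  History hist;
  hist.init((int)(maxD / dt) + 4,
            p.ans_frozen ? rb.L : r0.L,
            p.ans_frozen ? rb.f_ev : r0.f_ev, dt);

  std::vector<double> ts;
  ts.reserve((nsteps / record_every + 2) * NTS);
  std::vector<double> beats;
  std::vector<double> breath_starts;
  double vspt_warm = 0.0;
  Derived d;
  DelayedIn din;

  // breathing period for breath-event logging
  double Tb = 0.0;
  if (p.vent_mode != 0) Tb = 60.0 / p.RR;
  else if (p.amp_mus != 0.0) Tb = 60.0 / p.RR_spont;
  if (Tb > 0) breath_starts.push_back(0.0);

  BeatAcc beat;
  bool beat_open = false;

  double t = 0.0;
  for (long step = 0; step <= nsteps; ++step) {
    // stage-time delayed inputs (delays >> dt, so history suffices)
    if (p.ans_frozen) {
      din.L_Ts = din.L_E = din.L_R = din.L_Vu = rb.L;
      din.fev = rb.f_ev;
    } else {
      din.L_Ts = hist.lookL(p.D_Ts);
      din.L_E = hist.lookL(p.D_E);
      din.L_R = hist.lookL(p.D_R);
      din.L_Vu = hist.lookL(p.D_Vu);
      din.fev = hist.lookF(p.D_Tv);
    }

    derivs(t, y, T, din, p, k1, d, vspt_warm);

    if (!beat_open) { beat.start(t, T, y, d); beat_open = true; }
    beat.add(y, d);

    if (step % record_every == 0) {
      double row[NTS];
      fill_row(row, t, y, T, d);
      ts.insert(ts.end(), row, row + NTS);
    }
    if (!std::isfinite(d.Psa) || !std::isfinite(y[13]))
      stop("integration failure at t = %g s (non-finite state)", t);
    if (step == nsteps) break;

    // RK4
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    derivs(t + 0.5 * dt, yt, T, din, p, k2, d, vspt_warm);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    derivs(t + 0.5 * dt, yt, T, din, p, k3, d, vspt_warm);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + dt * k3[i];
    derivs(t + dt, yt, T, din, p, k4, d, vspt_warm);
    for (int i = 0; i < NS; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    double t_new = t + dt;

    // update delayed-signal history with the *current* (end-of-step) state
    Reflex rr = reflex_static(y[17], p);
    hist.push(rr.L, rr.f_ev);

    // cardiac-cycle rollover: refresh heart period, close the beat
    if (y[16] >= 1.0) {
      y[16] -= 1.0;
      beat.finish(t_new, beats);
      beat_open = false;
      double Tt = p.T_0 + p.G_Ts * y[18] + p.G_Tv * y[19];
      T = std::min(std::max(Tt, 0.2), 3.0);
    }

    // breath onset logging
    if (Tb > 0 && pmod(t_new, Tb) < pmod(t, Tb))
      breath_starts.push_back(std::floor(t_new / Tb + 0.5) * Tb);

    t = t_new;
  }

  int nrow_ts = ts.size() / NTS;
  NumericMatrix tsm(NTS, nrow_ts);
  std::copy(ts.begin(), ts.end(), tsm.begin());
  int nrow_b = beats.size() / NBEAT;
  NumericMatrix bm(NBEAT, nrow_b);
  std::copy(beats.begin(), beats.end(), bm.begin());

  CharacterVector tsc(NTS), bc(NBEAT);
  for (int i = 0; i < NTS; ++i) tsc[i] = TS_COLS[i];
  for (int i = 0; i < NBEAT; ++i) bc[i] = BEAT_COLS[i];

  NumericVector yf(NS);
  for (int i = 0; i < NS; ++i) yf[i] = y[i];

  return List::create(
    _["ts"] = tsm, _["ts_cols"] = tsc,
    _["beats"] = bm, _["beat_cols"] = bc,
    _["breath_starts"] = NumericVector(breath_starts.begin(),
                                       breath_starts.end()),
    _["final_state"] = yf, _["final_T"] = T, _["t_end"] = t);
}

// [[Rcpp::export(name = ".engine_derivs")]]
List engine_derivs(NumericVector y, double T_beat, List params, double t) {
  if (y.size() != NS) stop("state vector must have %d entries", NS);
  Params p = read_params(params);
  Reflex rb = reflex_static(p.P_n, p);
  DelayedIn din; // setpoint-basal delayed inputs for pointwise evaluation
  din.L_Ts = din.L_E = din.L_R = din.L_Vu = rb.L;
  din.fev = rb.f_ev;
  double dy[NS];
  Derived d;
  double warm = 0.0;
  derivs(t, &y[0], T_beat > 0 ? T_beat : p.T_0, din, p, dy, d, warm);
  NumericVector dyv(NS);
  for (int i = 0; i < NS; ++i) dyv[i] = dy[i];
  NumericVector row(NTS);
  fill_row(&row[0], t, &y[0], T_beat > 0 ? T_beat : p.T_0, d);
  CharacterVector tsc(NTS);
  for (int i = 0; i < NTS; ++i) tsc[i] = TS_COLS[i];
  row.names() = tsc;
  return List::create(_["dy"] = dyv, _["derived"] = row);
}

// [[Rcpp::export(name = ".engine_vspt")]]
double engine_vspt(double V_lv, double V_rv, double phi, List params,
                   double E_max_lvf, double E_max_rvf, double E_max_spt) {
  Params p = read_params(params);
  return solve_vspt(V_lv, V_rv, phi, E_max_lvf, E_max_rvf, E_max_spt,
                    p, 0.0);
}
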