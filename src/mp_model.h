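#ifndef MP_MODEL_H
#define MP_MODEL_H

#include <vector>
#include <cmath>
#include <cstring>
#include <string>
#include <stdexcept>

// ---------------------------------------------------------------------------
// Coarse-grained membrane-protein model.
//
// Degrees of freedom: backbone sites N, CA, C per residue, stored in a flat
// array x of length 9*n  (residue i -> x[9i+0..2]=N, x[9i+3..5]=CA,
// x[9i+6..8]=C).  Amide H, carbonyl O and the side-chain bead CB are pure
// functions of the backbone; their energy gradients are chain-ruled back onto
// N/CA/C.  Energies are in kBT, lengths in Angstrom, membrane midplane z = 0.
// ---------------------------------------------------------------------------

namespace mp {

// ---- small vector helpers -------------------------------------------------
inline void vset(double* a, double x, double y, double z) { a[0]=x; a[1]=y; a[2]=z; }
inline void vcopy(double* a, const double* b) { a[0]=b[0]; a[1]=b[1]; a[2]=b[2]; }
inline void vsub(double* o, const double* a, const double* b) { o[0]=a[0]-b[0]; o[1]=a[1]-b[1]; o[2]=a[2]-b[2]; }
inline void vadd(double* o, const double* a, const double* b) { o[0]=a[0]+b[0]; o[1]=a[1]+b[1]; o[2]=a[2]+b[2]; }
inline void vaxpy(double* o, double s, const double* a) { o[0]+=s*a[0]; o[1]+=s*a[1]; o[2]+=s*a[2]; }
inline double vdot(const double* a, const double* b) { return a[0]*b[0]+a[1]*b[1]+a[2]*b[2]; }
inline double vnorm2(const double* a) { return vdot(a,a); }
inline double vnorm(const double* a) { return std::sqrt(vnorm2(a)); }
inline void vscale(double* a, double s) { a[0]*=s; a[1]*=s; a[2]*=s; }
inline void vcross(double* o, const double* a, const double* b) {
    o[0]=a[1]*b[2]-a[2]*b[1]; o[1]=a[2]*b[0]-a[0]*b[2]; o[2]=a[0]*b[1]-a[1]*b[0];
}
// g_v += s * (I - u u^T)/|v| * g   where u = v/|v|
inline void proj_accum(double* gv, const double* u, double invlen, const double* g, double s) {
    double d = vdot(u, g);
    gv[0] += s * invlen * (g[0] - d*u[0]);
    gv[1] += s * invlen * (g[1] - d*u[1]);
    gv[2] += s * invlen * (g[2] - d*u[2]);
}

// ---- C1 switching functions ------------------------------------------------
inline double sstep(double t) { if (t <= 0) return 0; if (t >= 1) return 1; return t*t*(3 - 2*t); }
inline double dsstep(double t) { if (t <= 0 || t >= 1) return 0; return 6*t*(1 - t); }
// 1 for d<=a, 0 for d>=b
inline double sw_down(double d, double a, double b) { return sstep((b - d)/(b - a)); }
inline double dsw_down(double d, double a, double b) { return -dsstep((b - d)/(b - a))/(b - a); }
// 0 for c<=a, 1 for c>=b
inline double sw_up(double c, double a, double b) { return sstep((c - a)/(b - a)); }
inline double dsw_up(double c, double a, double b) { return dsstep((c - a)/(b - a))/(b - a); }

// ---- parameters -------------------------------------------------------------
struct Params {
    double lambda_hb = 1.0, lambda_pp = 1.0, lambda_memb = 1.0;
    double eps_hb = 1.5, eps_contact = 1.0, eps_burial = 0.5, eps_burial_bb = 0.25;
    double nonnative_hb_scale = 0.7;   // Go-type bias: non-native H-bonds are shallower
    double eps_unsat = 2.0, hb_core_bonus = 0.3;
    double hb_dist_cutoff = 3.0, hb_dist_inner = 2.2;    // H...O switch knots
    double hb_cos_lo = 0.766, hb_cos_hi = 0.940;         // -cos(angle NHO) switch knots
    double contact_cutoff = 8.0, contact_well_width = 2.0;
    double ev_diameter = 4.0, ev_diameter_ca = 3.6, eps_rep = 20.0;
    double burial_r_on = 6.5, burial_r_off = 9.5;
    double n_sat = 6.0, sat_ref = 0.6, shield_max = 0.6;
    double memb_thickness = 31.8, memb_width = 3.0;
    bool include_linker_membrane = true;
    double k_bond = 60.0, k_angle = 40.0;
    double k_tors_phi = 0.5, k_tors_psi = 0.5, k_tors_omega = 5.0;
};

// residue roles
enum Role { ROLE_TM = 0, ROLE_LINKER = 1, ROLE_TAIL = 2 };

struct Topology {
    int n = 0;
    std::vector<int> role;       // Role codes
    std::vector<int> helix;      // 0-based helix id, -1 if none
    std::vector<double> dG;      // water -> bilayer-center transfer free energy, kBT
    // native contacts: (i, j, d0), 0-based
    std::vector<int> ci, cj;
    std::vector<double> cd0;
    // native H-bonds: donor residue, acceptor residue (0-based)
    std::vector<int> hbd, hba;
};

struct EnergyOut {
    double hb = 0, sc = 0, cb_bur = 0, bb_bur = 0, cb_mem = 0, hb_mem = 0;
    double bonded = 0, ev = 0;
    double total() const { return hb + sc + cb_bur + bb_bur + cb_mem + hb_mem + bonded + ev; }
};

// optional per-term detail collection
struct Details {
    bool want = false;
    // H-bonds: donor, acceptor, d(H..O), -cos(NHO), s, energy
    std::vector<double> hb_rows;
    // contacts: i, j, d, energy
    std::vector<double> contact_rows;
    // per residue: n_cb, n_bb, e_cb_burial, e_bb_burial
    std::vector<double> burial_rows;
    // per residue: z_cb, f(z_cb), shield, e_cb_mem, e_hb_mem (donor+acceptor share)
    std::vector<double> memb_rows;
};

struct HbPair {
    int i, j;              // donor residue, acceptor residue
    double s;
    double w;              // well-depth factor (1 native, nonnative_hb_scale else)
    double gH[3], gO[3], gN[3];   // ds/d(site)
};

struct Model {
    Topology topo;
    Params par;

    // optional harmonic restraints on native helical donor(N)-acceptor(O)
    // distances (the "keep helices helical" perturbation); never lambda-scaled,
    // reported inside the bonded component.
    std::vector<int> ri_restr, rj_restr;   // N residue, O residue
    std::vector<double> rd0_restr;
    double k_restraint = 0.0;

    // workspace
    std::vector<double> H, O, CB;       // n x 3
    std::vector<char> hasH, hasO;
    std::vector<double> gH, gO, gCB;    // site gradients (dE/dsite)
    std::vector<double> nb_cb, nb_bb;   // smooth neighbour counts
    std::vector<double> dEdn_cb, dEdn_bb;
    std::vector<double> sat_d, sat_a;   // H-bond satisfaction sums per residue
    std::vector<double> dEdsat_d, dEdsat_a;
    std::vector<int> nat_acc;           // native acceptor of each donor (-1 none)
    std::vector<HbPair> hb_pairs;
    std::vector<int> pi_cb, pj_cb;      // active CB neighbour pairs
    std::vector<double> pd_cb;
    std::vector<int> pi_ca, pj_ca;
    std::vector<double> pd_ca;

    // Verlet neighbour lists (candidate pairs within cutoff + skin at the
    // last rebuild); the distance tests inside the energy loops make the
    // result identical to a full scan as long as no site moves more than
    // skin/2 between rebuilds.
    double nlist_skin = 2.5;
    std::vector<int> nl_cb_i, nl_cb_j, nl_ca_i, nl_ca_j, nl_hb_d, nl_hb_a;

    void build_lists(const double* x) {
        int n = topo.n;
        derived_sites(x);
        nl_cb_i.clear(); nl_cb_j.clear(); nl_ca_i.clear(); nl_ca_j.clear();
        nl_hb_d.clear(); nl_hb_a.clear();
        double rc = par.burial_r_off + nlist_skin;
        double rc2 = rc * rc;
        for (int i = 0; i < n; i++) {
            for (int j = i + 2; j < n; j++) {
                double v[3];
                vsub(v, &CB[3*i], &CB[3*j]);
                if (vnorm2(v) < rc2) { nl_cb_i.push_back(i); nl_cb_j.push_back(j); }
                vsub(v, x + 9*i + 3, x + 9*j + 3);
                if (vnorm2(v) < rc2) { nl_ca_i.push_back(i); nl_ca_j.push_back(j); }
            }
        }
        double rh = par.hb_dist_cutoff + 1.5 + nlist_skin;
        double rh2 = rh * rh;
        for (int i = 1; i < n; i++) {
            const double* Ni = x + 9*i;
            for (int j = 0; j < n - 1; j++) {
                if (j >= i - 2 && j <= i + 2) continue;
                double v[3];
                vsub(v, Ni, &O[3*j]);
                if (vnorm2(v) < rh2) { nl_hb_d.push_back(i); nl_hb_a.push_back(j); }
            }
        }
    }

    void init(const Topology& t, const Params& p) {
        topo = t; par = p;
        int n = topo.n;
        H.assign(3*n, 0); O.assign(3*n, 0); CB.assign(3*n, 0);
        hasH.assign(n, 0); hasO.assign(n, 0);
        gH.assign(3*n, 0); gO.assign(3*n, 0); gCB.assign(3*n, 0);
        nb_cb.assign(n, 0); nb_bb.assign(n, 0);
        dEdn_cb.assign(n, 0); dEdn_bb.assign(n, 0);
        sat_d.assign(n, 0); sat_a.assign(n, 0);
        dEdsat_d.assign(n, 0); dEdsat_a.assign(n, 0);
        nat_acc.assign(n, -1);
        for (size_t k = 0; k < topo.hbd.size(); k++)
            nat_acc[topo.hbd[k]] = topo.hba[k];
    }

    // ---- derived sites -----------------------------------------------------
    static constexpr double R_NH = 0.98;
    static constexpr double R_CO = 1.23;
    static constexpr double CB_KA = -0.58273431;  // coeff of (b x c)
    static constexpr double CB_KB = 0.56802827;   // coeff of b = CA - N
    static constexpr double CB_KC = -0.54067466;  // coeff of c = C - CA

    void derived_sites(const double* x) {
        int n = topo.n;
        for (int i = 0; i < n; i++) {
            const double* N = x + 9*i;
            const double* CA = x + 9*i + 3;
            const double* C = x + 9*i + 6;
            // CB
            double b[3], c[3], a[3];
            vsub(b, CA, N); vsub(c, C, CA); vcross(a, b, c);
            double* cb = &CB[3*i];
            vcopy(cb, CA);
            vaxpy(cb, CB_KA, a); vaxpy(cb, CB_KB, b); vaxpy(cb, CB_KC, c);
            // H (needs previous C)
            if (i > 0) {
                const double* Cp = x + 9*(i-1) + 6;
                double v1[3], v2[3], m[3];
                vsub(v1, CA, N); vsub(v2, Cp, N);
                double l1 = vnorm(v1), l2 = vnorm(v2);
                for (int k = 0; k < 3; k++) m[k] = -(v1[k]/l1 + v2[k]/l2);
                double lm = vnorm(m);
                double* h = &H[3*i];
                for (int k = 0; k < 3; k++) h[k] = N[k] + R_NH * m[k]/lm;
                hasH[i] = 1;
            } else hasH[i] = 0;
            // O (needs next N)
            if (i < n - 1) {
                const double* Nn = x + 9*(i+1);
                double w1[3], w2[3], m[3];
                vsub(w1, CA, C); vsub(w2, Nn, C);
                double l1 = vnorm(w1), l2 = vnorm(w2);
                for (int k = 0; k < 3; k++) m[k] = -(w1[k]/l1 + w2[k]/l2);
                double lm = vnorm(m);
                double* o = &O[3*i];
                for (int k = 0; k < 3; k++) o[k] = C[k] + R_CO * m[k]/lm;
                hasO[i] = 1;
            } else hasO[i] = 0;
        }
    }

    // chain-rule the accumulated site gradients back onto the backbone (into G)
    void backprop_sites(const double* x, double* G) {
        int n = topo.n;
        for (int i = 0; i < n; i++) {
            const double* N = x + 9*i;
            const double* CA = x + 9*i + 3;
            const double* C = x + 9*i + 6;
            // CB
            const double* g = &gCB[3*i];
            if (g[0] != 0 || g[1] != 0 || g[2] != 0) {
                double b[3], c[3], gb[3], gc[3], t[3];
                vsub(b, CA, N); vsub(c, C, CA);
                vcross(t, c, g);           // d(bxc)/db backprop
                for (int k = 0; k < 3; k++) gb[k] = CB_KB * g[k] + CB_KA * t[k];
                vcross(t, g, b);           // d(bxc)/dc backprop
                for (int k = 0; k < 3; k++) gc[k] = CB_KC * g[k] + CB_KA * t[k];
                for (int k = 0; k < 3; k++) {
                    G[9*i + k]     += -gb[k];
                    G[9*i + 3 + k] += g[k] + gb[k] - gc[k];
                    G[9*i + 6 + k] += gc[k];
                }
            }
            // H
            if (hasH[i]) {
                const double* gh = &gH[3*i];
                if (gh[0] != 0 || gh[1] != 0 || gh[2] != 0) {
                    const double* Cp = x + 9*(i-1) + 6;
                    double v1[3], v2[3], m[3];
                    vsub(v1, CA, N); vsub(v2, Cp, N);
                    double l1 = vnorm(v1), l2 = vnorm(v2);
                    double u1[3] = {v1[0]/l1, v1[1]/l1, v1[2]/l1};
                    double u2[3] = {v2[0]/l2, v2[1]/l2, v2[2]/l2};
                    double mm[3] = {-(u1[0]+u2[0]), -(u1[1]+u2[1]), -(u1[2]+u2[2])};
                    double lm = vnorm(mm);
                    double mh[3] = {mm[0]/lm, mm[1]/lm, mm[2]/lm};
                    double t[3] = {0,0,0};
                    // cap 1/|m|: the bisector shrinks toward zero at
                    // collinear N-CA/N-C(i-1) geometry (|m| ~ 1 normally)
                    proj_accum(t, mh, 1.0/std::max(lm, 0.05), gh, R_NH);
                    double g1[3] = {0,0,0}, g2[3] = {0,0,0};
                    proj_accum(g1, u1, 1.0/l1, t, -1.0);
                    proj_accum(g2, u2, 1.0/l2, t, -1.0);
                    for (int k = 0; k < 3; k++) {
                        G[9*i + k]       += gh[k] - g1[k] - g2[k];  // N
                        G[9*i + 3 + k]   += g1[k];                  // CA
                        G[9*(i-1) + 6+k] += g2[k];                  // C(i-1)
                    }
                }
            }
            // O
            if (hasO[i]) {
                const double* go = &gO[3*i];
                if (go[0] != 0 || go[1] != 0 || go[2] != 0) {
                    const double* Nn = x + 9*(i+1);
                    double w1[3], w2[3];
                    vsub(w1, CA, C); vsub(w2, Nn, C);
                    double l1 = vnorm(w1), l2 = vnorm(w2);
                    double u1[3] = {w1[0]/l1, w1[1]/l1, w1[2]/l1};
                    double u2[3] = {w2[0]/l2, w2[1]/l2, w2[2]/l2};
                    double mm[3] = {-(u1[0]+u2[0]), -(u1[1]+u2[1]), -(u1[2]+u2[2])};
                    double lm = vnorm(mm);
                    double mh[3] = {mm[0]/lm, mm[1]/lm, mm[2]/lm};
                    double t[3] = {0,0,0};
                    proj_accum(t, mh, 1.0/std::max(lm, 0.05), go, R_CO);
                    double g1[3] = {0,0,0}, g2[3] = {0,0,0};
                    proj_accum(g1, u1, 1.0/l1, t, -1.0);
                    proj_accum(g2, u2, 1.0/l2, t, -1.0);
                    for (int k = 0; k < 3; k++) {
                        G[9*i + 6 + k] += go[k] - g1[k] - g2[k];    // C
                        G[9*i + 3 + k] += g1[k];                    // CA
                        G[9*(i+1) + k] += g2[k];                    // N(i+1)
                    }
                }
            }
        }
    }

    // membrane depth profile and derivative wrt z
    inline double fz(double z) const {
        return 1.0/(1.0 + std::exp((std::fabs(z) - 0.5*par.memb_thickness)/par.memb_width));
    }
    inline double dfz(double z) const {
        double f = fz(z);
        double s = (z >= 0) ? 1.0 : -1.0;
        return -s * f * (1.0 - f) / par.memb_width;
    }

    inline bool memb_active(int i) const {
        if (topo.role[i] == ROLE_TM) return true;
        return par.include_linker_membrane;
    }

    // ---- full energy (and gradient G = dE/dx if G != nullptr) --------------
    // refresh_lists = false reuses the neighbour lists from the last
    // build_lists() call (the integrator rebuilds them on a fixed cadence)
    EnergyOut compute(const double* x, double* G, Details* det = nullptr,
                      bool refresh_lists = true) {
        int n = topo.n;
        EnergyOut E;
        if (refresh_lists) build_lists(x);
        derived_sites(x);
        std::fill(gH.begin(), gH.end(), 0.0);
        std::fill(gO.begin(), gO.end(), 0.0);
        std::fill(gCB.begin(), gCB.end(), 0.0);
        std::fill(nb_cb.begin(), nb_cb.end(), 0.0);
        std::fill(nb_bb.begin(), nb_bb.end(), 0.0);
        std::fill(dEdn_cb.begin(), dEdn_cb.end(), 0.0);
        std::fill(dEdn_bb.begin(), dEdn_bb.end(), 0.0);
        std::fill(sat_d.begin(), sat_d.end(), 0.0);
        std::fill(sat_a.begin(), sat_a.end(), 0.0);
        std::fill(dEdsat_d.begin(), dEdsat_d.end(), 0.0);
        std::fill(dEdsat_a.begin(), dEdsat_a.end(), 0.0);
        if (G) std::memset(G, 0, sizeof(double)*9*n);

        bonded_terms(x, G, E);
        pair_pass(x, G, E, det);
        hbond_terms(x, G, E, det);
        membrane_and_burial(x, G, E, det);
        restraint_terms(x, G, E);
        if (G) backprop_sites(x, G);
        return E;
    }

    void restraint_terms(const double* x, double* G, EnergyOut& E) {
        if (k_restraint <= 0.0 || ri_restr.empty()) return;
        double e = 0;
        for (size_t k = 0; k < ri_restr.size(); k++) {
            int i = ri_restr[k], j = rj_restr[k];
            if (!hasO[j]) continue;
            double v[3]; vsub(v, x + 9*i, &O[3*j]);
            double d = vnorm(v);
            double dd = d - rd0_restr[k];
            e += 0.5 * k_restraint * dd * dd;
            if (G) {
                double s = k_restraint * dd / d;
                vaxpy(G + 9*i, s, v);
                vaxpy(&gO[3*j], -s, v);
            }
        }
        E.bonded += e;
    }

    // ---- bonded: bond springs, angle springs, torsion bias ------------------
    void bond_spring(const double* a, const double* b, double r0, double k,
                     double* Ga, double* Gb, double& e) {
        double v[3]; vsub(v, a, b);
        double d = vnorm(v);
        double dd = d - r0;
        e += 0.5 * k * dd * dd;
        if (Ga) {
            double s = k * dd / d;
            vaxpy(Ga, s, v); vaxpy(Gb, -s, v);
        }
    }

    void angle_spring(const double* a, const double* b, const double* c,
                      double cos0, double k, double* Ga, double* Gb, double* Gc, double& e) {
        double u[3], v[3]; vsub(u, a, b); vsub(v, c, b);
        double lu = vnorm(u), lv = vnorm(v);
        double uh[3] = {u[0]/lu, u[1]/lu, u[2]/lu};
        double vh[3] = {v[0]/lv, v[1]/lv, v[2]/lv};
        double ct = vdot(uh, vh);
        double dd = ct - cos0;
        e += 0.5 * k * dd * dd;
        if (Ga) {
            double w = k * dd;
            for (int kk = 0; kk < 3; kk++) {
                double da = w * (vh[kk] - ct*uh[kk]) / lu;
                double dc = w * (uh[kk] - ct*vh[kk]) / lv;
                Ga[kk] += da; Gc[kk] += dc; Gb[kk] -= (da + dc);
            }
        }
    }

    // torsion bias U = k (1 - cos(chi - chi0)); takes cos/sin of chi0
    void torsion_bias(const double* p0, const double* p1, const double* p2, const double* p3,
                      double c0, double s0, double k, double* G0, double* G1, double* G2,
                      double* G3, double& e) {
        double b1[3], b2[3], b3[3], n1[3], n2[3], m[3];
        vsub(b1, p1, p0); vsub(b2, p2, p1); vsub(b3, p3, p2);
        vcross(n1, b1, b2); vcross(n2, b2, b3);
        double l2 = vnorm(b2);
        double n1sq = vnorm2(n1), n2sq = vnorm2(n2);
        // skip near-collinear geometry: the torsion is ill-defined and its
        // gradient diverges as 1/|n|^2
        double lim1 = 0.01 * vnorm2(b1) * (l2*l2);
        double lim2 = 0.01 * (l2*l2) * vnorm2(b3);
        if (n1sq < lim1 || n2sq < lim2 || l2 < 1e-10) return;
        vcross(m, n1, n2);
        double xx = vdot(n1, n2);
        double yy = vdot(m, b2) / l2;
        // cos/sin of (chi - chi0) without atan2: chi = atan2(yy, xx)
        double hyp = std::sqrt(xx*xx + yy*yy);
        if (hyp < 1e-12) return;
        double cosd = (xx * c0 + yy * s0) / hyp;
        double sind = (yy * c0 - xx * s0) / hyp;
        e += k * (1.0 - cosd);
        if (G0) {
            double dU = k * sind;
            double f0[3], f3[3];
            for (int kk = 0; kk < 3; kk++) {
                f0[kk] = -dU * l2 / n1sq * n1[kk];
                f3[kk] = dU * l2 / n2sq * n2[kk];
            }
            // near-collinear backbone angles make 1/|n|^2 blow up; cap the
            // end-atom gradients (inactive at regular geometry, where they
            // are orders of magnitude below the cap)
            const double cap = 1000.0;
            double m0 = vnorm(f0), m3 = vnorm(f3);
            if (m0 > cap) vscale(f0, cap / m0);
            if (m3 > cap) vscale(f3, cap / m3);
            double tf = vdot(b1, b2) / (l2*l2);
            double tg = vdot(b3, b2) / (l2*l2);
            for (int kk = 0; kk < 3; kk++) {
                double f1 = -(1.0 + tf)*f0[kk] + tg*f3[kk];
                double f2 = -f0[kk] - f1 - f3[kk];
                G0[kk] += f0[kk]; G1[kk] += f1; G2[kk] += f2; G3[kk] += f3[kk];
            }
        }
    }

    static constexpr double R_N_CA = 1.458, R_CA_C = 1.525, R_C_N = 1.329;
    static constexpr double COS_N_CA_C = -0.3616;  // cos(111.2)
    static constexpr double COS_CA_C_N = -0.4415;  // cos(116.2)
    static constexpr double COS_C_N_CA = -0.5255;  // cos(121.7)
    // torsion bias targets: phi -60 deg, psi -47 deg, omega 180 deg
    static constexpr double COS_PHI0 = 0.5, SIN_PHI0 = -0.86602540378;
    static constexpr double COS_PSI0 = 0.68199836; static constexpr double SIN_PSI0 = -0.73135370;

    void bonded_terms(const double* x, double* G, EnergyOut& E) {
        int n = topo.n;
        double e = 0;
        for (int i = 0; i < n; i++) {
            double* gN = G ? G + 9*i : nullptr;
            double* gCA = G ? G + 9*i + 3 : nullptr;
            double* gC = G ? G + 9*i + 6 : nullptr;
            const double* N = x + 9*i;
            const double* CA = x + 9*i + 3;
            const double* C = x + 9*i + 6;
            bond_spring(N, CA, R_N_CA, par.k_bond, gN, gCA, e);
            bond_spring(CA, C, R_CA_C, par.k_bond, gCA, gC, e);
            angle_spring(N, CA, C, COS_N_CA_C, par.k_angle, gN, gCA, gC, e);
            if (i < n - 1) {
                const double* Nn = x + 9*(i+1);
                const double* CAn = x + 9*(i+1) + 3;
                double* gNn = G ? G + 9*(i+1) : nullptr;
                double* gCAn = G ? G + 9*(i+1) + 3 : nullptr;
                bond_spring(C, Nn, R_C_N, par.k_bond, gC, gNn, e);
                angle_spring(CA, C, Nn, COS_CA_C_N, par.k_angle, gCA, gC, gNn, e);
                angle_spring(C, Nn, CAn, COS_C_N_CA, par.k_angle, gC, gNn, gCAn, e);
                // psi_i: N CA C N+1 ; omega: CA C N+1 CA+1
                torsion_bias(N, CA, C, Nn, COS_PSI0, SIN_PSI0, par.k_tors_psi,
                             gN, gCA, gC, gNn, e);
                torsion_bias(CA, C, Nn, CAn, -1.0, 0.0, par.k_tors_omega,
                             gCA, gC, gNn, gCAn, e);
            }
            if (i > 0) {
                const double* Cp = x + 9*(i-1) + 6;
                double* gCp = G ? G + 9*(i-1) + 6 : nullptr;
                // phi_i: C-1 N CA C
                torsion_bias(Cp, N, CA, C, COS_PHI0, SIN_PHI0, par.k_tors_phi,
                             gCp, gN, gCA, gC, e);
            }
        }
        E.bonded = e;
    }

    // ---- CB/CA pair pass: excluded volume, neighbour counts, contacts -------
    void pair_pass(const double* x, double* G, EnergyOut& E, Details* det) {
        int n = topo.n;
        pi_cb.clear(); pj_cb.clear(); pd_cb.clear();
        pi_ca.clear(); pj_ca.clear(); pd_ca.clear();
        double roff2 = par.burial_r_off * par.burial_r_off;
        double e_ev = 0;
        for (size_t k = 0; k < nl_cb_i.size(); k++) {
            int i = nl_cb_i[k], j = nl_cb_j[k];
            double v[3]; vsub(v, &CB[3*i], &CB[3*j]);
            double d2 = vnorm2(v);
            if (d2 >= roff2) continue;
            double d = std::sqrt(d2);
            pi_cb.push_back(i); pj_cb.push_back(j); pd_cb.push_back(d);
            double sw = sw_down(d, par.burial_r_on, par.burial_r_off);
            nb_cb[i] += sw; nb_cb[j] += sw;
            if (d < par.ev_diameter) {
                double t = 1.0 - d/par.ev_diameter;
                e_ev += par.eps_rep * t * t;
                if (G) {
                    double s = -2.0 * par.eps_rep * t / (par.ev_diameter * d);
                    vaxpy(&gCB[3*i], s, v); vaxpy(&gCB[3*j], -s, v);
                }
            }
        }
        for (size_t k = 0; k < nl_ca_i.size(); k++) {
            int i = nl_ca_i[k], j = nl_ca_j[k];
            double w[3]; vsub(w, x + 9*i + 3, x + 9*j + 3);
            double dc2 = vnorm2(w);
            if (dc2 >= roff2) continue;
            double d = std::sqrt(dc2);
            pi_ca.push_back(i); pj_ca.push_back(j); pd_ca.push_back(d);
            double sw = sw_down(d, par.burial_r_on, par.burial_r_off);
            nb_bb[i] += sw; nb_bb[j] += sw;
            if (d < par.ev_diameter_ca) {
                double t = 1.0 - d/par.ev_diameter_ca;
                e_ev += par.eps_rep * t * t;
                if (G) {
                    double s = -2.0 * par.eps_rep * t / (par.ev_diameter_ca * d);
                    vaxpy(G + 9*i + 3, s, w); vaxpy(G + 9*j + 3, -s, w);
                }
            }
        }
        E.ev = e_ev;

        // native contacts: smooth well centred at native distance
        double e_sc = 0;
        double rw = par.contact_well_width;
        for (size_t k = 0; k < topo.ci.size(); k++) {
            int i = topo.ci[k], j = topo.cj[k];
            double v[3]; vsub(v, &CB[3*i], &CB[3*j]);
            double d = vnorm(v);
            double t = (d - topo.cd0[k]) / rw;
            double e_pair = 0;
            if (std::fabs(t) < 1.0) {
                double q = 1.0 - t*t;
                e_pair = -par.lambda_pp * par.eps_contact * q * q;
                e_sc += e_pair;
                if (G) {
                    double s = par.lambda_pp * par.eps_contact * 4.0 * q * t / (rw * d);
                    vaxpy(&gCB[3*i], s, v); vaxpy(&gCB[3*j], -s, v);
                }
            }
            if (det && det->want) {
                det->contact_rows.push_back(i); det->contact_rows.push_back(j);
                det->contact_rows.push_back(d); det->contact_rows.push_back(e_pair);
            }
        }
        E.sc = e_sc;
    }

    // ---- H-bonds -------------------------------------------------------------
    void hbond_terms(const double* x, double* G, EnergyOut& E, Details* det) {
        int n = topo.n;
        hb_pairs.clear();
        double cut = par.hb_dist_cutoff;
        double pre2 = (cut + 1.5) * (cut + 1.5);
        double e_hb = 0;
        for (size_t k = 0; k < nl_hb_d.size(); k++) {
            int i = nl_hb_d[k], j = nl_hb_a[k];
            {
                if (!hasH[i] || !hasO[j]) continue;
                const double* Ni = x + 9*i;
                const double* Hi = &H[3*i];
                double vNO[3]; vsub(vNO, Ni, &O[3*j]);
                if (vnorm2(vNO) > pre2) continue;
                const double* Oj = &O[3*j];
                double vHO[3]; vsub(vHO, Hi, Oj);
                double d = vnorm(vHO);
                if (d >= cut) continue;
                // c = -cos(N-H..O) = unit(H-N) . unit(O-H)
                double v1[3], v2[3];
                vsub(v1, Hi, Ni); vsub(v2, Oj, Hi);
                double l1 = vnorm(v1), l2 = vnorm(v2);
                double u1[3] = {v1[0]/l1, v1[1]/l1, v1[2]/l1};
                double u2[3] = {v2[0]/l2, v2[1]/l2, v2[2]/l2};
                double c = vdot(u1, u2);
                if (c <= par.hb_cos_lo) continue;
                double sd = sw_down(d, par.hb_dist_inner, par.hb_dist_cutoff);
                double sa = sw_up(c, par.hb_cos_lo, par.hb_cos_hi);
                double s = sd * sa;
                if (s <= 0) continue;
                HbPair hp; hp.i = i; hp.j = j; hp.s = s;
                hp.w = (nat_acc[i] == j) ? 1.0 : par.nonnative_hb_scale;
                // gradients of s
                double dsd = dsw_down(d, par.hb_dist_inner, par.hb_dist_cutoff) * sa;
                double dsa = sd * dsw_up(c, par.hb_cos_lo, par.hb_cos_hi);
                // dc/dv1, dc/dv2
                double dc1[3], dc2[3];
                for (int k = 0; k < 3; k++) {
                    dc1[k] = (u2[k] - c*u1[k]) / l1;
                    dc2[k] = (u1[k] - c*u2[k]) / l2;
                }
                for (int k = 0; k < 3; k++) {
                    double ddH = vHO[k] / d;
                    hp.gH[k] = dsd * ddH + dsa * (dc1[k] - dc2[k]);
                    hp.gO[k] = -dsd * ddH + dsa * dc2[k];
                    hp.gN[k] = -dsa * dc1[k];
                }
                sat_d[i] += s; sat_a[j] += s;
                e_hb += -par.lambda_hb * par.eps_hb * hp.w * s;
                hb_pairs.push_back(hp);
                if (det && det->want) {
                    det->hb_rows.push_back(i); det->hb_rows.push_back(j);
                    det->hb_rows.push_back(d); det->hb_rows.push_back(c);
                    det->hb_rows.push_back(s);
                    det->hb_rows.push_back(-par.lambda_hb * par.eps_hb * hp.w * s);
                }
            }
        }
        E.hb = e_hb;
        // gradient application is deferred to membrane_and_burial(), which adds
        // the hb-membrane coupling weights before the single pass over pairs.
        (void)G;
    }

    // ---- burial + membrane terms (and the deferred H-bond gradient pass) -----
    void membrane_and_burial(const double* x, double* G, EnergyOut& E, Details* det) {
        int n = topo.n;
        double e_cb_bur = 0, e_bb_bur = 0, e_cb_mem = 0, e_hb_mem = 0;
        // burial (protein desolvation) + cb membrane
        for (int i = 0; i < n; i++) {
            double scb = sstep(nb_cb[i] / par.n_sat);
            double dscb = dsstep(nb_cb[i] / par.n_sat) / par.n_sat;
            double sgn = (topo.dG[i] > 0) ? 1.0 : ((topo.dG[i] < 0) ? -1.0 : 0.0);
            double e1 = par.lambda_pp * par.eps_burial * sgn * scb;
            e_cb_bur += e1;
            dEdn_cb[i] += par.lambda_pp * par.eps_burial * sgn * dscb;

            double sbb = sstep(nb_bb[i] / par.n_sat);
            double dsbb = dsstep(nb_bb[i] / par.n_sat) / par.n_sat;
            double e2 = -par.lambda_pp * par.eps_burial_bb * sbb;
            e_bb_bur += e2;
            dEdn_bb[i] += -par.lambda_pp * par.eps_burial_bb * dsbb;

            double zr = CB[3*i + 2];
            // far outside the slab the profile and its gradient vanish
            double far = 0.5*par.memb_thickness + 8.0*par.memb_width;
            double f = (std::fabs(zr) > far) ? 0.0 : fz(zr);
            double e3 = 0;
            // shielding never completes: a residue in a small bundle keeps
            // part of its lipid exposure even when fully coordinated
            double shield = par.shield_max * scb;
            double dshield = par.shield_max * dscb;
            if (memb_active(i)) {
                e3 = par.lambda_memb * topo.dG[i] * f * (1.0 - shield);
                e_cb_mem += e3;
                dEdn_cb[i] += par.lambda_memb * topo.dG[i] * f * (-dshield);
                if (G) gCB[3*i + 2] += par.lambda_memb * topo.dG[i] * dfz(zr) * (1.0 - shield);
            }
            if (det && det->want) {
                det->burial_rows.push_back(nb_cb[i]); det->burial_rows.push_back(nb_bb[i]);
                det->burial_rows.push_back(e1); det->burial_rows.push_back(e2);
                det->memb_rows.push_back(zr); det->memb_rows.push_back(f);
                det->memb_rows.push_back(shield); det->memb_rows.push_back(e3);
                det->memb_rows.push_back(0);  // hb-membrane share filled below
            }
        }
        // hb-membrane: donor groups (amide NH) and acceptor groups (carbonyl O)
        for (int i = 0; i < n; i++) {
            double far2 = 0.5*par.memb_thickness + 8.0*par.memb_width;
            if (hasH[i] && memb_active(i) && std::fabs(x[9*i + 2]) < far2) {
                double z = x[9*i + 2];             // N z
                double f = fz(z);
                double q = sstep(sat_d[i] / par.sat_ref);
                double dq = dsstep(sat_d[i] / par.sat_ref) / par.sat_ref;
                double psi = par.eps_unsat * (1.0 - q) - par.hb_core_bonus * par.eps_hb * q;
                double e = par.lambda_memb * f * psi;
                e_hb_mem += e;
                dEdsat_d[i] = par.lambda_memb * f *
                    (-par.eps_unsat - par.hb_core_bonus * par.eps_hb) * dq;
                if (G) G[9*i + 2] += par.lambda_memb * dfz(z) * psi;
                if (det && det->want) det->memb_rows[5*i + 4] += e;
            }
            if (hasO[i] && memb_active(i) && std::fabs(O[3*i + 2]) < far2) {
                double z = O[3*i + 2];
                double f = fz(z);
                double q = sstep(sat_a[i] / par.sat_ref);
                double dq = dsstep(sat_a[i] / par.sat_ref) / par.sat_ref;
                double psi = par.eps_unsat * (1.0 - q) - par.hb_core_bonus * par.eps_hb * q;
                double e = par.lambda_memb * f * psi;
                e_hb_mem += e;
                dEdsat_a[i] = par.lambda_memb * f *
                    (-par.eps_unsat - par.hb_core_bonus * par.eps_hb) * dq;
                if (G) gO[3*i + 2] += par.lambda_memb * dfz(z) * psi;
                if (det && det->want) det->memb_rows[5*i + 4] += e;
            }
        }
        E.cb_bur = e_cb_bur; E.bb_bur = e_bb_bur;
        E.cb_mem = e_cb_mem; E.hb_mem = e_hb_mem;
        if (!G) return;

        // deferred H-bond gradient pass with full weights
        for (const HbPair& hp : hb_pairs) {
            double w = -par.lambda_hb * par.eps_hb * hp.w + dEdsat_d[hp.i] + dEdsat_a[hp.j];
            vaxpy(&gH[3*hp.i], w, hp.gH);
            vaxpy(&gO[3*hp.j], w, hp.gO);
            vaxpy(G + 9*hp.i, w, hp.gN);
        }
        // neighbour-count gradients (CB and CA switches)
        for (size_t k = 0; k < pi_cb.size(); k++) {
            int i = pi_cb[k], j = pj_cb[k];
            double d = pd_cb[k];
            double dsw = dsw_down(d, par.burial_r_on, par.burial_r_off);
            if (dsw == 0.0) continue;
            double w = (dEdn_cb[i] + dEdn_cb[j]) * dsw;
            if (w == 0.0) continue;
            double v[3]; vsub(v, &CB[3*i], &CB[3*j]);
            double s = w / d;
            vaxpy(&gCB[3*i], s, v); vaxpy(&gCB[3*j], -s, v);
        }
        for (size_t k = 0; k < pi_ca.size(); k++) {
            int i = pi_ca[k], j = pj_ca[k];
            double d = pd_ca[k];
            double dsw = dsw_down(d, par.burial_r_on, par.burial_r_off);
            if (dsw == 0.0) continue;
            double w = (dEdn_bb[i] + dEdn_bb[j]) * dsw;
            if (w == 0.0) continue;
            double v[3]; vsub(v, x + 9*i + 3, x + 9*j + 3);
            double s = w / d;
            vaxpy(G + 9*i + 3, s, v); vaxpy(G + 9*j + 3, -s, v);
        }
    }
};

} // namespace mp

#endif
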