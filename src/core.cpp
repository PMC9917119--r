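#include <Rcpp.h>
#include "mp_model.h"
#include "mp_rng.h"

using namespace Rcpp;
using namespace mp;

// ---------------------------------------------------------------------------
// parsing helpers (R wrappers pass 0-based indices)
// ---------------------------------------------------------------------------

static Topology parse_topology(const List& t) {
    Topology topo;
    topo.n = as<int>(t["n"]);
    topo.role = as<std::vector<int>>(t["role"]);
    topo.helix = as<std::vector<int>>(t["helix"]);
    topo.dG = as<std::vector<double>>(t["dG"]);
    NumericMatrix cm = t["contacts"];
    for (int k = 0; k < cm.nrow(); k++) {
        topo.ci.push_back((int)cm(k, 0));
        topo.cj.push_back((int)cm(k, 1));
        topo.cd0.push_back(cm(k, 2));
    }
    IntegerMatrix hm = t["hbonds"];
    for (int k = 0; k < hm.nrow(); k++) {
        topo.hbd.push_back(hm(k, 0));
        topo.hba.push_back(hm(k, 1));
    }
    return topo;
}

static Params parse_params(const List& p) {
    Params q;
    q.lambda_hb = as<double>(p["lambda_hb"]);
    q.lambda_pp = as<double>(p["lambda_pp"]);
    q.lambda_memb = as<double>(p["lambda_memb"]);
    q.eps_hb = as<double>(p["eps_hb"]);
    q.nonnative_hb_scale = as<double>(p["nonnative_hb_scale"]);
    q.eps_contact = as<double>(p["eps_contact"]);
    q.eps_burial = as<double>(p["eps_burial"]);
    q.eps_burial_bb = as<double>(p["eps_burial_bb"]);
    q.eps_unsat = as<double>(p["eps_unsat"]);
    q.hb_core_bonus = as<double>(p["hb_core_bonus"]);
    q.hb_dist_cutoff = as<double>(p["hb_dist_cutoff"]);
    q.hb_dist_inner = as<double>(p["hb_dist_inner"]);
    q.hb_cos_lo = as<double>(p["hb_cos_lo"]);
    q.hb_cos_hi = as<double>(p["hb_cos_hi"]);
    q.contact_cutoff = as<double>(p["contact_cutoff"]);
    q.contact_well_width = as<double>(p["contact_well_width"]);
    q.ev_diameter = as<double>(p["excluded_volume_diameter"]);
    q.ev_diameter_ca = as<double>(p["excluded_volume_diameter_ca"]);
    q.eps_rep = as<double>(p["eps_rep"]);
    q.burial_r_on = as<double>(p["burial_r_on"]);
    q.burial_r_off = as<double>(p["burial_r_off"]);
    q.n_sat = as<double>(p["n_sat"]);
    q.sat_ref = as<double>(p["sat_ref"]);
    q.shield_max = as<double>(p["shield_max"]);
    q.memb_thickness = as<double>(p["membrane_thickness"]);
    q.memb_width = as<double>(p["membrane_width"]);
    q.include_linker_membrane = as<bool>(p["include_linker_membrane"]);
    q.k_bond = as<double>(p["k_bond"]);
    q.k_angle = as<double>(p["k_angle"]);
    q.k_tors_phi = as<double>(p["k_tors_phi"]);
    q.k_tors_psi = as<double>(p["k_tors_psi"]);
    q.k_tors_omega = as<double>(p["k_tors_omega"]);
    return q;
}

static void add_restraints(Model& M, const List& p) {
    if (!p.containsElementNamed("restraints")) return;
    RObject r = p["restraints"];
    if (r.isNULL()) return;
    NumericMatrix rm(r);
    if (rm.nrow() == 0) return;
    M.k_restraint = as<double>(p["restraint_k"]);
    for (int k = 0; k < rm.nrow(); k++) {
        M.ri_restr.push_back((int)rm(k, 0));
        M.rj_restr.push_back((int)rm(k, 1));
        M.rd0_restr.push_back(rm(k, 2));
    }
}

static NumericVector breakdown_vector(const EnergyOut& E) {
    NumericVector out = NumericVector::create(
        _["hb"] = E.hb, _["sc_sc"] = E.sc,
        _["cb_burial"] = E.cb_bur, _["bb_burial"] = E.bb_bur,
        _["cb_membrane"] = E.cb_mem, _["hb_membrane"] = E.hb_mem,
        _["bonded"] = E.bonded, _["excluded_volume"] = E.ev,
        _["total"] = E.total());
    return out;
}

// ---------------------------------------------------------------------------
// energy / forces
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_energy(NumericMatrix coords, List topo, List params, bool details = false) {
    Model M;
    M.init(parse_topology(topo), parse_params(params));
    add_restraints(M, params);
    Details det; det.want = details;
    EnergyOut E = M.compute(REAL(coords), nullptr, details ? &det : nullptr);
    List out = List::create(_["breakdown"] = breakdown_vector(E));
    if (details) {
        int nhb = det.hb_rows.size() / 6;
        NumericMatrix hb(nhb, 6);
        for (int k = 0; k < nhb; k++)
            for (int c = 0; c < 6; c++) hb(k, c) = det.hb_rows[6*k + c];
        colnames(hb) = CharacterVector::create("donor", "acceptor", "dist", "ncos", "s", "energy");
        int nc = det.contact_rows.size() / 4;
        NumericMatrix cm(nc, 4);
        for (int k = 0; k < nc; k++)
            for (int c = 0; c < 4; c++) cm(k, c) = det.contact_rows[4*k + c];
        colnames(cm) = CharacterVector::create("i", "j", "dist", "energy");
        int n = M.topo.n;
        NumericMatrix bm(n, 4), mm(n, 5);
        for (int i = 0; i < n; i++) {
            for (int c = 0; c < 4; c++) bm(i, c) = det.burial_rows[4*i + c];
            for (int c = 0; c < 5; c++) mm(i, c) = det.memb_rows[5*i + c];
        }
        colnames(bm) = CharacterVector::create("n_cb", "n_bb", "e_cb_burial", "e_bb_burial");
        colnames(mm) = CharacterVector::create("z_cb", "fz", "shield", "e_cb_membrane", "e_hb_membrane");
        out["hbonds"] = hb;
        out["contacts"] = cm;
        out["burial"] = bm;
        out["membrane"] = mm;
    }
    return out;
}

// springs: list of lists with fields kind ("pull", "anchor", "clamp"),
// residue (0-based, acts on CA), axis, k, target (scalar), point (3), force
static void apply_springs(const List& springs, const double* x, double* G,
                          double* e_spring) {
    *e_spring = 0;
    for (int si = 0; si < springs.size(); si++) {
        List sp = springs[si];
        std::string kind = as<std::string>(sp["kind"]);
        int res = as<int>(sp["residue"]);
        const double* ca = x + 9*res + 3;
        if (kind == "pull") {
            NumericVector a = sp["axis"];
            double k = as<double>(sp["k"]);
            double target = as<double>(sp["target"]);
            double d = ca[0]*a[0] + ca[1]*a[1] + ca[2]*a[2] - target;
            *e_spring += 0.5 * k * d * d;
            if (G) for (int c = 0; c < 3; c++) G[9*res + 3 + c] += k * d * a[c];
        } else if (kind == "anchor") {
            NumericVector p = sp["point"];
            double k = as<double>(sp["k"]);
            double v[3] = {ca[0]-p[0], ca[1]-p[1], ca[2]-p[2]};
            *e_spring += 0.5 * k * vnorm2(v);
            if (G) for (int c = 0; c < 3; c++) G[9*res + 3 + c] += k * v[c];
        } else if (kind == "clamp") {
            NumericVector a = sp["axis"];
            double f = as<double>(sp["force"]);
            *e_spring += -f * (ca[0]*a[0] + ca[1]*a[1] + ca[2]*a[2]);
            if (G) for (int c = 0; c < 3; c++) G[9*res + 3 + c] += -f * a[c];
        } else {
            stop("unknown spring kind '%s'", kind.c_str());
        }
    }
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix coords, List topo, List params, List springs) {
    Model M;
    M.init(parse_topology(topo), parse_params(params));
    add_restraints(M, params);
    int n = M.topo.n;
    std::vector<double> G(9*n, 0.0);
    EnergyOut E = M.compute(REAL(coords), G.data());
    double e_spring = 0;
    apply_springs(springs, REAL(coords), G.data(), &e_spring);
    double tot = E.total() + e_spring;
    if (!std::isfinite(tot)) {
        const char* which = !std::isfinite(E.hb) ? "hb" :
            !std::isfinite(E.sc) ? "sc_sc" :
            !std::isfinite(E.cb_mem) ? "cb_membrane" :
            !std::isfinite(E.bonded) ? "bonded" : "total";
        stop("non-finite energy in term '%s'", which);
    }
    NumericMatrix F(9, n);   // 9 x n, column-major == flat residue-major
    for (int i = 0; i < 9*n; i++) F[i] = -G[i];
    List out = List::create(_["forces"] = F,
                            _["breakdown"] = breakdown_vector(E),
                            _["spring_energy"] = e_spring);
    return out;
}

// ---------------------------------------------------------------------------
// minimizer (adaptive gradient descent; used by the system builders)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix coords, List topo, List params,
                  int max_iter = 500, double tol = 1e-3) {
    Model M;
    M.init(parse_topology(topo), parse_params(params));
    add_restraints(M, params);
    int n = M.topo.n, nd = 9*n;
    std::vector<double> x(REAL(coords), REAL(coords) + nd);
    std::vector<double> G(nd), xn(nd);
    double step = 1e-3;
    EnergyOut E = M.compute(x.data(), G.data());
    double e0 = E.total();
    int it;
    for (it = 0; it < max_iter; it++) {
        double gmax = 0;
        for (int i = 0; i < nd; i++) gmax = std::max(gmax, std::fabs(G[i]));
        if (gmax < tol) break;
        double s = step;
        if (s * gmax > 0.25) s = 0.25 / gmax;   // cap displacement per move
        for (int i = 0; i < nd; i++) xn[i] = x[i] - s * G[i];
        EnergyOut E1 = M.compute(xn.data(), nullptr);
        if (E1.total() < e0) {
            x.swap(xn);
            e0 = E1.total();
            step = std::min(step * 1.25, 0.05);
            M.compute(x.data(), G.data());
        } else {
            step *= 0.5;
            if (step < 1e-10) break;
        }
    }
    NumericMatrix out(9, n);
    std::copy(x.begin(), x.end(), REAL(out));
    return List::create(_["coords"] = out, _["energy"] = e0, _["iterations"] = it);
}

// ---------------------------------------------------------------------------
// overdamped Langevin
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_step_langevin(NumericMatrix coords, NumericMatrix forces,
                                double dt, double friction, double temperature,
                                int seed, double max_disp = 2.0) {
    // coords and forces are 9 x n (column-major == flat residue-major)
    int n = coords.ncol();
    NumericMatrix out(9, n);
    MpRng rng((std::uint64_t)seed);
    double mob = dt / friction;
    double sig = std::sqrt(2.0 * temperature * dt / friction);
    const double* xc = REAL(coords);
    const double* fc = REAL(forces);
    double* oc = REAL(out);
    for (int i = 0; i < n; i++) {
        for (int s = 0; s < 3; s++) {
            double d2 = 0;
            double dx[3];
            for (int c = 0; c < 3; c++) {
                dx[c] = mob * fc[9*i + 3*s + c] + sig * rng.rnorm();
                d2 += dx[c]*dx[c];
            }
            if (d2 > max_disp * max_disp)
                stop("unstable step: site displacement %.2f A exceeds %.2f A at residue %d",
                     std::sqrt(d2), max_disp, i + 1);
            for (int c = 0; c < 3; c++) oc[9*i + 3*s + c] = xc[9*i + 3*s + c] + dx[c];
        }
    }
    return out;
}

// [[Rcpp::export]]
List cpp_run_pulling(NumericMatrix coords, List topo, List params, List prot) {
    Model M;
    M.init(parse_topology(topo), parse_params(params));
    add_restraints(M, params);
    // protocol-level restraints override/augment
    if (prot.containsElementNamed("restraints")) {
        RObject r = prot["restraints"];
        if (!r.isNULL()) {
            NumericMatrix rm(r);
            M.k_restraint = as<double>(prot["restraint_k"]);
            for (int k = 0; k < rm.nrow(); k++) {
                M.ri_restr.push_back((int)rm(k, 0));
                M.rj_restr.push_back((int)rm(k, 1));
                M.rd0_restr.push_back(rm(k, 2));
            }
        }
    }
    int n = M.topo.n, nd = 9*n;
    std::string mode = as<std::string>(prot["mode"]);
    double k_spring = as<double>(prot["k"]);
    double vel = as<double>(prot["velocity"]);
    double clampf = prot.containsElementNamed("clamp_force") ? as<double>(prot["clamp_force"]) : 0.0;
    NumericVector axis = prot["axis"];
    int attach = as<int>(prot["attach"]);
    int anchor = as<int>(prot["anchor_residue"]);   // -1 if none
    double k_anchor = as<double>(prot["anchor_k"]);
    double temperature = as<double>(prot["temperature"]);
    double dt = as<double>(prot["dt"]);
    double friction = as<double>(prot["friction"]);
    int n_steps = as<int>(prot["n_steps"]);
    int fi = as<int>(prot["frame_interval"]);
    int seed = as<int>(prot["seed"]);
    double max_disp = as<double>(prot["max_disp"]);
    bool clamp = (mode == "force_clamp");

    std::vector<double> x(REAL(coords), REAL(coords) + nd);
    std::vector<double> G(nd);
    MpRng rng((std::uint64_t)seed);
    double mob = dt / friction;
    double sig = std::sqrt(2.0 * temperature * dt / friction);

    const double* att_ca = x.data() + 9*attach + 3;
    double a[3] = {axis[0], axis[1], axis[2]};
    double offset0 = prot.containsElementNamed("initial_offset") ?
        as<double>(prot["initial_offset"]) : 0.0;
    double c0 = vdot(a, att_ca) + offset0;   // pre-tensioned cantilever start
    double ext0_att = c0;
    double anchor_p[3] = {0, 0, 0};
    double ext0_anch = 0;
    if (anchor >= 0) {
        vcopy(anchor_p, x.data() + 9*anchor + 3);
        ext0_anch = vdot(a, anchor_p);
    }

    int nf = n_steps / fi + 1;
    NumericVector traj(nd * nf);
    traj.attr("dim") = IntegerVector::create(9, n, nf);
    IntegerVector steps(nf);
    NumericVector sx(nf), sforce(nf), senergy(nf), ext(nf);
    NumericMatrix bkm(nf, 9);
    colnames(bkm) = CharacterVector::create("hb", "sc_sc", "cb_burial", "bb_burial",
        "cb_membrane", "hb_membrane", "bonded", "excluded_volume", "total");

    auto capture = [&](int fidx, int step) {
        steps[fidx] = step;
        std::copy(x.begin(), x.end(), REAL(traj) + (std::size_t)fidx * nd);
        const double* ca = x.data() + 9*attach + 3;
        double cant = c0 + vel * step;
        double ext_val = vdot(a, ca) - ext0_att;
        if (anchor >= 0) ext_val -= (vdot(a, x.data() + 9*anchor + 3) - ext0_anch);
        ext[fidx] = ext_val;
        if (clamp) {
            sx[fidx] = NA_REAL;
            sforce[fidx] = clampf;
            senergy[fidx] = NA_REAL;
        } else {
            double disp = cant - vdot(a, ca);
            sx[fidx] = disp;
            sforce[fidx] = k_spring * disp;
            senergy[fidx] = 0.5 * k_spring * disp * disp;
        }
        EnergyOut E = M.compute(x.data(), nullptr, nullptr, false);
        NumericVector bv = breakdown_vector(E);
        for (int c = 0; c < 9; c++) bkm(fidx, c) = bv[c];
    };

    M.build_lists(x.data());
    capture(0, 0);
    int fidx = 1;
    const int nlist_every = 15;
    for (int step = 1; step <= n_steps; step++) {
        if ((step - 1) % nlist_every == 0) M.build_lists(x.data());
        EnergyOut E = M.compute(x.data(), G.data(), nullptr, false);
        if (!std::isfinite(E.total()))
            stop("non-finite energy at step %d", step);
        // springs
        double cant = c0 + vel * step;
        double* gca = G.data() + 9*attach + 3;
        const double* ca = x.data() + 9*attach + 3;
        if (clamp) {
            for (int c = 0; c < 3; c++) gca[c] += -clampf * a[c];
        } else {
            double d = vdot(a, ca) - cant;
            for (int c = 0; c < 3; c++) gca[c] += k_spring * d * a[c];
        }
        if (anchor >= 0) {
            double* gan = G.data() + 9*anchor + 3;
            const double* an = x.data() + 9*anchor + 3;
            for (int c = 0; c < 3; c++) gan[c] += k_anchor * (an[c] - anchor_p[c]);
        }
        // Euler-Maruyama update, with per-site gradient clipping: rare
        // near-singular geometries can spike the gradient far above the
        // physical force scale (a few kBT/A); clipping keeps the step
        // bounded without affecting regular dynamics
        const double gcap = 35.0;
        for (int i = 0; i < n; i++) {
            for (int s = 0; s < 3; s++) {
                double* gs = G.data() + 9*i + 3*s;
                double g2 = gs[0]*gs[0] + gs[1]*gs[1] + gs[2]*gs[2];
                if (g2 > gcap*gcap) {
                    double sc = gcap / std::sqrt(g2);
                    gs[0] *= sc; gs[1] *= sc; gs[2] *= sc;
                }
                double d2 = 0, dx[3];
                for (int c = 0; c < 3; c++) {
                    dx[c] = -mob * gs[c] + sig * rng.rnorm();
                    d2 += dx[c]*dx[c];
                }
                if (d2 > max_disp * max_disp)
                    stop("unstable integration at step %d: residue %d moved %.2f A (> %.2f A)",
                         step, i + 1, std::sqrt(d2), max_disp);
                for (int c = 0; c < 3; c++) x[9*i + 3*s + c] += dx[c];
            }
        }
        if (step % fi == 0) capture(fidx++, step);
        if (step % 2048 == 0) Rcpp::checkUserInterrupt();
    }

    return List::create(_["steps"] = steps, _["coords"] = traj,
                        _["x"] = sx, _["force"] = sforce,
                        _["spring_energy"] = senergy, _["extension"] = ext,
                        _["breakdown"] = bkm, _["seed"] = seed);
}

// ---------------------------------------------------------------------------
// single-bead integrator diagnostics (same update rule and RNG as the runs)
// ---------------------------------------------------------------------------

// type 0: harmonic U = 0.5 k x^2 with k = p1
// type 1: tilted double well U = p1 * (x^2 - 1)^2 + p2 * x
// [[Rcpp::export]]
NumericVector cpp_bead_sim(int type, double p1, double p2, double n_steps_d,
                           double dt, double friction, double temperature,
                           int seed, int thin, double x0) {
    long long n_steps = (long long)n_steps_d;
    MpRng rng((std::uint64_t)seed);
    double mob = dt / friction;
    double sig = std::sqrt(2.0 * temperature * dt / friction);
    long long nout = n_steps / thin;
    NumericVector out(nout);
    double x = x0;
    long long k = 0;
    for (long long step = 1; step <= n_steps; step++) {
        double f;
        if (type == 0) f = -p1 * x;
        else f = -(4.0 * p1 * x * (x*x - 1.0) + p2);
        x += mob * f + sig * rng.rnorm();
        if (step % thin == 0 && k < nout) out[k++] = x;
    }
    return out;
}

// ---------------------------------------------------------------------------
// per-frame trajectory metrics
// ---------------------------------------------------------------------------

static double hb_pair_s(const Model& M, const double* x, int i, int j) {
    // s for donor residue i -> acceptor residue j on current derived sites
    if (i < 1 || !M.hasO[j]) return 0.0;
    const double* Hi = &M.H[3*i];
    const double* Oj = &M.O[3*j];
    const double* Ni = x + 9*i;
    double vHO[3]; vsub(vHO, Hi, Oj);
    double d = vnorm(vHO);
    if (d >= M.par.hb_dist_cutoff) return 0.0;
    double v1[3], v2[3];
    vsub(v1, Hi, Ni); vsub(v2, Oj, Hi);
    double c = vdot(v1, v2) / (vnorm(v1) * vnorm(v2));
    if (c <= M.par.hb_cos_lo) return 0.0;
    return sw_down(d, M.par.hb_dist_inner, M.par.hb_dist_cutoff) *
           sw_up(c, M.par.hb_cos_lo, M.par.hb_cos_hi);
}

// [[Rcpp::export]]
List cpp_traj_metrics(NumericVector traj, List topo, List params,
                      IntegerMatrix helices) {
    // helices: rows of (start, end) 0-based inclusive
    Model M;
    M.init(parse_topology(topo), parse_params(params));
    IntegerVector dim = traj.attr("dim");
    int n = dim[1], nf = dim[2];
    int nh = helices.nrow();
    NumericMatrix nhp(nf, nh), helicity(nf, nh), com_z(nf, nh);
    IntegerMatrix contacts(nf, nh);
    IntegerVector contacts_total(nf), hb_native(nf);
    double cut2 = M.par.contact_cutoff * M.par.contact_cutoff;
    int nhb = M.topo.hbd.size();
    std::vector<char> part(n);

    for (int f = 0; f < nf; f++) {
        const double* x = REAL(traj) + (std::size_t)f * 9 * n;
        M.derived_sites(x);
        // NH projections and helix CA z centroids
        for (int h = 0; h < nh; h++) {
            int a = helices(h, 0), b = helices(h, 1);
            double acc = 0; int cnt = 0; double zacc = 0;
            for (int i = a; i <= b; i++) {
                zacc += x[9*i + 5];  // CA z
                if (!M.hasH[i]) continue;
                double v[3];
                vsub(v, x + 9*i, &M.H[3*i]);   // N - H, points along helix axis
                acc += v[2] / vnorm(v);
                cnt++;
            }
            nhp(f, h) = cnt ? acc / cnt : NA_REAL;
            com_z(f, h) = zacc / (b - a + 1);
        }
        // native H-bond satisfaction + helicity (participation)
        std::fill(part.begin(), part.end(), 0);
        int sat = 0;
        for (int k = 0; k < nhb; k++) {
            double s = hb_pair_s(M, x, M.topo.hbd[k], M.topo.hba[k]);
            if (s >= 0.25) {   // lenient count threshold: robust to thermal wobble
                sat++;
                part[M.topo.hbd[k]] = 1;
                part[M.topo.hba[k]] = 1;
            }
        }
        hb_native[f] = sat;
        for (int h = 0; h < nh; h++) {
            int a = helices(h, 0), b = helices(h, 1);
            int c = 0;
            for (int i = a; i <= b; i++) c += part[i];
            helicity(f, h) = (double)c / (b - a + 1);
        }
        // inter-helix CB contacts
        int tot = 0;
        std::vector<int> per(nh, 0);
        for (int i = 0; i < n; i++) {
            int hi = M.topo.helix[i];
            if (hi < 0) continue;
            for (int j = i + 1; j < n; j++) {
                int hj = M.topo.helix[j];
                if (hj < 0 || hj == hi) continue;
                double v[3]; vsub(v, &M.CB[3*i], &M.CB[3*j]);
                if (vnorm2(v) <= cut2) {
                    tot++;
                    per[hi]++; per[hj]++;
                }
            }
        }
        contacts_total[f] = tot;
        for (int h = 0; h < nh; h++) contacts(f, h) = per[h];
    }
    return List::create(_["nh"] = nhp, _["helicity"] = helicity,
                        _["contacts"] = contacts, _["contacts_total"] = contacts_total,
                        _["hb_native"] = hb_native, _["com_z"] = com_z);
}

// contact counts per frame between a target residue set and all other helices
// [[Rcpp::export]]
IntegerVector cpp_contact_series(NumericVector traj, List topo, List params,
                                 IntegerVector target) {
    Model M;
    M.init(parse_topology(topo), parse_params(params));
    IntegerVector dim = traj.attr("dim");
    int n = dim[1], nf = dim[2];
    std::vector<char> in_t(n, 0);
    for (int k = 0; k < target.size(); k++) in_t[target[k]] = 1;
    double cut2 = M.par.contact_cutoff * M.par.contact_cutoff;
    IntegerVector out(nf);
    for (int f = 0; f < nf; f++) {
        const double* x = REAL(traj) + (std::size_t)f * 9 * n;
        M.derived_sites(x);
        int cnt = 0;
        for (int i = 0; i < n; i++) {
            if (!in_t[i]) continue;
            for (int j = 0; j < n; j++) {
                if (in_t[j] || M.topo.helix[j] < 0) continue;
                double v[3]; vsub(v, &M.CB[3*i], &M.CB[3*j]);
                if (vnorm2(v) <= cut2) cnt++;
            }
        }
        out[f] = cnt;
    }
    return out;
}

// [[Rcpp::export]]
List cpp_derived_sites(NumericMatrix coords) {
    int n = coords.ncol();
    Model M;
    Topology t; t.n = n;
    t.role.assign(n, 0); t.helix.assign(n, -1); t.dG.assign(n, 0.0);
    M.init(t, Params());
    M.derived_sites(REAL(coords));
    NumericMatrix H(n, 3), O(n, 3), CBm(n, 3);
    LogicalVector hasH(n), hasO(n);
    for (int i = 0; i < n; i++) {
        for (int c = 0; c < 3; c++) {
            H(i, c) = M.H[3*i + c];
            O(i, c) = M.O[3*i + c];
            CBm(i, c) = M.CB[3*i + c];
        }
        hasH[i] = (bool)M.hasH[i];
        hasO[i] = (bool)M.hasO[i];
        if (!M.hasH[i]) { H(i, 0) = H(i, 1) = H(i, 2) = NA_REAL; }
        if (!M.hasO[i]) { O(i, 0) = O(i, 1) = O(i, 2) = NA_REAL; }
    }
    return List::create(_["H"] = H, _["O"] = O, _["CB"] = CBm,
                        _["has_H"] = hasH, _["has_O"] = hasO);
}

// H-bond list on a single conformation (used by helix annotation and analyses)
// [[Rcpp::export]]
NumericMatrix cpp_hbond_list(NumericMatrix coords, List topo, List params) {
    List e = cpp_energy(coords, topo, params, true);
    return e["hbonds"];
}
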