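"""Generate the benzene wavefunction fixtures shipped under inst/extdata.

Produces, from an ideal D6h geometry (r_CC = 1.397 A, r_CH = 1.087 A):
  benzene_rhf_631gd.molden   geometry, 6-31G(d) basis (6d cartesian), the
                             MOs needed by the CI fixtures (all 21 occupied
                             + low virtuals incl. the pi* set)
  benzene_cas66.civec        all-pi CAS-CI (6 electrons, 6 orbitals) vector
  benzene_cas3018.civec      valence CAS-CI (30 electrons, 18 orbitals)
                             vector, leading terms of the normalised vector
  benzene_reference_values.tsv  engine-evaluated MO and Psi spot values used
                             to pin the R-side evaluator
  MANIFEST                   sha256 checksums

Determinant convention in .civec files: coefficients refer to spin-factored
determinants whose occupied orbitals are listed in ascending MO order
(alpha block and beta block separately).  The sign correction from the
frozen-core/active operator ordering used internally is applied on output.

Run:  python make_fixtures.py  (writes into ../extdata, caches in scratch/)
"""

import hashlib
import os
import sys
import numpy as np

sys.path.insert(0, os.path.dirname(os.path.abspath(__file__)))
import minichem as mc

HERE = os.path.dirname(os.path.abspath(__file__))
EXTDATA = os.path.normpath(os.path.join(HERE, "..", "extdata"))
SCRATCH = os.path.normpath(os.path.join(HERE, "..", "..", "scratch"))
R_CC = 1.397
R_CH = 1.087


def run_rhf():
    cache = os.path.join(SCRATCH, "benzene_rhf.npz")
    atoms = mc.benzene_geometry(R_CC, R_CH)
    basis = mc.AOBasisSet(atoms)
    if os.path.exists(cache):
        d = np.load(cache)
        out = {k: d[k] for k in d.files}
        out["nocc"] = int(out["nocc"])
        return atoms, basis, out
    print("computing ERIs (%d AOs) ..." % basis.nao)
    eri = mc.eri_packed(basis.lmn, basis.cen, basis.nprim, basis.exps,
                        basis.coefs)
    print("running RHF ...")
    out = mc.rhf(basis, atoms, eri=eri)
    np.savez_compressed(cache, E=out["E"], C=out["C"], eps=out["eps"],
                        S=out["S"], h=out["h"], eri=out["eri"],
                        Enuc=out["Enuc"], nocc=out["nocc"])
    return atoms, basis, out


_D_PAIRS = [(0, 0), (1, 1), (2, 2), (0, 1), (0, 2), (1, 2)]


def _dfprod(lmn):
    return (mc.df(2 * lmn[0] - 1) * mc.df(2 * lmn[1] - 1)
            * mc.df(2 * lmn[2] - 1))


def point_op_ao_matrix(atoms, basis, A):
    """AO representation of an orthogonal point operation r -> A r that
    maps the atom set onto itself.  Handles s, p and cartesian-d shells
    with per-component normalisation."""
    nat = len(atoms)
    amap = []
    for i, (sym, p) in enumerate(atoms):
        q = A @ p
        hits = [j for j, (s2, r) in enumerate(atoms)
                if s2 == sym and np.linalg.norm(r - q) < 1e-8]
        assert len(hits) == 1, "geometry not symmetric under the operation"
        amap.append(hits[0])
    nao_of = {}
    for sym in set(s for s, _ in atoms):
        nao_of[sym] = sum(len(mc.CART[mc.ANG[t]])
                          for t, _, _ in mc.BASIS_631GD[sym])
    offs = np.zeros(nat, dtype=int)
    o = 0
    for i, (sym, _) in enumerate(atoms):
        offs[i] = o
        o += nao_of[sym]
    # component-mixing blocks: (R ao_a)(r) = ao_a(A r); for a monomial of
    # degree l this expands over the shell's components on the image atom
    p_block = A.copy()  # mono_a(A d) = sum_b A[a, b] mono_b(d)
    d_block = np.zeros((6, 6))
    for a, (al, be) in enumerate(_D_PAIRS):
        for b, (i2, j2) in enumerate(_D_PAIRS):
            if i2 == j2:
                d_block[a, b] = A[al, i2] * A[be, i2]
            else:
                d_block[a, b] = A[al, i2] * A[be, j2] + A[al, j2] * A[be, i2]
    R = np.zeros((basis.nao, basis.nao))
    m = 0
    while m < basis.nao:
        ia = basis.ao_atom[m]
        local = m - offs[ia]
        tgt0 = offs[amap[ia]]
        L = int(basis.lmn[m].sum())  # first component of a shell block
        ncomp = len(mc.CART[L])
        for a in range(ncomp):
            for b in range(ncomp):
                if L == 0:
                    c = 1.0
                elif L == 1:
                    c = p_block[a, b]
                else:
                    c = d_block[a, b]
                if c != 0.0:
                    na = 1.0 / np.sqrt(_dfprod(mc.CART[L][a]))
                    nb = 1.0 / np.sqrt(_dfprod(mc.CART[L][b]))
                    R[tgt0 + local + b, m + a] += c * na / nb
        m += ncomp
    return R


def sigma_v_ao_matrix(atoms, basis, phi=0.0):
    """Reflection through the plane containing z and the in-plane
    direction at angle phi; phi = 0 passes through atom 1, phi = pi/6
    through the C1-C2 bond midpoint."""
    c2, s2 = np.cos(2 * phi), np.sin(2 * phi)
    A = np.array([[c2, s2, 0.0], [s2, -c2, 0.0], [0.0, 0.0, 1.0]])
    return point_op_ao_matrix(atoms, basis, A)


def symmetry_adapt_degenerate(C, eps, S, R, tol=1e-7):
    """Rotate each degenerate MO pair/group to sigma_v eigenfunctions
    (even first), with a sign convention (largest coefficient positive).
    Canonicalises the arbitrary eigensolver rotation so that truncated CI
    expansions are reproducible and symmetry-clean."""
    C = C.copy()
    n = C.shape[1]
    i = 0
    while i < n:
        j = i + 1
        while j < n and abs(eps[j] - eps[j - 1]) < tol:
            j += 1
        g = j - i
        if g > 1:
            Cg = C[:, i:j]
            M = Cg.T @ S @ (R @ Cg)
            M = 0.5 * (M + M.T)
            w, v = np.linalg.eigh(M)
            order = np.argsort(-w)  # even (+1) first
            C[:, i:j] = Cg @ v[:, order]
        for k in range(i, j):
            mx = np.argmax(np.abs(C[:, k]))
            if C[mx, k] < 0:
                C[:, k] = -C[:, k]
        i = j
    return C


def pi_orbital_flags(basis, S, C):
    """True for MOs antisymmetric w.r.t. the molecular (xy) plane."""
    z_odd = basis.lmn[:, 2] % 2 == 1
    w_all = np.einsum("mi,mn,ni->i", C, S, C)
    Szz = S[np.ix_(~z_odd, ~z_odd)]
    Cin = C[~z_odd, :]
    w_in = np.einsum("mi,mn,ni->i", Cin, Szz, Cin)
    return (w_in / w_all) < 1e-6


def interleave_sign(frozen, active_occ):
    """Parity of merging (frozen asc)+(active occ asc) into ascending order."""
    inv = sum(1 for f in frozen for a in active_occ if a < f)
    return -1.0 if inv % 2 else 1.0


def ci_terms(cas, ci, act, frozen):
    """Flatten CI matrix to (alpha_occ_str, beta_occ_str, coef) in the
    all-ascending determinant convention, sorted by |c| desc then lexico."""
    terms = []
    for ia, sa in enumerate(cas.sa):
        stra = "".join("1" if k in sa else "0" for k in range(cas.norb))
        occ_a = [act[k] for k in sa]
        sg_a = interleave_sign(frozen, occ_a)
        for ib, sb in enumerate(cas.sb):
            c = ci[ia, ib]
            if abs(c) < 1e-12:
                continue
            strb = "".join("1" if k in sb else "0" for k in range(cas.norb))
            occ_b = [act[k] for k in sb]
            sg_b = interleave_sign(frozen, occ_b)
            terms.append((stra, strb, sg_a * sg_b * c))
    terms.sort(key=lambda t: (-abs(t[2]), t[0], t[1]))
    if terms[0][2] < 0:
        terms = [(a, b, -c) for a, b, c in terms]
    return terms


def write_civec(path, comment, norb_total, nalpha, nbeta, act, frozen, terms,
                max_terms=None):
    tot = sum(c * c for _, _, c in terms)
    if max_terms is not None:
        terms = terms[:max_terms]
    cap = sum(c * c for _, _, c in terms)
    with open(path, "w") as f:
        f.write("# DVMS CI vector, one determinant per line\n")
        f.write("# %s\n" % comment)
        f.write("format civec-1\n")
        f.write("norb %d\n" % norb_total)
        f.write("nalpha %d\nnbeta %d\n" % (nalpha, nbeta))
        f.write("active " + " ".join(str(a + 1) for a in act) + "\n")
        f.write("frozen " + " ".join(str(a + 1) for a in frozen) + "\n")
        f.write("norm_total %.12f\n" % tot)
        f.write("norm_listed %.12f\n" % cap)
        f.write("nterm %d\n" % len(terms))
        for a, b, c in terms:
            f.write("%s %s % .12e\n" % (a, b, c))
    print("wrote %s (%d terms, captured %.6f of %.6f)"
          % (path, len(terms), cap, tot))


def write_molden(path, atoms, mo_idx, C, eps, nocc):
    with open(path, "w") as f:
        f.write("[Molden Format]\n[Title]\n")
        f.write(" benzene RHF/6-31G(d), ideal D6h r_CC=%.3f A r_CH=%.3f A, "
                "cartesian 6d\n" % (R_CC, R_CH))
        f.write("[Atoms] AU\n")
        for i, (sym, xyz) in enumerate(atoms):
            f.write("%-2s %3d %3d %18.10f %18.10f %18.10f\n"
                    % (sym, i + 1, mc.Z_OF[sym], xyz[0], xyz[1], xyz[2]))
        f.write("[GTO]\n")
        for i, (sym, _) in enumerate(atoms):
            f.write("%d 0\n" % (i + 1))
            for (typ, es, cs) in mc.BASIS_631GD[sym]:
                f.write(" %s %4d 1.00\n" % (typ.lower(), len(es)))
                for a, c in zip(es, cs):
                    f.write("  %18.10e %18.10e\n" % (a, c))
            f.write("\n")
        f.write("[6D]\n[MO]\n")
        for k in mo_idx:
            f.write(" Sym= %da\n Ene= %.10f\n Spin= Alpha\n Occup= %.1f\n"
                    % (k + 1, eps[k], 2.0 if k < nocc else 0.0))
            for m in range(C.shape[0]):
                if abs(C[m, k]) >= 1e-12:
                    f.write(" %4d %.10e\n" % (m + 1, C[m, k]))
    print("wrote", path)


def reread_molden_C(path, nao, nmo):
    """Coefficients as actually stored (so reference values are computed
    from the very numbers the R reader will see)."""
    C = np.zeros((nao, nmo))
    k = -1
    with open(path) as f:
        in_mo = False
        for line in f:
            if line.strip().startswith("[MO]"):
                in_mo = True
                continue
            if not in_mo:
                continue
            if line.strip().startswith("Sym="):
                k += 1
                continue
            parts = line.split()
            if len(parts) == 2 and parts[0].isdigit():
                C[int(parts[0]) - 1, k] = float(parts[1])
    return C


def psi_engine(basis, C, occ_lists_a, occ_lists_b, coefs, x):
    """Engine-side Psi at 3N config x (alpha block then beta block)."""
    n = len(x) // 3
    pts = np.array(x).reshape(n, 3)
    na = len(occ_lists_a[0])
    Mall = mc.mo_values(basis, C, pts, list(range(C.shape[1])))
    tot = 0.0
    for oa, ob, c in zip(occ_lists_a, occ_lists_b, coefs):
        da = np.linalg.det(Mall[:na][:, oa])
        db = np.linalg.det(Mall[na:][:, ob])
        tot += c * da * db
    return tot


def main():
    os.makedirs(EXTDATA, exist_ok=True)
    os.makedirs(SCRATCH, exist_ok=True)
    atoms, basis, out = run_rhf()
    C, eps, S = out["C"], out["eps"], out["S"]
    frame = os.environ.get("DVMS_SYMMETRY_FRAME", "bond")
    R = sigma_v_ao_matrix(atoms, basis,
                          phi=(np.pi / 6 if frame == "bond" else 0.0))
    C = symmetry_adapt_degenerate(C, eps, S, R)
    # verify: still orthonormal and sigma_v-diagonal within pairs
    assert np.max(np.abs(C.T @ S @ C - np.eye(basis.nao))) < 1e-8
    eri, h = out["eri"], out["h"]
    nocc = out["nocc"]
    print("RHF energy %.8f, nocc %d, nao %d" % (out["E"], nocc, basis.nao))
    is_pi = pi_orbital_flags(basis, S, C)
    occ_pi = [i for i in range(nocc) if is_pi[i]]
    vir_pi = [i for i in range(nocc, basis.nao) if is_pi[i]][:3]
    print("pi occupied:", occ_pi, "eps", eps[occ_pi])
    print("pi virtual:", vir_pi, "eps", eps[vir_pi])
    print("orbital energies around gap:", eps[max(0, nocc - 5):nocc + 6])
    assert len(occ_pi) == 3

    # ---------------- (6,6) all-pi CAS-CI ----------------
    act66 = sorted(occ_pi + vir_pi)
    frozen66 = [i for i in range(nocc) if i not in act66]
    g66 = mc.mo_transform_active(eri, C, act66, basis.nao)
    h66, efz66 = mc.core_hamiltonian_active(h, eri, C, frozen66, act66,
                                            basis.nao)
    cas66 = mc.CASCI(h66, g66, 6, 3, 3, Efz=efz66, Enuc=out["Enuc"])
    e66, ci66 = cas66.solve_dense()
    print("CAS-CI(6,6) energy %.8f (corr %.6f)" % (e66, e66 - out["E"]))
    terms66 = ci_terms(cas66, ci66, act66, frozen66)
    write_civec(os.path.join(EXTDATA, "benzene_cas66.civec"),
                "all-pi CAS-CI(6,6) from RHF/6-31G(d) orbitals, E = %.8f Eh"
                % e66, basis.nao, nocc, nocc, act66, frozen66, terms66)

    # ---------------- valence (30,18) CAS-CI ----------------
    act3018 = list(range(6, 24))  # 15 valence-occupied + 3 lowest virtuals
    frozen3018 = list(range(6))
    cache = os.path.join(SCRATCH, "benzene_cas3018.npz")
    if os.path.exists(cache):
        d = np.load(cache)
        e3018 = float(d["e"])
        ci3018 = d["ci"]
        cas3018 = mc.CASCI(np.asarray(d["h1"]), np.asarray(d["g"]), 18, 15, 15,
                           Efz=float(d["efz"]), Enuc=out["Enuc"])
    else:
        print("transforming integrals for (30,18) ...")
        g30 = mc.mo_transform_active(eri, C, act3018, basis.nao)
        h30, efz30 = mc.core_hamiltonian_active(h, eri, C, frozen3018,
                                                act3018, basis.nao)
        print("building string lists ...")
        cas3018 = mc.CASCI(h30, g30, 18, 15, 15, Efz=efz30, Enuc=out["Enuc"])
        print("Davidson, %d determinants ..." % (cas3018.nsa * cas3018.nsb))
        e3018, ci3018 = cas3018.solve_davidson(tol=1e-8)
        np.savez_compressed(cache, e=e3018, ci=ci3018, h1=h30, g=g30,
                            efz=efz30)
    print("CAS-CI(30,18) energy %.8f (corr %.6f)" % (e3018, e3018 - out["E"]))
    terms3018 = ci_terms(cas3018, ci3018, act3018, frozen3018)
    write_civec(os.path.join(EXTDATA, "benzene_cas3018.civec"),
                "valence CAS-CI(30,18) from RHF/6-31G(d) orbitals, "
                "E = %.8f Eh; leading terms of the normalised vector"
                % e3018, basis.nao, nocc, nocc, act3018, frozen3018,
                terms3018, max_terms=400)

    # ---------------- Molden MO fixture ----------------
    mo_keep = sorted(set(range(nocc)) | set(act3018) | set(act66))
    write_molden(os.path.join(EXTDATA, "benzene_rhf_631gd.molden"),
                 atoms, mo_keep, C, eps, nocc)

    # ---------------- reference spot values ----------------
    # recompute from the file as written (stored precision, zero-trimmed)
    Cfile = np.zeros_like(C)
    Cstored = reread_molden_C(
        os.path.join(EXTDATA, "benzene_rhf_631gd.molden"),
        basis.nao, len(mo_keep))
    for col, k in enumerate(mo_keep):
        Cfile[:, k] = Cstored[:, col]
    C = Cfile
    rng = np.random.default_rng(20200305)
    pts = rng.uniform(-5.0, 5.0, size=(12, 3))
    pts[:, 2] = rng.uniform(-3.0, 3.0, size=12)
    vals = mc.mo_values(basis, C, pts, mo_keep)
    ref = os.path.join(EXTDATA, "benzene_reference_values.tsv")
    with open(ref, "w") as f:
        f.write("# engine-evaluated reference values, benzene RHF/6-31G(d)\n")
        f.write("# block 1: MO values; columns: x y z bohr then MO value "
                "for each stored MO (1-based indices listed)\n")
        f.write("MOIDX " + " ".join(str(i + 1) for i in mo_keep) + "\n")
        for p, row in zip(pts, vals):
            f.write("MOVAL %12.8f %12.8f %12.8f " % tuple(p)
                    + " ".join("%.12e" % v for v in row) + "\n")
        # Psi spot checks: random electron configuration near atoms
        f.write("# block 2: Psi values; config = 42 electrons (21 alpha "
                "then 21 beta), each x y z bohr, then Psi for the single "
                "determinant and for the 7 leading (6,6) terms\n")
        occ0 = list(range(nocc))
        for rep in range(3):
            x = []
            centers = [a[1] for a in atoms] * 4
            for e in range(42):
                c0 = centers[rng.integers(0, len(centers))]
                x.extend(c0 + rng.normal(0, 0.7, 3))
            # single determinant
            psi1 = psi_engine(basis, C, [occ0], [occ0], [1.0], x)
            # 7 leading (6,6) terms (ascending convention, as in file)
            oa, ob, cc = [], [], []
            for a, b, c in terms66[:7]:
                occ_a = sorted(frozen66 + [act66[k] for k, ch in enumerate(a)
                                           if ch == "1"])
                occ_b = sorted(frozen66 + [act66[k] for k, ch in enumerate(b)
                                           if ch == "1"])
                oa.append(occ_a)
                ob.append(occ_b)
                cc.append(c)
            psi7 = psi_engine(basis, C, oa, ob, cc, x)
            f.write("PSI " + " ".join("%.8f" % v for v in x)
                    + " %.12e %.12e\n" % (psi1, psi7))
    print("wrote", ref)

    # ---------------- manifest ----------------
    man = os.path.join(EXTDATA, "MANIFEST")
    names = ["benzene_rhf_631gd.molden", "benzene_cas66.civec",
             "benzene_cas3018.civec", "benzene_reference_values.tsv"]
    with open(man, "w") as f:
        f.write("# md5 checksums of the benzene wavefunction fixtures\n")
        for nm in names:
            with open(os.path.join(EXTDATA, nm), "rb") as g:
                f.write("%s  %s\n"
                        % (hashlib.md5(g.read()).hexdigest(), nm))
    print("wrote", man)

    # report leading groups for the truncation protocol
    for label, terms in [("(6,6)", terms66), ("(30,18)", terms3018)]:
        mags = [abs(c) for _, _, c in terms[:30]]
        print(label, "leading |c|:", " ".join("%.5f" % m for m in mags))


if __name__ == "__main__":
    main()
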