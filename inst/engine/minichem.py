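"""Minimal restricted Hartree-Fock + determinant CAS-CI engine.

Self-contained backend used to (re)generate the benzene wavefunction fixtures
shipped with the dvms R package: Gaussian-basis integrals (McMurchie-Davidson),
RHF/6-31G(d) with DIIS, and CAS-CI in a frozen-core active space, solved
either densely (small spaces) or by Davidson iteration (the valence (30,18)
space, ~6.7e5 determinants).

Only numpy/scipy/numba are required.  Cartesian d functions (6d), each
component individually normalised; AO order within a shell: s; px,py,pz;
xx,yy,zz,xy,xz,yz.
"""

import numpy as np
from numba import njit
import itertools

BOHR_PER_ANGSTROM = 1.0 / 0.529177210903

# 6-31G / 6-31G(d) exponents and contraction coefficients (published values;
# SP shells split into separate S and P shells sharing exponents).
BASIS_631GD = {
    "H": [
        ("S", [18.7311370, 2.8253937, 0.6401217],
              [0.03349460, 0.23472695, 0.81375733]),
        ("S", [0.1612778], [1.0]),
    ],
    "C": [
        ("S", [3047.5249, 457.36951, 103.94869, 29.210155, 9.2866630, 3.1639270],
              [0.0018347, 0.0140373, 0.0688426, 0.2321844, 0.4679413, 0.3623120]),
        ("S", [7.8682724, 1.8812885, 0.5442493],
              [-0.1193324, -0.1608542, 1.1434564]),
        ("P", [7.8682724, 1.8812885, 0.5442493],
              [0.0689991, 0.3164240, 0.7443083]),
        ("S", [0.1687144], [1.0]),
        ("P", [0.1687144], [1.0]),
        ("D", [0.8], [1.0]),
    ],
}

ANG = {"S": 0, "P": 1, "D": 2}
CART = {
    0: [(0, 0, 0)],
    1: [(1, 0, 0), (0, 1, 0), (0, 0, 1)],
    2: [(2, 0, 0), (0, 2, 0), (0, 0, 2), (1, 1, 0), (1, 0, 1), (0, 1, 1)],
}
Z_OF = {"H": 1, "C": 6}


def df(n):  # double factorial, df(-1) = 1
    return 1 if n <= 0 else n * df(n - 2)


def prim_norm(a, l, m, n):
    L = l + m + n
    return ((2 * a / np.pi) ** 0.75 * (4 * a) ** (L / 2.0)
            / np.sqrt(df(2 * l - 1) * df(2 * m - 1) * df(2 * n - 1)))


class AOBasisSet:
    """Flat cartesian AO list with fully folded normalisation."""

    def __init__(self, atoms):
        # atoms: list of (symbol, xyz_bohr)
        self.atoms = atoms
        lmn, cen, exps, coefs, nprim, shell_id, ao_atom = [], [], [], [], [], [], []
        self.shells = []  # (atom index, l, exps, contraction coefs)
        sid = 0
        for ia, (sym, xyz) in enumerate(atoms):
            for (typ, es, cs) in BASIS_631GD[sym]:
                l = ANG[typ]
                self.shells.append((ia, l, list(es), list(cs)))
                for (i, j, k) in CART[l]:
                    lmn.append((i, j, k))
                    cen.append(xyz)
                    exps.append(list(es))
                    coefs.append([c * prim_norm(a, i, j, k)
                                  for a, c in zip(es, cs)])
                    nprim.append(len(es))
                    shell_id.append(sid)
                    ao_atom.append(ia)
                sid += 1
        self.nao = len(lmn)
        mp = max(nprim)
        self.lmn = np.array(lmn, dtype=np.int64)
        self.cen = np.array(cen, dtype=np.float64)
        self.nprim = np.array(nprim, dtype=np.int64)
        self.exps = np.zeros((self.nao, mp))
        self.coefs = np.zeros((self.nao, mp))
        for m in range(self.nao):
            self.exps[m, : nprim[m]] = exps[m]
            self.coefs[m, : nprim[m]] = coefs[m]
        self.shell_id = np.array(shell_id, dtype=np.int64)
        self.ao_atom = np.array(ao_atom, dtype=np.int64)
        # contraction self-overlap -> unit-normalised AOs
        S = overlap_matrix(self.lmn, self.cen, self.nprim, self.exps, self.coefs)
        self.coefs /= np.sqrt(np.diag(S))[:, None]


# ---------------------------------------------------------------- integrals

@njit(cache=True)
def _E_coef(i, j, a, b, AB):
    """1-D Hermite expansion coefficients E_t^{ij}, t = 0..i+j (includes K_AB)."""
    p = a + b
    E = np.zeros((i + 1, j + 1, i + j + 1))
    E[0, 0, 0] = np.exp(-a * b / p * AB * AB)
    PA = -b * AB / p
    PB = a * AB / p
    for ii in range(1, i + 1):
        for t in range(ii + 1):
            v = PA * E[ii - 1, 0, t]
            if t > 0:
                v += E[ii - 1, 0, t - 1] / (2.0 * p)
            if t + 1 <= ii - 1:
                v += (t + 1) * E[ii - 1, 0, t + 1]
            E[ii, 0, t] = v
    for jj in range(1, j + 1):
        for ii in range(i + 1):
            for t in range(ii + jj + 1):
                v = PB * E[ii, jj - 1, t]
                if t > 0:
                    v += E[ii, jj - 1, t - 1] / (2.0 * p)
                if t + 1 <= ii + jj - 1:
                    v += (t + 1) * E[ii, jj - 1, t + 1]
                E[ii, jj, t] = v
    return E[i, j, :]


@njit(cache=True)
def _boys(nmax, x, out):
    if x < 1e-13:
        for n in range(nmax + 1):
            out[n] = 1.0 / (2 * n + 1)
    elif x < 35.0:
        s = 0.0
        term = 1.0 / (2 * nmax + 1)
        k = 0
        while True:
            s += term
            k += 1
            term *= 2.0 * x / (2 * nmax + 2 * k + 1)
            if term < 1e-17 * s or k > 500:
                break
        ex = np.exp(-x)
        out[nmax] = ex * s
        for n in range(nmax - 1, -1, -1):
            out[n] = (2.0 * x * out[n + 1] + ex) / (2 * n + 1)
    else:
        out[0] = 0.5 * np.sqrt(np.pi / x)
        ex = np.exp(-x)
        for n in range(nmax):
            out[n + 1] = ((2 * n + 1) * out[n] - ex) / (2.0 * x)


@njit(cache=True)
def _R_tensor(tmax, umax, vmax, p, X, Y, Z):
    """Hermite-Coulomb R_{tuv} at n = 0."""
    L = tmax + umax + vmax
    T = p * (X * X + Y * Y + Z * Z)
    F = np.zeros(L + 1)
    _boys(L, T, F)
    R = np.zeros((L + 1, tmax + 1, umax + 1, vmax + 1))
    for n in range(L + 1):
        R[n, 0, 0, 0] = (-2.0 * p) ** n * F[n]
    for t in range(1, tmax + 1):
        for n in range(L - t + 1):
            v = X * R[n + 1, t - 1, 0, 0]
            if t > 1:
                v += (t - 1) * R[n + 1, t - 2, 0, 0]
            R[n, t, 0, 0] = v
    for u in range(1, umax + 1):
        for t in range(tmax + 1):
            for n in range(L - t - u + 1):
                v = Y * R[n + 1, t, u - 1, 0]
                if u > 1:
                    v += (u - 1) * R[n + 1, t, u - 2, 0]
                R[n, t, u, 0] = v
    for w in range(1, vmax + 1):
        for u in range(umax + 1):
            for t in range(tmax + 1):
                for n in range(L - t - u - w + 1):
                    v = Z * R[n + 1, t, u, w - 1]
                    if w > 1:
                        v += (w - 1) * R[n + 1, t, u, w - 2]
                    R[n, t, u, w] = v
    return R[0]


@njit(cache=True)
def overlap_matrix(lmn, cen, nprim, exps, coefs):
    nao = lmn.shape[0]
    S = np.zeros((nao, nao))
    for m in range(nao):
        for n in range(m + 1):
            acc = 0.0
            for pp in range(nprim[m]):
                a = exps[m, pp]
                ca = coefs[m, pp]
                for qq in range(nprim[n]):
                    b = exps[n, qq]
                    cb = coefs[n, qq]
                    p = a + b
                    v = (np.pi / p) ** 1.5
                    for ax in range(3):
                        e = _E_coef(lmn[m, ax], lmn[n, ax], a, b,
                                    cen[m, ax] - cen[n, ax])
                        v *= e[0]
                    acc += ca * cb * v
            S[m, n] = acc
            S[n, m] = acc
    return S


@njit(cache=True)
def kinetic_matrix(lmn, cen, nprim, exps, coefs):
    nao = lmn.shape[0]
    T = np.zeros((nao, nao))
    for m in range(nao):
        for n in range(m + 1):
            acc = 0.0
            for pp in range(nprim[m]):
                a = exps[m, pp]
                ca = coefs[m, pp]
                for qq in range(nprim[n]):
                    b = exps[n, qq]
                    cb = coefs[n, qq]
                    p = a + b
                    pref = (np.pi / p) ** 1.5
                    # 1-D overlaps S(i, j + d) for d in {-2, 0, +2}
                    s0 = np.zeros(3)
                    sp2 = np.zeros(3)
                    sm2 = np.zeros(3)
                    for ax in range(3):
                        i = lmn[m, ax]
                        j = lmn[n, ax]
                        AB = cen[m, ax] - cen[n, ax]
                        s0[ax] = _E_coef(i, j, a, b, AB)[0]
                        sp2[ax] = _E_coef(i, j + 2, a, b, AB)[0]
                        if j >= 2:
                            sm2[ax] = _E_coef(i, j - 2, a, b, AB)[0]
                    tt = 0.0
                    for ax in range(3):
                        j = lmn[n, ax]
                        tx = (-2.0 * b * b * sp2[ax]
                              + b * (2 * j + 1) * s0[ax]
                              - 0.5 * j * (j - 1) * sm2[ax])
                        prod = tx
                        for ax2 in range(3):
                            if ax2 != ax:
                                prod *= s0[ax2]
                        tt += prod
                    acc += ca * cb * pref * tt
            T[m, n] = acc
            T[n, m] = acc
    return T


@njit(cache=True)
def nuclear_matrix(lmn, cen, nprim, exps, coefs, atom_xyz, atom_Z):
    nao = lmn.shape[0]
    V = np.zeros((nao, nao))
    for m in range(nao):
        for n in range(m + 1):
            acc = 0.0
            for pp in range(nprim[m]):
                a = exps[m, pp]
                ca = coefs[m, pp]
                for qq in range(nprim[n]):
                    b = exps[n, qq]
                    cb = coefs[n, qq]
                    p = a + b
                    Ex = _E_coef(lmn[m, 0], lmn[n, 0], a, b, cen[m, 0] - cen[n, 0])
                    Ey = _E_coef(lmn[m, 1], lmn[n, 1], a, b, cen[m, 1] - cen[n, 1])
                    Ez = _E_coef(lmn[m, 2], lmn[n, 2], a, b, cen[m, 2] - cen[n, 2])
                    Px = (a * cen[m, 0] + b * cen[n, 0]) / p
                    Py = (a * cen[m, 1] + b * cen[n, 1]) / p
                    Pz = (a * cen[m, 2] + b * cen[n, 2]) / p
                    tmax = lmn[m, 0] + lmn[n, 0]
                    umax = lmn[m, 1] + lmn[n, 1]
                    vmax = lmn[m, 2] + lmn[n, 2]
                    for ic in range(atom_xyz.shape[0]):
                        R = _R_tensor(tmax, umax, vmax, p,
                                      Px - atom_xyz[ic, 0],
                                      Py - atom_xyz[ic, 1],
                                      Pz - atom_xyz[ic, 2])
                        s = 0.0
                        for t in range(tmax + 1):
                            for u in range(umax + 1):
                                for w in range(vmax + 1):
                                    s += Ex[t] * Ey[u] * Ez[w] * R[t, u, w]
                        acc -= ca * cb * atom_Z[ic] * 2.0 * np.pi / p * s
            V[m, n] = acc
            V[n, m] = acc
    return V


@njit(cache=True)
def _pair_index(i, j):
    return i * (i + 1) // 2 + j if i >= j else j * (j + 1) // 2 + i


@njit(cache=True)
def _eri_ao_quartet(m, n, l, s, lmn, cen, nprim, exps, coefs):
    acc = 0.0
    for p1 in range(nprim[m]):
        a = exps[m, p1]
        ca = coefs[m, p1]
        for p2 in range(nprim[n]):
            b = exps[n, p2]
            cb = coefs[n, p2]
            p = a + b
            Ex1 = _E_coef(lmn[m, 0], lmn[n, 0], a, b, cen[m, 0] - cen[n, 0])
            Ey1 = _E_coef(lmn[m, 1], lmn[n, 1], a, b, cen[m, 1] - cen[n, 1])
            Ez1 = _E_coef(lmn[m, 2], lmn[n, 2], a, b, cen[m, 2] - cen[n, 2])
            Px = (a * cen[m, 0] + b * cen[n, 0]) / p
            Py = (a * cen[m, 1] + b * cen[n, 1]) / p
            Pz = (a * cen[m, 2] + b * cen[n, 2]) / p
            t1 = lmn[m, 0] + lmn[n, 0]
            u1 = lmn[m, 1] + lmn[n, 1]
            v1 = lmn[m, 2] + lmn[n, 2]
            for p3 in range(nprim[l]):
                c = exps[l, p3]
                cc = coefs[l, p3]
                for p4 in range(nprim[s]):
                    d = exps[s, p4]
                    cd = coefs[s, p4]
                    q = c + d
                    Ex2 = _E_coef(lmn[l, 0], lmn[s, 0], c, d, cen[l, 0] - cen[s, 0])
                    Ey2 = _E_coef(lmn[l, 1], lmn[s, 1], c, d, cen[l, 1] - cen[s, 1])
                    Ez2 = _E_coef(lmn[l, 2], lmn[s, 2], c, d, cen[l, 2] - cen[s, 2])
                    Qx = (c * cen[l, 0] + d * cen[s, 0]) / q
                    Qy = (c * cen[l, 1] + d * cen[s, 1]) / q
                    Qz = (c * cen[l, 2] + d * cen[s, 2]) / q
                    t2 = lmn[l, 0] + lmn[s, 0]
                    u2 = lmn[l, 1] + lmn[s, 1]
                    v2 = lmn[l, 2] + lmn[s, 2]
                    alpha = p * q / (p + q)
                    R = _R_tensor(t1 + t2, u1 + u2, v1 + v2, alpha,
                                  Px - Qx, Py - Qy, Pz - Qz)
                    ss = 0.0
                    for t in range(t1 + 1):
                        for u in range(u1 + 1):
                            for w in range(v1 + 1):
                                e1 = Ex1[t] * Ey1[u] * Ez1[w]
                                if e1 == 0.0:
                                    continue
                                for tt in range(t2 + 1):
                                    for uu in range(u2 + 1):
                                        for ww in range(v2 + 1):
                                            sgn = 1.0 if (tt + uu + ww) % 2 == 0 else -1.0
                                            ss += (e1 * sgn
                                                   * Ex2[tt] * Ey2[uu] * Ez2[ww]
                                                   * R[t + tt, u + uu, w + ww])
                    acc += (ca * cb * cc * cd * ss * 2.0 * np.pi ** 2.5
                            / (p * q * np.sqrt(p + q)))
    return acc


@njit(cache=True)
def eri_packed(lmn, cen, nprim, exps, coefs, thresh=1e-12):
    """All unique (mn|ls), 8-fold packed; Schwarz screened."""
    nao = lmn.shape[0]
    npair = nao * (nao + 1) // 2
    qd = np.zeros(npair)
    for m in range(nao):
        for n in range(m + 1):
            qd[_pair_index(m, n)] = np.sqrt(
                abs(_eri_ao_quartet(m, n, m, n, lmn, cen, nprim, exps, coefs)))
    out = np.zeros(npair * (npair + 1) // 2)
    for m in range(nao):
        for n in range(m + 1):
            mn = _pair_index(m, n)
            for l in range(nao):
                for s in range(l + 1):
                    ls = _pair_index(l, s)
                    if ls > mn:
                        continue
                    if qd[mn] * qd[ls] < thresh:
                        continue
                    out[mn * (mn + 1) // 2 + ls] = _eri_ao_quartet(
                        m, n, l, s, lmn, cen, nprim, exps, coefs)
    return out


@njit(cache=True)
def fock_2e(P, eri, nao):
    """G[m,n] = sum_ls P[l,s] (2(mn|ls) - (ml|sn)) / ... via 8-fold loop."""
    G = np.zeros((nao, nao))
    for i in range(nao):
        for j in range(i + 1):
            ij = i * (i + 1) // 2 + j
            for k in range(nao):
                for l in range(k + 1):
                    kl = k * (k + 1) // 2 + l
                    if kl > ij:
                        continue
                    v = eri[ij * (ij + 1) // 2 + kl]
                    if v == 0.0:
                        continue
                    fac = 1.0
                    if i == j:
                        fac *= 0.5
                    if k == l:
                        fac *= 0.5
                    if ij == kl:
                        fac *= 0.5
                    v8 = v * fac
                    # 8 permutations (a,b,c,d) of (ij|kl)
                    for perm in range(8):
                        if perm == 0:
                            a, b2, c2, d2 = i, j, k, l
                        elif perm == 1:
                            a, b2, c2, d2 = j, i, k, l
                        elif perm == 2:
                            a, b2, c2, d2 = i, j, l, k
                        elif perm == 3:
                            a, b2, c2, d2 = j, i, l, k
                        elif perm == 4:
                            a, b2, c2, d2 = k, l, i, j
                        elif perm == 5:
                            a, b2, c2, d2 = l, k, i, j
                        elif perm == 6:
                            a, b2, c2, d2 = k, l, j, i
                        else:
                            a, b2, c2, d2 = l, k, j, i
                        G[a, b2] += P[c2, d2] * v8
                        G[a, d2] -= 0.5 * P[b2, c2] * v8
    return G


def eri_get(eri, i, j, k, l):
    ij = _pair_index(i, j)
    kl = _pair_index(k, l)
    if ij < kl:
        ij, kl = kl, ij
    return eri[ij * (ij + 1) // 2 + kl]


# --------------------------------------------------------------------- RHF

def rhf(basis, atoms, eri=None, maxiter=120, conv=1e-10, verbose=True):
    Zs = np.array([Z_OF[s] for s, _ in atoms], dtype=np.float64)
    xyz = np.array([p for _, p in atoms])
    S = overlap_matrix(basis.lmn, basis.cen, basis.nprim, basis.exps, basis.coefs)
    T = kinetic_matrix(basis.lmn, basis.cen, basis.nprim, basis.exps, basis.coefs)
    V = nuclear_matrix(basis.lmn, basis.cen, basis.nprim, basis.exps, basis.coefs,
                       xyz, Zs)
    if eri is None:
        eri = eri_packed(basis.lmn, basis.cen, basis.nprim, basis.exps, basis.coefs)
    h = T + V
    Enuc = 0.0
    for i in range(len(atoms)):
        for j in range(i):
            Enuc += Zs[i] * Zs[j] / np.linalg.norm(xyz[i] - xyz[j])
    w, U = np.linalg.eigh(S)
    X = U @ np.diag(w ** -0.5) @ U.T
    nocc = int(round(Zs.sum())) // 2
    # core guess
    e, C = np.linalg.eigh(X.T @ h @ X)
    C = X @ C
    P = 2.0 * C[:, :nocc] @ C[:, :nocc].T
    errs, focks = [], []
    Eold = 0.0
    for it in range(maxiter):
        F = h + fock_2e(P, eri, basis.nao)
        err = F @ P @ S - S @ P @ F
        errs.append(err)
        focks.append(F)
        if len(errs) > 8:
            errs.pop(0)
            focks.pop(0)
        if len(errs) > 1:
            nd = len(errs)
            B = -np.ones((nd + 1, nd + 1))
            B[nd, nd] = 0.0
            for a in range(nd):
                for b in range(nd):
                    B[a, b] = np.sum(errs[a] * errs[b])
            rhs = np.zeros(nd + 1)
            rhs[nd] = -1.0
            try:
                cdi = np.linalg.solve(B, rhs)
                F = sum(cdi[a] * focks[a] for a in range(nd))
            except np.linalg.LinAlgError:
                pass
        e, Cp = np.linalg.eigh(X.T @ F @ X)
        C = X @ Cp
        P = 2.0 * C[:, :nocc] @ C[:, :nocc].T
        E = 0.5 * np.sum(P * (h + h + fock_2e(P, eri, basis.nao))) / 1.0
        # recompute consistently: E = 0.5 * sum(P*(h+F_at_P))
        Fp = h + fock_2e(P, eri, basis.nao)
        E = 0.5 * np.sum(P * (h + Fp)) + Enuc
        dE = abs(E - Eold)
        derr = np.max(np.abs(err))
        if verbose:
            print(f"  SCF iter {it:3d}  E = {E:.10f}  dE = {dE:.2e}  |FPS-SPF| = {derr:.2e}")
        if dE < conv and derr < 1e-7:
            break
        Eold = E
    return {"E": E, "C": C, "eps": e, "S": S, "h": h, "eri": eri,
            "Enuc": Enuc, "nocc": nocc, "X": X}


# ------------------------------------------------------- active-space CI

def mo_transform_active(eri, C, act, nao):
    """(pq|rs) over active MO list `act` from packed AO ERIs."""
    na = len(act)
    Ca = C[:, act]
    npair_a = na * (na + 1) // 2
    npair = nao * (nao + 1) // 2
    half = np.zeros((npair_a, npair))
    M = np.zeros((nao, nao))
    for l in range(nao):
        for s in range(l + 1):
            ls = _pair_index(l, s)
            for m in range(nao):
                for n in range(nao):
                    M[m, n] = eri_get(eri, m, n, l, s)
            A = Ca.T @ M @ Ca
            idx = 0
            for p in range(na):
                for q in range(p + 1):
                    half[idx, ls] = A[p, q]
                    idx += 1
    g = np.zeros((na, na, na, na))
    M2 = np.zeros((nao, nao))
    idx = 0
    for p in range(na):
        for q in range(p + 1):
            row = half[idx]
            idx += 1
            for l in range(nao):
                for s in range(l + 1):
                    M2[l, s] = row[_pair_index(l, s)]
                    M2[s, l] = M2[l, s]
            B = Ca.T @ M2 @ Ca
            g[p, q] = B
            g[q, p] = B
    return g


def core_hamiltonian_active(h, eri, C, frozen, act, nao):
    """Effective one-electron ints over `act` plus frozen-core energy."""
    if len(frozen):
        Cf = C[:, frozen]
        Pf = 2.0 * Cf @ Cf.T
        Ff = h + fock_2e(Pf, eri, nao)
        Efz = 0.5 * np.sum(Pf * (h + Ff))
    else:
        Ff = h.copy()
        Efz = 0.0
    Ca = C[:, act]
    return Ca.T @ Ff @ Ca, Efz


# determinant strings ------------------------------------------------------

def make_strings(norb, nelec):
    return [tuple(c) for c in itertools.combinations(range(norb), nelec)]


def string_excitations(strings, norb):
    """Per string: list of (target string index, p(created), q(destroyed), sign)."""
    index = {s: i for i, s in enumerate(strings)}
    exc = []
    for s in strings:
        occ = set(s)
        row = []
        for q in s:
            for p in range(norb):
                if p in occ and p != q:
                    continue
                if p == q:
                    continue
                t = tuple(sorted(occ - {q} | {p}))
                lo, hi = (q, p) if q < p else (p, q)
                nbet = sum(1 for o in s if lo < o < hi)
                row.append((index[t], p, q, 1.0 if nbet % 2 == 0 else -1.0))
        exc.append(row)
    return exc


@njit(cache=True)
def _sigma_kernel(C, sig, h1, g, occ_a, occ_b, exc_a, nexc_a, exc_b, nexc_b,
                  diag):
    nsa, nsb = C.shape
    ne_a = occ_a.shape[1]
    ne_b = occ_b.shape[1]
    # diagonal
    for ia in range(nsa):
        for ib in range(nsb):
            sig[ia, ib] += diag[ia, ib] * C[ia, ib]
    # alpha singles (one-electron + same-spin partial + coulomb w/ beta)
    for ia in range(nsa):
        for x in range(nexc_a[ia]):
            ja = int(exc_a[ia, x, 0])
            p = int(exc_a[ia, x, 1])
            q = int(exc_a[ia, x, 2])
            sg = exc_a[ia, x, 3]
            base = h1[p, q]
            # sum over alpha occ of J/K (common orbitals: occ(ia) minus q)
            for kk in range(ne_a):
                k = occ_a[ia, kk]
                if k == q:
                    continue
                base += g[p, q, k, k] - g[p, k, k, q]
            for ib in range(nsb):
                jb = 0.0
                for kk in range(ne_b):
                    k = occ_b[ib, kk]
                    jb += g[p, q, k, k]
                sig[ja, ib] += sg * (base + jb) * C[ia, ib]
    # beta singles
    for ib in range(nsb):
        for x in range(nexc_b[ib]):
            jb = int(exc_b[ib, x, 0])
            p = int(exc_b[ib, x, 1])
            q = int(exc_b[ib, x, 2])
            sg = exc_b[ib, x, 3]
            base = h1[p, q]
            for kk in range(ne_b):
                k = occ_b[ib, kk]
                if k == q:
                    continue
                base += g[p, q, k, k] - g[p, k, k, q]
            for ia in range(nsa):
                ja_ = 0.0
                for kk in range(ne_a):
                    k = occ_a[ia, kk]
                    ja_ += g[p, q, k, k]
                sig[ia, jb] += sg * (base + ja_) * C[ia, ib]
    return


@njit(cache=True)
def _sigma_doubles_same(C, sig, dbl, ndbl, is_alpha):
    ns = ndbl.shape[0]
    for i in range(ns):
        for x in range(ndbl[i]):
            j = int(dbl[i, x, 0])
            v = dbl[i, x, 1]
            if is_alpha:
                for ib in range(C.shape[1]):
                    sig[j, ib] += v * C[i, ib]
            else:
                for ia in range(C.shape[0]):
                    sig[ia, j] += v * C[ia, i]


@njit(cache=True)
def _sigma_ab(C, sig, g, exc_a, nexc_a, exc_b, nexc_b):
    nsa, nsb = C.shape
    for ia in range(nsa):
        for x in range(nexc_a[ia]):
            ja = int(exc_a[ia, x, 0])
            p = int(exc_a[ia, x, 1])
            q = int(exc_a[ia, x, 2])
            sga = exc_a[ia, x, 3]
            for ib in range(nsb):
                cv = C[ia, ib]
                for y in range(nexc_b[ib]):
                    jb = int(exc_b[ib, y, 0])
                    r = int(exc_b[ib, y, 1])
                    s = int(exc_b[ib, y, 2])
                    sgb = exc_b[ib, y, 3]
                    sig[ja, jb] += sga * sgb * g[p, q, r, s] * cv
    return


class CASCI:
    """Determinant CAS-CI over an active orbital list with frozen core."""

    def __init__(self, h1, g, norb, nelec_a, nelec_b, Efz=0.0, Enuc=0.0):
        self.h1, self.g, self.norb = h1, g, norb
        self.Efz, self.Enuc = Efz, Enuc
        self.sa = make_strings(norb, nelec_a)
        self.sb = self.sa if nelec_b == nelec_a else make_strings(norb, nelec_b)
        self.nsa, self.nsb = len(self.sa), len(self.sb)
        self.occ_a = np.array(self.sa, dtype=np.int64)
        self.occ_b = np.array(self.sb, dtype=np.int64)
        ea = string_excitations(self.sa, norb)
        eb = ea if self.sb is self.sa else string_excitations(self.sb, norb)
        self.exc_a, self.nexc_a = self._pack_exc(ea)
        self.exc_b, self.nexc_b = (self.exc_a, self.nexc_a) if eb is ea \
            else self._pack_exc(eb)
        self.dbl_a = self._double_lists(self.sa, ea)
        self.dbl_b = self.dbl_a if self.sb is self.sa else \
            self._double_lists(self.sb, eb)
        self.diag = self._diagonal()

    @staticmethod
    def _pack_exc(exc):
        mx = max(len(r) for r in exc)
        out = np.zeros((len(exc), mx, 4))
        n = np.zeros(len(exc), dtype=np.int64)
        for i, row in enumerate(exc):
            n[i] = len(row)
            for x, (j, p, q, sg) in enumerate(row):
                out[i, x, 0] = j
                out[i, x, 1] = p
                out[i, x, 2] = q
                out[i, x, 3] = sg
        return out, n

    def _double_lists(self, strings, exc):
        """Same-spin double-excitation amplitudes: H element for strings
        differing by exactly two orbitals: sum over hole/particle pairings
        with antisymmetrised integrals."""
        g = self.g
        index = {s: i for i, s in enumerate(strings)}
        rows = []
        for i, s in enumerate(strings):
            occ = set(s)
            row = {}
            holes = list(s)
            parts = [p for p in range(self.norb) if p not in occ]
            for q1i in range(len(holes)):
                for q2i in range(q1i + 1, len(holes)):
                    q1, q2 = holes[q1i], holes[q2i]
                    for p1i in range(len(parts)):
                        for p2i in range(p1i + 1, len(parts)):
                            p1, p2 = parts[p1i], parts[p2i]
                            t = tuple(sorted(occ - {q1, q2} | {p1, p2}))
                            j = index[t]
                            # sign: apply a_q2->p2 then a_q1->p1 sequentially
                            sg, val = self._double_element(s, q1, q2, p1, p2)
                            row[j] = row.get(j, 0.0) + sg * val
            rows.append(sorted(row.items()))
        mx = max((len(r) for r in rows), default=0)
        out = np.zeros((len(rows), max(mx, 1), 2))
        n = np.zeros(len(rows), dtype=np.int64)
        for i, r in enumerate(rows):
            n[i] = len(r)
            for x, (j, v) in enumerate(r):
                out[i, x, 0] = j
                out[i, x, 1] = v
        return out, n

    def _double_element(self, s, q1, q2, p1, p2):
        """<T| H |S> for same-spin double q1,q2 -> p1,p2 (q1<q2, p1<p2):
        value = (p1 q1|p2 q2) - (p1 q2|p2 q1), sign from operator ordering."""
        g = self.g
        # sign: annihilate q2 then q1, create p1... use occupation-counting:
        occ = list(s)
        sign = 1.0

        def ann(o, x):
            k = o.index(x)
            nonlocal sign
            sign *= (-1.0) ** k
            o.pop(k)

        def cre(o, x):
            k = 0
            while k < len(o) and o[k] < x:
                k += 1
            nonlocal sign
            sign *= (-1.0) ** k
            o.insert(k, x)

        ann(occ, q1)
        ann(occ, q2)
        cre(occ, p2)
        cre(occ, p1)
        val = g[p1, q1, p2, q2] - g[p1, q2, p2, q1]
        return sign, val

    def _diagonal(self):
        h1, g = self.h1, self.g
        nsa, nsb = self.nsa, self.nsb
        # per-string one-electron + same-spin two-electron
        ea = np.zeros(nsa)
        for i, s in enumerate(self.sa):
            v = sum(h1[p, p] for p in s)
            v += sum(g[p, p, q, q] - g[p, q, q, p]
                     for ii, p in enumerate(s) for q in s[ii + 1:])
            ea[i] = v
        if self.sb is self.sa:
            eb = ea
        else:
            eb = np.zeros(nsb)
            for i, s in enumerate(self.sb):
                v = sum(h1[p, p] for p in s)
                v += sum(g[p, p, q, q] - g[p, q, q, p]
                         for ii, p in enumerate(s) for q in s[ii + 1:])
                eb[i] = v
        diag = ea[:, None] + eb[None, :]
        # alpha-beta coulomb
        ja = np.zeros((nsa, self.norb))
        for i, s in enumerate(self.sa):
            for p in range(self.norb):
                ja[i, p] = sum(g[q, q, p, p] for q in s)
        for ib, s in enumerate(self.sb):
            diag[:, ib] += sum(ja[:, p] for p in s)
        return diag

    def sigma(self, C):
        sig = np.zeros_like(C)
        _sigma_kernel(C, sig, self.h1, self.g, self.occ_a, self.occ_b,
                      self.exc_a, self.nexc_a, self.exc_b, self.nexc_b,
                      self.diag)
        _sigma_doubles_same(C, sig, self.dbl_a[0], self.dbl_a[1], True)
        _sigma_doubles_same(C, sig, self.dbl_b[0], self.dbl_b[1], False)
        _sigma_ab(C, sig, self.g, self.exc_a, self.nexc_a,
                  self.exc_b, self.nexc_b)
        return sig

    def dense_h(self):
        n = self.nsa * self.nsb
        H = np.zeros((n, n))
        for k in range(n):
            e = np.zeros((self.nsa, self.nsb))
            e.flat[k] = 1.0
            H[:, k] = self.sigma(e).ravel()
        return H

    def solve_dense(self):
        H = self.dense_h()
        w, v = np.linalg.eigh(H)
        return w[0] + self.Efz + self.Enuc, v[:, 0].reshape(self.nsa, self.nsb)

    def solve_davidson(self, tol=1e-9, maxiter=80, verbose=True):
        n = self.nsa * self.nsb
        diag = self.diag.ravel()
        i0 = int(np.argmin(diag))
        b = [np.zeros(n)]
        b[0][i0] = 1.0
        sig = []
        for it in range(maxiter):
            while len(sig) < len(b):
                k = len(sig)
                sig.append(self.sigma(b[k].reshape(self.nsa, self.nsb)).ravel())
            m = len(b)
            Hs = np.zeros((m, m))
            for a in range(m):
                for c in range(m):
                    Hs[a, c] = np.dot(b[a], sig[c])
            Hs = 0.5 * (Hs + Hs.T)
            w, v = np.linalg.eigh(Hs)
            theta = w[0]
            y = v[:, 0]
            x = sum(y[a] * b[a] for a in range(m))
            r = sum(y[a] * sig[a] for a in range(m)) - theta * x
            rn = np.linalg.norm(r)
            if verbose:
                print(f"  Davidson iter {it:3d}  E = {theta + self.Efz + self.Enuc:.10f}  |r| = {rn:.2e}  dim = {m}")
            if rn < tol:
                return theta + self.Efz + self.Enuc, x.reshape(self.nsa, self.nsb)
            denom = diag - theta
            denom[np.abs(denom) < 1e-8] = 1e-8
            t = -r / denom
            # orthogonalise
            for bb in b:
                t -= np.dot(bb, t) * bb
            nt = np.linalg.norm(t)
            if nt < 1e-12:
                t = np.random.default_rng(it).standard_normal(n)
                for bb in b:
                    t -= np.dot(bb, t) * bb
                nt = np.linalg.norm(t)
            b.append(t / nt)
            if len(b) > 24:
                # restart
                b = [x / np.linalg.norm(x)]
                sig = []
        raise RuntimeError("Davidson did not converge")


# --------------------------------------------------------------- benzene

def benzene_geometry(r_cc=1.397, r_ch=1.087):
    """Ideal D6h benzene, xy-plane, C6 axis = z; input Angstrom, output bohr."""
    atoms = []
    rc = r_cc * BOHR_PER_ANGSTROM  # hexagon circumradius equals bond length
    rh = (r_cc + r_ch) * BOHR_PER_ANGSTROM
    for k in range(6):
        th = np.pi / 3.0 * k
        atoms.append(("C", np.array([rc * np.cos(th), rc * np.sin(th), 0.0])))
    for k in range(6):
        th = np.pi / 3.0 * k
        atoms.append(("H", np.array([rh * np.cos(th), rh * np.sin(th), 0.0])))
    return atoms


def mo_values(basis, C, points, which):
    """Engine-side MO evaluation at cartesian points (bohr)."""
    pts = np.atleast_2d(points)
    ao = np.zeros((pts.shape[0], basis.nao))
    for m in range(basis.nao):
        d = pts - basis.cen[m]
        r2 = np.sum(d * d, axis=1)
        poly = (d[:, 0] ** basis.lmn[m, 0]
                * d[:, 1] ** basis.lmn[m, 1]
                * d[:, 2] ** basis.lmn[m, 2])
        rad = np.zeros(pts.shape[0])
        for p in range(basis.nprim[m]):
            rad += basis.coefs[m, p] * np.exp(-basis.exps[m, p] * r2)
        ao[:, m] = poly * rad
    return ao @ C[:, which]
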