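"""Self-tests for the minimal HF/CAS-CI engine.

Run:  python test_engine.py
The CI oracle builds the Hamiltonian in full Fock space from explicit
Jordan-Wigner creation/annihilation matrices -- a completely independent
route to the string-based sigma code.
"""

import numpy as np
import minichem as mc


def jw_operators(nso):
    """Creation operator matrices over 2^nso Fock space, JW ordering."""
    I = np.eye(2)
    Z = np.diag([1.0, -1.0])
    cr = np.array([[0.0, 0.0], [1.0, 0.0]])  # |1><0|
    ops = []
    for p in range(nso):
        mats = [Z] * p + [cr] + [I] * (nso - p - 1)
        M = mats[0]
        for m in mats[1:]:
            M = np.kron(M, m)
        ops.append(M)
    return ops


def oracle_spectrum(h1, g, norb, na, nb):
    """Sector eigenvalues from explicit second-quantised H (spin orbitals:
    alpha = 0..norb-1, beta = norb..2norb-1)."""
    nso = 2 * norb
    a_dag = jw_operators(nso)
    a = [m.T for m in a_dag]
    dim = 2 ** nso
    H = np.zeros((dim, dim))
    for p in range(norb):
        for q in range(norb):
            if h1[p, q] != 0.0:
                H += h1[p, q] * (a_dag[p] @ a[q] + a_dag[p + norb] @ a[q + norb])
    for p in range(norb):
        for q in range(norb):
            for r in range(norb):
                for s in range(norb):
                    v = g[p, q, r, s]
                    if v == 0.0:
                        continue
                    for sp1 in (0, norb):
                        for sp2 in (0, norb):
                            H += 0.5 * v * (a_dag[p + sp1] @ a_dag[r + sp2]
                                            @ a[s + sp2] @ a[q + sp1])
    # project onto (na, nb) sector
    occs = []
    for k in range(dim):
        bits = [(k >> i) & 1 for i in range(nso)]
        # JW kron order: op index 0 is the MOST significant factor
        bits = [(k >> (nso - 1 - i)) & 1 for i in range(nso)]
        if sum(bits[:norb]) == na and sum(bits[norb:]) == nb:
            occs.append(k)
    Hs = H[np.ix_(occs, occs)]
    return np.linalg.eigvalsh(Hs)


def test_casci_vs_fockspace():
    rng = np.random.default_rng(7)
    norb, na, nb = 4, 2, 2
    h1 = rng.standard_normal((norb, norb))
    h1 = 0.5 * (h1 + h1.T)
    g = rng.standard_normal((norb,) * 4) * 0.2
    # impose 8-fold permutational symmetry of real (pq|rs)
    g = g + g.transpose(1, 0, 2, 3)
    g = g + g.transpose(0, 1, 3, 2)
    g = g + g.transpose(2, 3, 0, 1)
    cas = mc.CASCI(h1, g, norb, na, nb)
    H = cas.dense_h()
    assert np.max(np.abs(H - H.T)) < 1e-10, "CASCI H not symmetric"
    w = np.linalg.eigvalsh(H)
    w_ref = oracle_spectrum(h1, g, norb, na, nb)
    err = np.max(np.abs(w - w_ref))
    print(f"CASCI vs Fock-space oracle: dim {len(w)}, max |dE| = {err:.3e}")
    assert err < 1e-9
    # Davidson agrees with dense on the ground state
    e_dense, _ = cas.solve_dense()
    e_dav, _ = cas.solve_davidson(verbose=False)
    print(f"dense {e_dense:.10f}  davidson {e_dav:.10f}")
    assert abs(e_dense - e_dav) < 1e-8


def test_h2_rhf():
    r = 0.7414 * mc.BOHR_PER_ANGSTROM
    atoms = [("H", np.array([0.0, 0.0, -r / 2])), ("H", np.array([0.0, 0.0, r / 2]))]
    basis = mc.AOBasisSet(atoms)
    out = mc.rhf(basis, atoms, verbose=False)
    print(f"H2 RHF/6-31G energy = {out['E']:.6f}")
    assert -1.132 < out["E"] < -1.120  # literature ~ -1.1268


def test_h2_fci():
    # FCI in the full 4-orbital space must lie below RHF and above -1.18
    r = 0.7414 * mc.BOHR_PER_ANGSTROM
    atoms = [("H", np.array([0.0, 0.0, -r / 2])), ("H", np.array([0.0, 0.0, r / 2]))]
    basis = mc.AOBasisSet(atoms)
    out = mc.rhf(basis, atoms, verbose=False)
    act = list(range(4))
    gmo = mc.mo_transform_active(out["eri"], out["C"], act, basis.nao)
    h1, efz = mc.core_hamiltonian_active(out["h"], out["eri"], out["C"],
                                         [], act, basis.nao)
    cas = mc.CASCI(h1, gmo, 4, 1, 1, Efz=efz, Enuc=out["Enuc"])
    e, ci = cas.solve_dense()
    print(f"H2 FCI/6-31G energy = {e:.6f} (corr {e - out['E']:.6f})")
    assert e < out["E"] - 0.01
    assert -1.16 < e < -1.14  # literature FCI/6-31G ~ -1.1516


if __name__ == "__main__":
    test_casci_vs_fockspace()
    test_h2_rhf()
    test_h2_fci()
    print("engine self-tests passed")
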