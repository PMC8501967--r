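"""Stage 2 of template building: shared-backbone refinement.

Builds on the same CCD-derived in-plane Watson-Crick pairing as
make_templates.py, then: (1) optimizes a single sugar-phosphate backbone
pose (5 torsional DOFs on the scaffold strand; the partner strand uses its
dyad image) against the stacking transform with a steric penalty, and
(2) grafts that one backbone onto all four nucleotides.  A uniform
backbone guarantees that every dinucleotide step has identical
backbone-backbone geometry, so a stacked duplex of any sequence is
clash-free by construction.
"""
import sys
import numpy as np
from scipy.optimize import least_squares, minimize
import biotite.structure.info as info

RING = {
    "DA": ["N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"],
    "DG": ["N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"],
    "DT": ["N1", "C2", "N3", "C4", "C5", "C6"],
    "DC": ["N1", "C2", "N3", "C4", "C5", "C6"],
}
GLYC = {"DA": "N9", "DG": "N9", "DT": "N1", "DC": "N1"}
BASE_EXTRA = {"N6", "O6", "N2", "O2", "O4", "N4", "C7"}
BACKBONE = ["P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
            "C2'", "C1'"]
RISE = 3.32
TWIST = np.deg2rad(360.0 / 10.5)
C1_RADIUS = 5.90
HBONDS = {
    "AT": [("N1", "N3", 2.82), ("N6", "O4", 2.95), ("C2", "O2", 3.58)],
    "GC": [("O6", "N4", 2.91), ("N1", "N3", 2.95), ("N2", "O2", 2.86)],
}
C1C1 = 10.85
CLASH_TARGET = 2.4


def load(res):
    a = info.residue(res)
    keep = (a.element != "H") & (a.atom_name != "OP3")
    a = a[keep]
    return list(a.atom_name), list(a.element), a.coord.astype(float).copy()


def idx(names, n):
    return names.index(n)


def rot_axis(axis, theta):
    axis = axis / np.linalg.norm(axis)
    K = np.array([[0, -axis[2], axis[1]], [axis[2], 0, -axis[0]],
                  [-axis[1], axis[0], 0]])
    return np.eye(3) + np.sin(theta) * K + (1 - np.cos(theta)) * (K @ K)


def planarize(names, xyz, res):
    ring = np.array([xyz[idx(names, n)] for n in RING[res]])
    c = ring.mean(axis=0)
    xyz = xyz - c
    ring = ring - c
    _, _, vt = np.linalg.svd(ring)
    normal = vt[2]
    z = np.array([0.0, 0.0, 1.0])
    v = np.cross(normal, z)
    s = np.linalg.norm(v)
    if s > 1e-12:
        xyz = xyz @ rot_axis(v, np.arctan2(s, normal @ z)).T
    return xyz


def canonical(names, xyz, res, face_up=True):
    n_g = xyz[idx(names, GLYC[res])]
    c1 = xyz[idx(names, "C1'")]
    xyz = xyz - n_g
    d = n_g - c1
    d[2] = 0.0
    th = np.arctan2(d[0], d[1])
    xyz = xyz @ rot_axis(np.array([0, 0, 1.0]), th).T
    if not face_up:
        xyz = xyz @ rot_axis(np.array([0, 1.0, 0]), np.pi).T
    return xyz


def build_pair(pur_res, pyr_res, key):
    pn, pe, pxyz = load(pur_res)
    yn, ye, yxyz = load(pyr_res)
    pxyz = canonical(pn, planarize(pn, pxyz, pur_res), pur_res)
    yxyz = planarize(yn, yxyz, pyr_res)
    best = None
    for flip in (True, False):
        y0 = canonical(yn, yxyz.copy(), pyr_res, face_up=not flip)

        def resid(par):
            R = rot_axis(np.array([0, 0, 1.0]), par[0])
            moved = y0 @ R.T + np.array([par[1], par[2], 0.0])
            out = [np.linalg.norm(pxyz[idx(pn, a)] - moved[idx(yn, b)]) - d
                   for a, b, d in HBONDS[key]]
            out.append(np.linalg.norm(pxyz[idx(pn, "C1'")] -
                                      moved[idx(yn, "C1'")]) - C1C1)
            return out

        for th0 in np.linspace(0, 2 * np.pi, 8, endpoint=False):
            sol = least_squares(resid, [th0, 8.0, 0.0])
            if best is None or sol.cost < best[0]:
                R = rot_axis(np.array([0, 0, 1.0]), sol.x[0])
                best = (sol.cost, y0 @ R.T +
                        np.array([sol.x[1], sol.x[2], 0.0]))
    print(f"{key}: pairing residual {np.sqrt(best[0]):.3f} A")
    return (pn, pe, pxyz), (yn, ye, best[1])


def pair_frame(pur, pyr):
    pn, pe, pxyz = pur
    yn, ye, yxyz = pyr
    c1p = pxyz[idx(pn, "C1'")] * np.array([1, 1, 0])
    c1y = yxyz[idx(yn, "C1'")] * np.array([1, 1, 0])
    mid = 0.5 * (c1p + c1y)
    chord = c1y - c1p
    half = 0.5 * np.linalg.norm(chord)
    w = np.cross(np.array([0, 0, 1.0]), chord)
    w = w / np.linalg.norm(w)
    d = np.sqrt(max(C1_RADIUS ** 2 - half ** 2, 0.0))
    M = 0.5 * (pxyz[idx(pn, GLYC["DA"])] + yxyz[idx(yn, GLYC["DT"])])
    M[2] = 0.0
    cands = [mid + d * w, mid - d * w]
    O = max(cands, key=lambda o: np.linalg.norm(M - o))
    u = (M - O) / np.linalg.norm(M - O)
    th = np.arctan2(u[0], u[1])
    R = rot_axis(np.array([0, 0, 1.0]), th)
    return ((pn, pe, (pxyz - O) @ R.T), (yn, ye, (yxyz - O) @ R.T))


def dyad(xyz):
    return xyz @ rot_axis(np.array([0, 1.0, 0]), np.pi).T


def apply_torsions(names, xyz, res, par):
    chi_d, gam, bet, spin, swing = par
    out = xyz.copy()
    n_g, c1 = idx(names, GLYC[res]), idx(names, "C1'")
    base_atoms = set(RING[res]) | BASE_EXTRA
    Rchi = rot_axis(out[c1] - out[n_g], chi_d)
    for i, nm in enumerate(names):
        if nm not in base_atoms:
            out[i] = Rchi @ (out[i] - out[n_g]) + out[n_g]
    c4, c5, o5 = idx(names, "C4'"), idx(names, "C5'"), idx(names, "O5'")
    p, c3, o3 = idx(names, "P"), idx(names, "C3'"), idx(names, "O3'")
    Rg = rot_axis(out[c5] - out[c4], gam)
    for i in (o5, p, idx(names, "OP1"), idx(names, "OP2")):
        out[i] = Rg @ (out[i] - out[c5]) + out[c5]
    Rb = rot_axis(out[o5] - out[c5], bet)
    for i in (p, idx(names, "OP1"), idx(names, "OP2")):
        out[i] = Rb @ (out[i] - out[o5]) + out[o5]
    Rs = rot_axis(out[p] - out[o5], spin)
    for i in (idx(names, "OP1"), idx(names, "OP2")):
        out[i] = Rs @ (out[i] - out[p]) + out[p]
    Rw = rot_axis(out[c3] - out[c4], swing)
    out[o3] = Rw @ (out[o3] - out[c3]) + out[c3]
    return out


def stack(xyz, k):
    R = rot_axis(np.array([0, 0, 1.0]), k * TWIST)
    return xyz @ R.T + np.array([0, 0, k * RISE])


def backbone_cost(pn, pxyz, yn, ybase_xyz, res, par, verbose=False):
    """pxyz: scaffold nucleotide; partner = its own base + dyad backbone."""
    px = apply_torsions(pn, pxyz, res, par)
    bb = {nm: px[idx(pn, nm)] for nm in BACKBONE}
    # partner: base atoms from the paired pyrimidine + dyad backbone
    yx = ybase_xyz.copy()
    for nm in BACKBONE:
        yx[idx(yn, nm)] = dyad(bb[nm][None, :])[0]
    gap = np.linalg.norm(stack(px, 1)[idx(pn, "P")] -
                         px[idx(pn, "O3'")]) - 1.60
    # glycosidic attachment of the partner base to the copied backbone
    gly = np.linalg.norm(yx[idx(yn, "C1'")] -
                         yx[idx(yn, GLYC["DT" if "N1" in yn else "DT"])])
    gly_pen = (gly - 1.47)
    # clash over 3 stacked pairs, both strands
    frames, labels = [], []
    for k in (0, 1, 2):
        frames.append(stack(px, k))
        labels += [("s", k, nm) for nm in pn]
        frames.append(stack(yx, k))
        labels += [("y", k, nm) for nm in yn]
    coords = np.vstack(frames)
    strand = np.array([0 if l[0] == "s" else 1 for l in labels])
    level = np.array([l[1] for l in labels])
    names_arr = np.array([l[2] for l in labels])
    d = np.linalg.norm(coords[:, None, :] - coords[None, :, :], axis=2)
    iu = np.triu_indices(len(labels), 1)
    same = (strand[iu[0]] == strand[iu[1]]) & (level[iu[0]] == level[iu[1]])
    adj = (strand[iu[0]] == strand[iu[1]]) & \
        (np.abs(level[iu[0]] - level[iu[1]]) == 1)
    lo = np.where(level[iu[0]] < level[iu[1]], iu[0], iu[1])
    hi = np.where(level[iu[0]] < level[iu[1]], iu[1], iu[0])
    don = np.where(strand[iu[0]] == 0, lo, hi)
    acc = np.where(strand[iu[0]] == 0, hi, lo)
    link = adj & np.isin(names_arr[don], ["O3'", "C3'", "C2'"]) & \
        np.isin(names_arr[acc], ["P", "O5'", "OP1", "OP2"])
    dd = d[iu][~(same | link)]
    pen = np.sum(np.clip(CLASH_TARGET - dd, 0, None) ** 2)
    cost = gap ** 2 + 0.25 * gly_pen ** 2 + 4.0 * pen
    if verbose:
        print(f"  gap {gap+1.6:.2f} A, partner glyc bond {gly:.2f} A, "
              f"min non-bonded {dd.min():.2f} A, cost {cost:.5f}")
    return cost, px, yx


def graft(names, xyz, res, bb, strand1=True):
    """Replace backbone atom positions with the shared backbone pose."""
    out = xyz.copy()
    for nm in BACKBONE:
        p = bb[nm]
        out[idx(names, nm)] = p if strand1 else dyad(p[None, :])[0]
    return out


def main(out_csv):
    rng = np.random.default_rng(20240902)
    (an, ae, axyz), (tn, te, txyz) = build_pair("DA", "DT", "AT")
    (an2, ae2, axyz2), (tn2, te2, txyz2) = pair_frame((an, ae, axyz),
                                                      (tn, te, txyz))
    an, axyz, tn, txyz = an2, axyz2, tn2, txyz2
    best = None
    for flipped in (False, True):
        ax = dyad(axyz) if flipped else axyz
        tx = dyad(txyz) if flipped else txyz
        for _ in range(16):
            x0 = rng.uniform(-np.pi, np.pi, 5)
            sol = minimize(lambda p: backbone_cost(an, ax, tn, tx, "DA",
                                                   p)[0],
                           x0, method="Nelder-Mead",
                           options={"maxiter": 3000, "fatol": 1e-12})
            if best is None or sol.fun < best[0]:
                best = (sol.fun, sol.x, flipped, ax, tx)
    fun, par, flipped, ax, tx = best
    print(f"AT backbone: flipped={flipped}, cost {fun:.6f}")
    _, afin, tfin = backbone_cost(an, ax, tn, tx, "DA", par, verbose=True)
    bb = {nm: afin[idx(an, nm)] for nm in BACKBONE}

    # GC pair: in-plane pairing, then graft the shared backbone
    (gn, ge, gxyz), (cn, ce, cxyz) = build_pair("DG", "DC", "GC")
    (gn2, ge2, gxyz2), (cn2, ce2, cxyz2) = pair_frame((gn, ge, gxyz),
                                                      (cn, ce, cxyz))
    gn, gxyz, cn, cxyz = gn2, gxyz2, cn2, cxyz2
    if flipped:
        gxyz, cxyz = dyad(gxyz), dyad(cxyz)
    gfin = graft(gn, gxyz, "DG", bb, strand1=True)
    cfin = graft(cn, cxyz, "DC", bb, strand1=False)
    for lbl, names, xyz, res in (("G", gn, gfin, "DG"), ("C", cn, cfin,
                                                         "DC")):
        g = np.linalg.norm(xyz[idx(names, "C1'")] -
                           xyz[idx(names, GLYC[res])])
        print(f"  {lbl} glycosidic C1'-N bond after graft: {g:.2f} A")

    pairs = {"AT": ((an, ae, afin, "DA"), (tn, te, tfin, "DT")),
             "GC": ((gn, ge, gfin, "DG"), (cn, ce, cfin, "DC"))}
    rows = []
    for key, (s1, s2) in pairs.items():
        for (names, elems, xyz, resn), role in ((s1, "scaffold"),
                                                (s2, "partner")):
            for nm, el, c in zip(names, elems, xyz):
                rows.append((key[0], role, resn, nm, el, *np.round(c, 4)))
        for (names, elems, xyz, resn), role in ((s2, "scaffold"),
                                                (s1, "partner")):
            for nm, el, c in zip(names, elems, xyz):
                rows.append((key[1], role, resn, nm, el,
                             *np.round(dyad(xyz)[list(names).index(nm)], 4)))
    with open(out_csv, "w") as fh:
        fh.write("scaffold_base,role,residue,atom,element,x,y,z\n")
        for r in rows:
            fh.write(",".join(str(x) for x in r) + "\n")
    print(f"wrote {out_csv}: {len(rows)} atom rows")

    # verification: random-sequence 12-bp duplex, all-pairs clash check
    tpl = {}
    for r in rows:
        tpl.setdefault((r[0], r[1]), []).append(r)
    rng2 = np.random.default_rng(7)
    seqs = rng2.choice(list("ACGT"), 12)
    allc, allnames = [], []
    for i, b in enumerate(seqs):
        for role in ("scaffold", "partner"):
            for r in tpl[(b, role)]:
                allc.append(stack(np.array(r[5:8], float)[None, :], i)[0])
                allnames.append((role, i, r[3]))
    allc = np.array(allc)
    d = np.linalg.norm(allc[:, None, :] - allc[None, :, :], axis=2)
    iu = np.triu_indices(len(allc), 1)
    role_a = np.array([n[0] for n in allnames])
    lev = np.array([n[1] for n in allnames])
    nm = np.array([n[2] for n in allnames])
    same = (role_a[iu[0]] == role_a[iu[1]]) & (lev[iu[0]] == lev[iu[1]])
    adj = (role_a[iu[0]] == role_a[iu[1]]) & \
        (np.abs(lev[iu[0]] - lev[iu[1]]) == 1)
    lo = np.where(lev[iu[0]] < lev[iu[1]], iu[0], iu[1])
    hi = np.where(lev[iu[0]] < lev[iu[1]], iu[1], iu[0])
    don = np.where(role_a[iu[0]] == "scaffold", lo, hi)
    acc = np.where(role_a[iu[0]] == "scaffold", hi, lo)
    link = adj & np.isin(nm[don], ["O3'", "C3'", "C2'"]) & \
        np.isin(nm[acc], ["P", "O5'", "OP1", "OP2"])
    dd = d[iu][~(same | link)]
    print(f"verification 12-bp random duplex: min non-bonded {dd.min():.2f} A")


if __name__ == "__main__":
    main(sys.argv[1] if len(sys.argv) > 1 else
         "inst/extdata/bform_templates_synthetic.csv")
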