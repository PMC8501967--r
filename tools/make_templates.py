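"""Build synthetic idealized B-form base-pair templates (build-time only).

Heavy-atom nucleotide geometry is taken from the public PDB Chemical
Component Dictionary ideal coordinates (via biotite), planarized, and
Watson-Crick paired by least-squares placement against canonical
hydrogen-bond distances plus the 10.85 A C1'-C1' separation.  Backbone
torsions (chi, gamma, beta, O3' swing, phosphate spin) are then optimized
per strand so that, under the stacking transform (rise 3.32 A, twist
+34.2857 deg about +z), successive residues form a near-bonded O3'-P
contact and a stacked duplex is free of steric clashes below 2.0 A.
The result is frozen as a plain-text CSV shipped with the package; the R
code only applies rigid transforms to it.  This is a declared synthetic
stand-in for the 3DNA/Olson average B-form parameter set, which is not
obtainable in this environment.

Pair frame convention (documented in the package vignette):
  - base-pair plane = xy-plane, helix axis = +z through the origin
  - origin equidistant from the two C1' atoms (radius 5.90 A each)
  - +y points from the origin toward the glycosidic-nitrogen midpoint
  - the scaffold-side nucleotide runs 5'->3' along +z.
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
CHI4 = {"DA": "C4", "DG": "C4", "DT": "C2", "DC": "C2"}
BASE_EXTRA = {"N6", "O6", "N2", "O2", "O4", "N4", "C7"}

RISE = 3.32
TWIST = np.deg2rad(360.0 / 10.5)
C1_RADIUS = 5.90
HBONDS = {
    "AT": [("N1", "N3", 2.82), ("N6", "O4", 2.95), ("C2", "O2", 3.58)],
    "GC": [("O6", "N4", 2.91), ("N1", "N3", 2.95), ("N2", "O2", 2.86)],
}
C1C1 = 10.85
CLASH_TARGET = 2.4   # optimize non-bonded contacts above this


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
    pxyz = canonical(pn, planarize(pn, pxyz, pur_res), pur_res, True)
    yxyz = planarize(yn, yxyz, pyr_res)

    best = None
    for flip in (True, False):
        y0 = canonical(yn, yxyz.copy(), pyr_res, face_up=not flip)

        def resid(par):
            R = rot_axis(np.array([0, 0, 1.0]), par[0])
            moved = y0 @ R.T + np.array([par[1], par[2], 0.0])
            out = [np.linalg.norm(pxyz[idx(pn, a_p)] -
                                  moved[idx(yn, a_y)]) - d
                   for a_p, a_y, d in HBONDS[key]]
            out.append(np.linalg.norm(pxyz[idx(pn, "C1'")] -
                                      moved[idx(yn, "C1'")]) - C1C1)
            return out

        for th0 in np.linspace(0, 2 * np.pi, 8, endpoint=False):
            sol = least_squares(resid, [th0, 8.0, 0.0])
            if best is None or sol.cost < best[0]:
                R = rot_axis(np.array([0, 0, 1.0]), sol.x[0])
                best = (sol.cost, y0 @ R.T +
                        np.array([sol.x[1], sol.x[2], 0.0]), flip)
    cost, yfin, flip = best
    c1c1 = np.linalg.norm(pxyz[idx(pn, "C1'")] - yfin[idx(yn, "C1'")])
    print(f"{key}: pairing residual {np.sqrt(cost):.3f} A, "
          f"C1'-C1' {c1c1:.2f} A")
    return (pn, pe, pxyz), (yn, ye, yfin)


def pair_frame(pur, pyr, key):
    """Place the pair so both C1' are at radius C1_RADIUS, +y toward the
    glycosidic midpoint, plane = xy."""
    pn, pe, pxyz = pur
    yn, ye, yxyz = pyr
    c1p = pxyz[idx(pn, "C1'")].copy()
    c1y = yxyz[idx(yn, "C1'")].copy()
    c1p[2] = c1y[2] = 0.0
    mid = 0.5 * (c1p + c1y)
    chord = c1y - c1p
    half = 0.5 * np.linalg.norm(chord)
    w = np.cross(np.array([0, 0, 1.0]), chord)
    w = w / np.linalg.norm(w)
    d = np.sqrt(max(C1_RADIUS ** 2 - half ** 2, 0.0))
    M = 0.5 * (pxyz[idx(pn, GLYC["DA"])] + yxyz[idx(yn, GLYC["DT"])])
    M[2] = 0.0
    cands = [mid + d * w, mid - d * w]
    # origin on the far side from the glycosidic midpoint (major groove side)
    O = max(cands, key=lambda o: np.linalg.norm(M - o))
    u = M - O
    u = u / np.linalg.norm(u)
    th = np.arctan2(u[0], u[1])
    R = rot_axis(np.array([0, 0, 1.0]), th)
    return ((pn, pe, (pxyz - O) @ R.T), (yn, ye, (yxyz - O) @ R.T))


def dyad_flip(xyz):
    return xyz @ rot_axis(np.array([0, 1.0, 0]), np.pi).T


def moved_residue(names, xyz, res, par):
    """Apply torsional DOFs: chi, gamma, beta, phosphate spin, O3' swing."""
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


def stack_transform(xyz, k):
    R = rot_axis(np.array([0, 0, 1.0]), k * TWIST)
    return xyz @ R.T + np.array([0, 0, k * RISE])


def duplex_cost(pur, pyr, par, verbose=False):
    """Bonded O3'-P targets + clash penalty on a 3-bp stacked duplex."""
    pn, pe, px0 = pur
    yn, ye, yx0 = pyr
    px = moved_residue(pn, px0, pn_res[0], par[:5])
    yx = moved_residue(yn, yx0, pn_res[1], par[5:])
    # scaffold strand runs +z: O3'(i) bonds P(i+1) = stacked image
    gap_p = np.linalg.norm(stack_transform(px, 1)[idx(pn, "P")] -
                           px[idx(pn, "O3'")]) - 1.60
    # partner runs -z: O3' of image(i+1) bonds P(i)
    gap_y = np.linalg.norm(stack_transform(yx, 1)[idx(yn, "O3'")] -
                           yx[idx(yn, "P")]) - 1.60
    # clash penalty over 3 stacked pairs
    frames = []
    labels = []
    for k in (0, 1, 2):
        frames.append(stack_transform(px, k))
        labels += [("s", k, nm) for nm in pn]
        frames.append(stack_transform(yx, k))
        labels += [("y", k, nm) for nm in yn]
    coords = np.vstack(frames)
    nat = len(labels)
    strand = np.array([0 if l[0] == "s" else 1 for l in labels])
    level = np.array([l[1] for l in labels])
    names_arr = np.array([l[2] for l in labels])
    d = np.linalg.norm(coords[:, None, :] - coords[None, :, :], axis=2)
    iu = np.triu_indices(nat, 1)
    same_res = (strand[iu[0]] == strand[iu[1]]) & \
               (level[iu[0]] == level[iu[1]])
    # bonded/1-3 neighbourhood across the backbone link
    adj = (strand[iu[0]] == strand[iu[1]]) & \
          (np.abs(level[iu[0]] - level[iu[1]]) == 1)
    lo = np.where(level[iu[0]] < level[iu[1]], iu[0], iu[1])
    hi = np.where(level[iu[0]] < level[iu[1]], iu[1], iu[0])
    # for scaffold (+z) the lower residue donates O3'; partner is reversed
    don = np.where(strand[iu[0]] == 0, lo, hi)
    acc = np.where(strand[iu[0]] == 0, hi, lo)
    link = adj & np.isin(names_arr[don], ["O3'", "C3'", "C2'"]) & \
        np.isin(names_arr[acc], ["P", "O5'", "OP1", "OP2"])
    mask = ~(same_res | link)
    dd = d[iu][mask]
    pen = np.sum(np.clip(CLASH_TARGET - dd, 0, None) ** 2)
    cost = gap_p ** 2 + gap_y ** 2 + 4.0 * pen
    if verbose:
        print(f"  gaps: scaffold {gap_p+1.6:.2f} A, partner {gap_y+1.6:.2f} A"
              f", min non-bonded {dd.min():.2f} A, cost {cost:.4f}")
    return cost


def main(out_csv):
    global pn_res
    rows = []
    rng = np.random.default_rng(20240901)
    for key, pur_res, pyr_res in (("AT", "DA", "DT"), ("GC", "DG", "DC")):
        pn_res = (pur_res, pyr_res)
        pur, pyr = build_pair(pur_res, pyr_res, key)
        pur, pyr = pair_frame(pur, pyr, key)
        best = None
        for flipped in (False, True):
            p = (pur[0], pur[1], dyad_flip(pur[2]) if flipped else pur[2])
            y = (pyr[0], pyr[1], dyad_flip(pyr[2]) if flipped else pyr[2])
            for trial in range(24):
                x0 = rng.uniform(-np.pi, np.pi, 10)
                sol = minimize(lambda par: duplex_cost(p, y, par),
                               x0, method="Nelder-Mead",
                               options={"maxiter": 4000, "fatol": 1e-10,
                                        "xatol": 1e-6})
                if best is None or sol.fun < best[0]:
                    best = (sol.fun, sol.x, flipped, p, y)
        fun, par, flipped, p, y = best
        print(f"{key}: orientation flipped={flipped}, final cost {fun:.5f}")
        duplex_cost(p, y, par, verbose=True)
        pfin = moved_residue(p[0], p[2], pur_res, par[:5])
        yfin = moved_residue(y[0], y[2], pyr_res, par[5:])
        for names, elems, xyz, resn, role in (
                (p[0], p[1], pfin, pur_res, "scaffold"),
                (y[0], y[1], yfin, pyr_res, "partner")):
            for nm, el, c in zip(names, elems, xyz):
                rows.append((key[0], role, resn, nm, el, *np.round(c, 4)))
        # scaffold = pyrimidine: dyad-rotated pair (swaps strand polarity)
        for names, elems, xyz, resn, role in (
                (y[0], y[1], dyad_flip(yfin), pyr_res, "scaffold"),
                (p[0], p[1], dyad_flip(pfin), pur_res, "partner")):
            for nm, el, c in zip(names, elems, xyz):
                rows.append((key[1], role, resn, nm, el, *np.round(c, 4)))
    with open(out_csv, "w") as fh:
        fh.write("scaffold_base,role,residue,atom,element,x,y,z\n")
        for r in rows:
            fh.write(",".join(str(x) for x in r) + "\n")
    print(f"wrote {out_csv}: {len(rows)} atom rows")


if __name__ == "__main__":
    main(sys.argv[1] if len(sys.argv) > 1 else
         "inst/extdata/bform_templates_synthetic.csv")
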