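"""Independent reference implementation of identity tracking metrics.

Reads a JSON file {"gt": [...], "hyp": [...], "iou": t} where each track
row is {"track_id": i, "slice": s, "x":, "y":, "w":, "h":}, recomputes
IDTP/IDFP/IDFN via scipy's linear_sum_assignment on the trajectory
overlap matrix, plus CLEAR-style sequential frame matching (previous-pair
preference, then per-slice LSAP on 1-IoU) for per-track coverage and ID
switches, and prints the results as JSON. Used by the R test suite as a
cross-language oracle; it shares no code with the R implementation.
"""
import json
import sys

import numpy as np
from scipy.optimize import linear_sum_assignment

FORBIDDEN = 1e6


def iou(a, b):
    ix = max(0.0, min(a[0] + a[2], b[0] + b[2]) - max(a[0], b[0]))
    iy = max(0.0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
    inter = ix * iy
    union = a[2] * a[3] + b[2] * b[3] - inter
    return inter / union if union > 0 else 0.0


def to_tracks(rows):
    tracks = {}
    for r in rows:
        tracks.setdefault(r["track_id"], {})[r["slice"]] = (
            r["x"], r["y"], r["w"], r["h"])
    return tracks


def lsap_matches(cost):
    """Min-cost assignment; pairs at or above FORBIDDEN are dropped."""
    n, m = cost.shape
    s = max(n, m)
    padded = np.zeros((s, s))
    padded[:n, :m] = cost
    ri, ci = linear_sum_assignment(padded)
    return [(i, j) for i, j in zip(ri, ci)
            if i < n and j < m and cost[i, j] < FORBIDDEN]


def main(path):
    data = json.load(open(path))
    thr = data["iou"]
    G = to_tracks(data["gt"])
    H = to_tracks(data["hyp"])
    gids, hids = sorted(G), sorted(H)

    overlap = np.zeros((len(gids), len(hids)))
    for i, g in enumerate(gids):
        for j, h in enumerate(hids):
            common = set(G[g]) & set(H[h])
            overlap[i, j] = sum(
                1 for s in common if iou(G[g][s], H[h][s]) >= thr)
    idtp = 0.0
    if overlap.size:
        ri, ci = linear_sum_assignment(-overlap)
        idtp = float(overlap[ri, ci].sum())
    idfn = len(data["gt"]) - idtp
    idfp = len(data["hyp"]) - idtp

    prev = {}
    matched = {g: 0 for g in gids}
    last_hyp = {}
    switches = 0
    for s in sorted({r["slice"] for r in data["gt"]}):
        gboxes = {g: G[g][s] for g in gids if s in G[g]}
        hboxes = {h: H[h][s] for h in hids if s in H[h]}
        pairs = {}
        used = set()
        for g in sorted(gboxes):
            hb = prev.get(g)
            if hb is not None and hb in hboxes and hb not in used \
                    and iou(gboxes[g], hboxes[hb]) >= thr:
                pairs[g] = hb
                used.add(hb)
        remg = [g for g in sorted(gboxes) if g not in pairs]
        remh = [h for h in sorted(hboxes) if h not in used]
        if remg and remh:
            cost = np.full((len(remg), len(remh)), FORBIDDEN)
            for i, g in enumerate(remg):
                for j, h in enumerate(remh):
                    v = iou(gboxes[g], hboxes[h])
                    if v >= thr:
                        cost[i, j] = 1 - v
            for i, j in lsap_matches(cost):
                pairs[remg[i]] = remh[j]
        for g, hb in pairs.items():
            matched[g] += 1
            if g in last_hyp and last_hyp[g] != hb:
                switches += 1
            last_hyp[g] = hb
            prev[g] = hb

    def coverage(g):
        r = matched[g] / len(G[g])
        if r >= 0.8:
            return "mostly_tracked"
        if r <= 0.2:
            return "mostly_lost"
        return "partially_tracked"

    json.dump({"idtp": idtp, "idfp": idfp, "idfn": idfn,
               "switches": switches,
               "coverage": {str(g): coverage(g) for g in gids}},
              sys.stdout)


if __name__ == "__main__":
    main(sys.argv[1])
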