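#!/usr/bin/env python
"""Independent reference implementation of the CLEAR, IDF1 and HOTA
tracking metrics, used only as a cross-check oracle in the R test suite.

Implements the published definitions directly on numpy with scipy's
linear_sum_assignment, sharing no code with the R package:
  - CLEAR: per-frame Hungarian matching at IoU >= 0.5 with match
    persistence; MOTA = 1 - (FN + FP + IDS) / GT; IDS counts changes of a
    ground-truth identity's matched prediction id.
  - IDF1: global identity pairing maximising overlap-matched detections.
  - HOTA: soft potential-match counts -> global alignment score ->
    per-frame matching -> per-alpha TP/FN/FP and association accuracy,
    averaged over alpha = 0.05..0.95.

Usage: python ref_eval.py gt.txt pred.txt   (prints a JSON object)
"""
import json
import sys

import numpy as np
from scipy.optimize import linear_sum_assignment


def read_mot(path):
    rows = []
    with open(path) as fh:
        for line in fh:
            line = line.strip()
            if not line:
                continue
            parts = line.split(",")
            rows.append([float(x) for x in parts[:6]])
    if not rows:
        return np.zeros((0, 6))
    return np.asarray(rows)


def iou_matrix(a, b):
    if len(a) == 0 or len(b) == 0:
        return np.zeros((len(a), len(b)))
    ax1, ay1 = a[:, 2], a[:, 3]
    ax2, ay2 = a[:, 2] + a[:, 4], a[:, 3] + a[:, 5]
    bx1, by1 = b[:, 2], b[:, 3]
    bx2, by2 = b[:, 2] + b[:, 4], b[:, 3] + b[:, 5]
    iw = np.maximum(0, np.minimum(ax2[:, None], bx2[None, :]) -
                    np.maximum(ax1[:, None], bx1[None, :]))
    ih = np.maximum(0, np.minimum(ay2[:, None], by2[None, :]) -
                    np.maximum(ay1[:, None], by1[None, :]))
    inter = iw * ih
    area_a = (a[:, 4] * a[:, 5])[:, None]
    area_b = (b[:, 4] * b[:, 5])[None, :]
    return inter / (area_a + area_b - inter)


def frames_of(x):
    return {int(f): x[x[:, 0] == f] for f in np.unique(x[:, 0])}


def clear_metrics(gt, pred, thr=0.5):
    gtf, prf = frames_of(gt), frames_of(pred)
    frames = sorted(set(gtf) | set(prf))
    prev = {}
    last_match = {}
    n_match = fp = fn = ids = 0
    sum_iou = 0.0
    tracked = {}
    for f in frames:
        g = gtf.get(f, np.zeros((0, 6)))
        p = prf.get(f, np.zeros((0, 6)))
        sim = iou_matrix(g, p)
        keep_g, keep_p = [], []
        pid_list = list(p[:, 1])
        for gi in range(len(g)):
            gid = int(g[gi, 1])
            if gid in prev and prev[gid] in pid_list:
                pj = pid_list.index(prev[gid])
                if pj not in keep_p and sim[gi, pj] >= thr:
                    keep_g.append(gi)
                    keep_p.append(pj)
        rem_g = [i for i in range(len(g)) if i not in keep_g]
        rem_p = [j for j in range(len(p)) if j not in keep_p]
        if rem_g and rem_p:
            sub = 1 - sim[np.ix_(rem_g, rem_p)]
            sub[sub > 1 - thr] = 1e6
            ri, cj = linear_sum_assignment(sub)
            for i, j in zip(ri, cj):
                if sub[i, j] <= 1 - thr:
                    keep_g.append(rem_g[i])
                    keep_p.append(rem_p[j])
        for gi, pj in zip(keep_g, keep_p):
            gid, pid = int(g[gi, 1]), int(p[pj, 1])
            n_match += 1
            sum_iou += sim[gi, pj]
            if gid in last_match and last_match[gid] != pid:
                ids += 1
            last_match[gid] = pid
            prev[gid] = pid
            tracked[gid] = tracked.get(gid, 0) + 1
        fn += len(g) - len(keep_g)
        fp += len(p) - len(keep_p)
    total_gt = len(gt)
    alive = {int(i): int((gt[:, 1] == i).sum()) for i in np.unique(gt[:, 1])}
    ratios = [tracked.get(i, 0) / a for i, a in alive.items()]
    return {
        "MOTA": 100 * (1 - (fn + fp + ids) / total_gt),
        "MOTP": 100 * sum_iou / n_match if n_match else float("nan"),
        "IDS": ids, "FP": fp, "FN": fn,
        "MTR": 100 * sum(r >= 0.8 for r in ratios) / len(ratios),
        "MLR": 100 * sum(r < 0.2 for r in ratios) / len(ratios),
    }


def idf1_metrics(gt, pred, thr=0.5):
    gids = sorted(set(gt[:, 1]))
    pids = sorted(set(pred[:, 1]))
    pair = np.zeros((len(gids), len(pids)))
    gtf, prf = frames_of(gt), frames_of(pred)
    for f in set(gtf) & set(prf):
        g, p = gtf[f], prf[f]
        sim = iou_matrix(g, p)
        for gi, pj in zip(*np.where(sim >= thr)):
            pair[gids.index(g[gi, 1]), pids.index(p[pj, 1])] += 1
    idtp = 0.0
    if pair.size:
        ri, cj = linear_sum_assignment(-pair)
        idtp = pair[ri, cj].sum()
    idfp = len(pred) - idtp
    idfn = len(gt) - idtp
    denom = 2 * idtp + idfp + idfn
    return {"IDF1": 100 * 2 * idtp / denom if denom else 0.0}


def hota_metrics(gt, pred):
    alphas = np.arange(0.05, 0.96, 0.05)
    gids = sorted(set(gt[:, 1]))
    pids = sorted(set(pred[:, 1]))
    g_count = np.array([(gt[:, 1] == i).sum() for i in gids], float)
    p_count = np.array([(pred[:, 1] == j).sum() for j in pids], float)
    gtf, prf = frames_of(gt), frames_of(pred)
    frames = sorted(set(gtf) | set(prf))
    pot = np.zeros((len(gids), len(pids)))
    per_frame = []
    for f in frames:
        g = gtf.get(f, np.zeros((0, 6)))
        p = prf.get(f, np.zeros((0, 6)))
        if len(g) == 0 or len(p) == 0:
            continue
        sim = iou_matrix(g, p)
        gi = np.array([gids.index(i) for i in g[:, 1]])
        pj = np.array([pids.index(j) for j in p[:, 1]])
        denom = sim.sum(0)[None, :] + sim.sum(1)[:, None] - sim
        soft = np.where(denom > np.finfo(float).eps, sim / denom, 0)
        pot[np.ix_(gi, pj)] += soft
        per_frame.append((gi, pj, sim))
    galign = pot / (g_count[:, None] + p_count[None, :] - pot)
    tp = np.zeros(len(alphas))
    mcnt = [np.zeros((len(gids), len(pids))) for _ in alphas]
    for gi, pj, sim in per_frame:
        score = galign[np.ix_(gi, pj)] * sim
        ri, cj = linear_sum_assignment(-score)
        s = sim[ri, cj]
        for ai, a in enumerate(alphas):
            ok = s >= a - np.finfo(float).eps
            tp[ai] += ok.sum()
            for i, j in zip(ri[ok], cj[ok]):
                mcnt[ai][gi[i], pj[j]] += 1
    total_gt, total_pred = len(gt), len(pred)
    hota_a = []
    for ai in range(len(alphas)):
        fn = total_gt - tp[ai]
        fp = total_pred - tp[ai]
        det_a = tp[ai] / (tp[ai] + fn + fp) if tp[ai] + fn + fp else 0.0
        m = mcnt[ai]
        denom = g_count[:, None] + p_count[None, :] - m
        a_c = np.where(denom > 0, m / denom, 0)
        ass_a = (m * a_c).sum() / tp[ai] if tp[ai] else 0.0
        hota_a.append(np.sqrt(det_a * ass_a))
    return {"HOTA": 100 * float(np.mean(hota_a))}


def main():
    gt = read_mot(sys.argv[1])
    pred = read_mot(sys.argv[2])
    out = {}
    out.update(clear_metrics(gt, pred))
    out.update(idf1_metrics(gt, pred))
    out.update(hota_metrics(gt, pred))
    print(json.dumps(out))


if __name__ == "__main__":
    main()
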