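#!/usr/bin/env python
"""Floating-point LP backend: solve an equality-constrained bounded LP with
scipy.optimize.linprog (HiGHS). Reads a JSON problem, writes a JSON result.

Input:  {"A": [[row]...], "ncol": n, "b": [...], "c": [...], "lb": [...], "ub": [...]}
        (maximize c.x s.t. A.x = b, lb <= x <= ub; null bound = infinite)
Output: {"status": "optimal"|"infeasible"|"unbounded", "x": [...], "objective": f}
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def main(fin, fout):
    with open(fin) as fh:
        p = json.load(fh)
    n = int(p["ncol"])
    A = np.array(p["A"], dtype=float).reshape(-1, n) if p["A"] else np.zeros((0, n))
    b = np.array(p["b"], dtype=float)
    c = np.array(p["c"], dtype=float)
    lb = [(-np.inf if v is None else float(v)) for v in p["lb"]]
    ub = [(np.inf if v is None else float(v)) for v in p["ub"]]
    res = linprog(-c, A_eq=A if A.shape[0] else None,
                  b_eq=b if A.shape[0] else None,
                  bounds=list(zip(lb, ub)), method="highs")
    if res.status == 0:
        out = {"status": "optimal", "x": list(map(float, res.x)),
               "objective": float(-res.fun)}
    elif res.status == 2:
        out = {"status": "infeasible", "x": None, "objective": None}
    elif res.status == 3:
        out = {"status": "unbounded", "x": None, "objective": None}
    else:
        out = {"status": "error", "x": None, "objective": None}
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
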