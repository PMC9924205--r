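"""Batch MILP runner: solves a list of models with scipy's HiGHS interface.

Usage: python milp_solve.py models.json results.json

Input JSON: {"models": [{"obj", "A", "con_lb", "con_ub", "lb", "ub",
"integrality"}, ...]} with 1e30 standing in for infinity.
Output JSON: a list of {"status": "optimal"|"infeasible"|"error",
"objective": float, "x": [float, ...]} in the same order.
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29


def definf(a):
    a = np.asarray(a, dtype=float)
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def solve_one(m):
    c = np.asarray(m["obj"], dtype=float)
    A = np.asarray(m["A"], dtype=float)
    con = LinearConstraint(A, definf(m["con_lb"]), definf(m["con_ub"]))
    bounds = Bounds(definf(m["lb"]), definf(m["ub"]))
    res = milp(c=c, constraints=con, bounds=bounds,
               integrality=np.asarray(m["integrality"], dtype=int))
    if res.status == 0:
        return {"status": "optimal", "objective": float(res.fun),
                "x": [float(v) for v in res.x]}
    if res.status == 2:
        return {"status": "infeasible", "objective": None, "x": None}
    return {"status": "error", "objective": None, "x": None,
            "message": str(res.message)}


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    out = [solve_one(m) for m in payload["models"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
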