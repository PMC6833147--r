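"""Independent LP oracle used by the test suite.

Reads a JSON file with a list of problems {c, A (row-major), m, n, b, lb,
ub, maximize}, solves each with scipy.optimize.linprog (HiGHS), and writes a
JSON list of {status, objective}. Bounds use +/-1e30 as infinity sentinels.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

INF = 1e30


def main(inp, outp):
    probs = json.load(open(inp))
    out = []
    for p in probs:
        m, n = p["m"], p["n"]
        c = np.array(p["c"], dtype=float)
        if p.get("maximize", True):
            c = -c
        A = np.array(p["A"], dtype=float).reshape(m, n)
        lb = [(-np.inf if v <= -INF else v) for v in p["lb"]]
        ub = [(np.inf if v >= INF else v) for v in p["ub"]]
        r = linprog(c, A_eq=A, b_eq=p["b"], bounds=list(zip(lb, ub)),
                    method="highs")
        status = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(
            r.status, "other")
        obj = None
        if r.status == 0:
            obj = -r.fun if p.get("maximize", True) else r.fun
        out.append({"status": status, "objective": obj})
    json.dump(out, open(outp, "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
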