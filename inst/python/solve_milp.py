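"""Standard-form LP/MILP back end.

Reads a JSON file holding one problem or a list of problems, solves each with
HiGHS (scipy.optimize.milp), and writes a JSON list of results.  The problem
format is produced by latentpath::.solveHighs():

  sense        "max" or "min"
  c            objective coefficients (length n)
  A            sparse triplet {i, j, x, nrow, ncol}, 1-based indices
  clb, cub     constraint lower/upper bounds (length nrow; +/-1e30 = inf)
  vlb, vub     variable bounds (length n)
  integrality  0 (continuous) or 1 (integer) per variable

Only plumbing lives here: every model (MDF, pathway MILP, FBA) is assembled
on the R side.
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import LinearConstraint, Bounds, milp

BIG = 1e29


def _inf(v):
    v = np.atleast_1d(np.asarray(v, dtype=float))
    v[v >= BIG] = np.inf
    v[v <= -BIG] = -np.inf
    return v


def solve_one(p):
    n = int(p["A"]["ncol"])
    m = int(p["A"]["nrow"])
    c = np.atleast_1d(np.asarray(p["c"], dtype=float))
    sign = -1.0 if p.get("sense", "min") == "max" else 1.0
    A = sparse.coo_matrix(
        (
            np.atleast_1d(np.asarray(p["A"]["x"], dtype=float)),
            (
                np.atleast_1d(np.asarray(p["A"]["i"], dtype=int)) - 1,
                np.atleast_1d(np.asarray(p["A"]["j"], dtype=int)) - 1,
            ),
        ),
        shape=(m, n),
    ).tocsc()
    cons = LinearConstraint(A, _inf(p["clb"]), _inf(p["cub"]))
    bounds = Bounds(_inf(p["vlb"]), _inf(p["vub"]))
    integrality = np.atleast_1d(np.asarray(p.get("integrality", [0] * n), dtype=int))
    res = milp(
        c=sign * c,
        constraints=cons,
        bounds=bounds,
        integrality=integrality,
        options={"presolve": True},
    )
    if res.status == 0:
        return {
            "status": "optimal",
            "objective": float(sign * res.fun),
            "x": [float(v) for v in res.x],
        }
    if res.status == 2:
        return {"status": "infeasible", "objective": None, "x": None}
    return {
        "status": "error",
        "objective": None,
        "x": None,
        "message": str(res.message),
    }


def main(path_in, path_out):
    with open(path_in) as fh:
        problems = json.load(fh)
    if isinstance(problems, dict):
        problems = [problems]
    out = [solve_one(p) for p in problems]
    with open(path_out, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
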