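"""Batch LP oracle: solves min cc'x s.t. A x <= b, Aeq x = beq, x >= lb
with SciPy's HiGHS backend. Reads a JSON list of problems, writes a JSON
list of {status, fun}."""
import json
import sys

from scipy.optimize import linprog

with open(sys.argv[1]) as fh:
    problems = json.load(fh)

out = []
for p in problems:
    lb = [v[0] if isinstance(v, list) else v for v in p["lb"]]
    res = linprog(
        c=[v[0] if isinstance(v, list) else v for v in p["cc"]],
        A_ub=p.get("A"), b_ub=p.get("b"),
        A_eq=p.get("Aeq"), b_eq=p.get("beq"),
        bounds=[(v, None) for v in lb],
        method="highs")
    out.append({"status": int(res.status),
                "fun": res.fun if res.success else None})

with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
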