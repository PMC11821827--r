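"""Batch convex-hull volumes via Qhull (scipy.spatial.ConvexHull).

Reads a plain-text instance file:
    line 1: number of instances
    per instance: a header line "n m", then n lines of m floats
Writes one line per instance to stdout: "<volume> <degenerate 0/1>".

A set with fewer than m+1 points, or one that Qhull rejects as flat
(affinely dependent), is degenerate: volume 0, flag 1.
"""
import sys

import numpy as np
from scipy.spatial import ConvexHull, QhullError


def main(path):
    out = []
    with open(path) as fh:
        n_inst = int(fh.readline())
        for _ in range(n_inst):
            n, m = (int(x) for x in fh.readline().split())
            pts = np.empty((n, m))
            for i in range(n):
                pts[i] = [float(x) for x in fh.readline().split()]
            if not np.isfinite(pts).all():
                raise ValueError("non-finite coordinates")
            if n < m + 1:
                out.append("0 1")
                continue
            try:
                hull = ConvexHull(pts)
                out.append("%.17g 0" % hull.volume)
            except QhullError:
                out.append("0 1")
    sys.stdout.write("\n".join(out) + "\n")


if __name__ == "__main__":
    main(sys.argv[1])
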