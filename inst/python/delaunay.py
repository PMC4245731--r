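"""Delaunay triangulation backend.

Reads whitespace-separated xyz coordinates (one point per row) from argv[1],
writes one row per tetrahedron to argv[2]: four 0-based point indices followed
by the four face-neighbour tetrahedron indices (-1 = convex hull face).

Exit codes: 0 ok, 3 degenerate input (triangulation impossible), 2 usage/IO.
"""
import sys

import numpy as np
from scipy.spatial import Delaunay
from scipy.spatial._qhull import QhullError


def main():
    if len(sys.argv) != 3:
        sys.stderr.write("usage: delaunay.py points.txt out.txt\n")
        return 2
    pts = np.loadtxt(sys.argv[1], ndmin=2)
    if pts.ndim != 2 or pts.shape[1] != 3 or pts.shape[0] < 4:
        sys.stderr.write("need >= 4 three-dimensional points\n")
        return 3
    try:
        tri = Delaunay(pts)
    except QhullError as exc:
        sys.stderr.write("qhull: %s\n" % str(exc).splitlines()[0])
        return 3
    out = np.hstack([tri.simplices, tri.neighbors]).astype(np.int64)
    np.savetxt(sys.argv[2], out, fmt="%d")
    return 0


if __name__ == "__main__":
    sys.exit(main())
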