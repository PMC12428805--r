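"""Independent dense-flow reference used only as a cross-check oracle.

Reads two grayscale images stored as whitespace-separated text matrices,
runs scikit-image's iterative Lucas-Kanade flow, and writes the estimated
displacement (same ref -> mov convention: ref(p) ~ mov(p + d(p))) as two
text matrices <out_stem>_dx.txt and <out_stem>_dy.txt.

usage: python flow_oracle.py ref.txt mov.txt out_stem [radius]
"""
import sys

import numpy as np
from skimage.registration import optical_flow_ilk


def main() -> None:
    ref = np.loadtxt(sys.argv[1])
    mov = np.loadtxt(sys.argv[2])
    stem = sys.argv[3]
    radius = int(sys.argv[4]) if len(sys.argv) > 4 else 7
    # optical_flow_ilk(reference, moving) returns (row, col) displacement v
    # such that moving(p + v(p)) ~ reference(p)
    v, u = optical_flow_ilk(ref, mov, radius=radius)
    np.savetxt(stem + "_dx.txt", u)
    np.savetxt(stem + "_dy.txt", v)


if __name__ == "__main__":
    main()
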