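"""Bridge between MATLAB v5 container files and CSV, used by dcColoc for
its MATLAB localization dialect.

Layout of the .mat file (this package's documented dialect):
  frame, x, y, intensity : double column vectors (x, y in nm)
  pixel_size_nm, n_frames : double scalars
  channel : string

Usage:
  python mat_bridge.py write <mat> <csv> <channel> <pixel_size_nm> <n_frames>
  python mat_bridge.py read  <mat> <csv> <meta_csv>
"""
import sys

import numpy as np
import scipy.io


def main(argv):
    mode = argv[0]
    if mode == "write":
        mat_path, csv_path, channel, pixel, nframes = argv[1:6]
        data = np.genfromtxt(csv_path, delimiter=",", names=True)
        data = np.atleast_1d(data)
        cols = {}
        for name in ("frame", "x", "y", "intensity"):
            cols[name] = np.asarray(data[name], dtype=float).reshape(-1, 1)
        cols["pixel_size_nm"] = float(pixel)
        cols["n_frames"] = float(nframes)
        cols["channel"] = channel
        scipy.io.savemat(mat_path, cols, format="5")
    elif mode == "read":
        mat_path, csv_path, meta_path = argv[1:4]
        mat = scipy.io.loadmat(mat_path)
        missing = [c for c in ("frame", "x", "y", "intensity")
                   if c not in mat]
        if missing:
            sys.stderr.write("missing variable(s): %s\n"
                             % ",".join(missing))
            return 2
        cols = [np.asarray(mat[c], dtype=float).ravel()
                for c in ("frame", "x", "y", "intensity")]
        with open(csv_path, "w") as fh:
            fh.write("frame,x,y,intensity\n")
            for f, x, y, i in zip(*cols):
                fh.write("%d,%.17g,%.17g,%.17g\n" % (int(f), x, y, i))
        channel = ""
        if "channel" in mat and mat["channel"].size:
            channel = str(np.asarray(mat["channel"]).ravel()[0])
        pixel = float(np.asarray(mat.get("pixel_size_nm", 100.0)).ravel()[0])
        nframes = int(np.asarray(mat.get("n_frames", 0)).ravel()[0])
        with open(meta_path, "w") as fh:
            fh.write("channel,pixel_size_nm,n_frames\n")
            fh.write("%s,%.17g,%d\n" % (channel, pixel, nframes))
    else:
        sys.stderr.write("unknown mode %r\n" % mode)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
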