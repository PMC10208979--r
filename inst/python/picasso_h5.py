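"""Bridge between resikit and the Picasso-dialect HDF5 localization format.

Usage:
    python picasso_h5.py read  <file.hdf5> <out.csv>
    python picasso_h5.py write <in.csv>   <file.hdf5>

The HDF5 layout is a single structured dataset named "locs" whose fields
are a subset of {frame, x, y, z, lpx, lpy, channel}. All fields are stored
as float64 except frame/channel (uint32/int32) so that a write/read round
trip is lossless. The CSV exchanged with R carries the same raw (pixel
or nm) units as the dataset; unit conversion happens on the R side.
"""
import csv
import sys

import h5py
import numpy as np

FLOAT_FIELDS = ("x", "y", "z", "lpx", "lpy")


def read(h5_path, csv_path):
    with h5py.File(h5_path, "r") as f:
        if "locs" not in f:
            sys.exit("format error: missing dataset 'locs'")
        locs = f["locs"][()]
    names = list(locs.dtype.names or ())
    with open(csv_path, "w", newline="") as out:
        w = csv.writer(out)
        w.writerow(names)
        for rec in locs:
            w.writerow([repr(v) if isinstance(v, float) else v
                        for v in (rec[n].item() for n in names)])


def write(csv_path, h5_path):
    with open(csv_path, newline="") as src:
        rows = list(csv.reader(src))
    header, body = rows[0], rows[1:]
    dtype = []
    for name in header:
        if name == "frame":
            dtype.append((name, "u4"))
        elif name == "channel":
            dtype.append((name, "i4"))
        else:
            dtype.append((name, "f8"))
    locs = np.zeros(len(body), dtype=dtype)
    for i, row in enumerate(body):
        for name, val in zip(header, row):
            locs[i][name] = float(val)
    with h5py.File(h5_path, "w") as f:
        f.create_dataset("locs", data=locs)


def main(argv):
    if len(argv) != 4 or argv[1] not in ("read", "write"):
        sys.exit(__doc__)
    if argv[1] == "read":
        read(argv[2], argv[3])
    else:
        write(argv[2], argv[3])


if __name__ == "__main__":
    main(sys.argv)
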