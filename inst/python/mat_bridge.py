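"""MATLAB .nirs/.mat <-> JSON bridge.

R has no MATLAB-file reader in this dependency set; this helper converts the
Homer-style .nirs structure (fields d, SD.MeasList, SD.Lambda, SD.SrcPos,
SD.DetPos, optional t, s, aux, age) to and from JSON for the R package.

Usage:
    python mat_bridge.py read  <file.mat>  <out.json>
    python mat_bridge.py write <in.json>   <file.mat>
"""
import json
import sys

import numpy as np
import scipy.io as sio


def fail(msg):
    json.dump({"error": msg}, open(sys.argv[3], "w"))
    sys.exit(1)


def getfield(sd, name):
    try:
        v = getattr(sd, name)
    except AttributeError:
        return None
    return np.atleast_2d(np.asarray(v, dtype=float)).tolist()


def do_read(path, out):
    try:
        m = sio.loadmat(path, squeeze_me=False, struct_as_record=False)
    except Exception as e:  # noqa: BLE001
        fail(f"cannot read MATLAB file {path}: {e}")
    if "d" not in m:
        fail("missing mandatory field: d")
    if "SD" not in m:
        fail("missing mandatory field: SD")
    d = np.asarray(m["d"], dtype=float)
    sd = m["SD"][0, 0]
    meas = getfield(sd, "MeasList")
    if meas is None:
        fail("missing mandatory field: SD.MeasList")
    obj = {
        "d": d.tolist(),
        "meas_list": meas,
        "lambda": getfield(sd, "Lambda"),
        "src_pos": getfield(sd, "SrcPos"),
        "det_pos": getfield(sd, "DetPos"),
    }
    for opt in ("t", "s", "aux", "age"):
        if opt in m:
            obj[opt] = np.asarray(m[opt], dtype=float).ravel().tolist()
    json.dump(obj, open(out, "w"))


def do_write(inp, path):
    obj = json.load(open(inp))
    sd = {
        "MeasList": np.asarray(obj["meas_list"], dtype=float),
        "Lambda": np.asarray(obj["lambda"], dtype=float),
        "SrcPos": np.asarray(obj["src_pos"], dtype=float),
        "DetPos": np.asarray(obj["det_pos"], dtype=float),
    }
    sd["nSrcs"] = float(sd["SrcPos"].shape[0])
    sd["nDets"] = float(sd["DetPos"].shape[0])
    out = {"d": np.asarray(obj["d"], dtype=float), "SD": sd}
    for opt in ("t", "s", "aux", "age"):
        if obj.get(opt) is not None:
            out[opt] = np.asarray(obj[opt], dtype=float)
    sio.savemat(path, out)


if __name__ == "__main__":
    if len(sys.argv) != 4 or sys.argv[1] not in ("read", "write"):
        sys.stderr.write(__doc__)
        sys.exit(2)
    if sys.argv[1] == "read":
        do_read(sys.argv[2], sys.argv[3])
    else:
        do_write(sys.argv[2], sys.argv[3])
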