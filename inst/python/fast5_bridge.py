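#!/usr/bin/env python
"""HDF5 bridge between multi-read FAST5 containers and SLOW5 ASCII.

Only byte shuttling lives here; all format logic stays in the R package.

Expected multi-read FAST5 layout (one group per read):

    /read_<read_id>                 attrs: run metadata strings (run_id, ...)
    /read_<read_id>/channel_id      attrs: digitisation, offset, range,
                                           sampling_rate
    /read_<read_id>/Raw/Signal      int16 dataset

ATTRIBUTE_MAP below translates alternative attribute spellings seen in the
wild; extend it if your files use others.

Usage:
    fast5_bridge.py dump  <in.fast5> <out.slow5>
    fast5_bridge.py build <in.slow5> <out.fast5>

Exit codes: 0 ok, 2 usage, 3 missing dependency, 4 unsupported format.
"""

import sys

try:
    import h5py
    import numpy as np
except ImportError as exc:  # pragma: no cover
    sys.stderr.write("missing dependency: %s\n" % exc)
    sys.exit(3)

# calibration attribute name -> accepted spellings, in priority order
ATTRIBUTE_MAP = {
    "digitisation": ["digitisation", "digitization"],
    "offset": ["offset"],
    "range": ["range"],
    "sampling_rate": ["sampling_rate", "sample_rate"],
}

PRIMARY_TYPES = "#char*\tuint32_t\tdouble\tdouble\tdouble\tdouble\tuint64_t\tint16_t*"
PRIMARY_NAMES = "#read_id\tread_group\tdigitisation\toffset\trange\tsampling_rate\tlen_raw_signal\traw_signal"


def _die(code, msg):
    sys.stderr.write(msg + "\n")
    sys.exit(code)


def _decode(v):
    if isinstance(v, bytes):
        return v.decode("utf-8")
    return str(v)


def _get_cal(grp, name):
    for cand in ATTRIBUTE_MAP[name]:
        if cand in grp.attrs:
            return float(grp.attrs[cand])
    _die(4, "read group %s lacks calibration attribute %s" % (grp.name, name))


def dump(fast5_path, slow5_path):
    with h5py.File(fast5_path, "r") as h5:
        keys = [k for k in h5.keys() if k.startswith("read_")]
        if not keys:
            if "Raw" in h5 or "UniqueGlobalKey" in h5:
                _die(4, "single-read FAST5 is not supported; "
                        "use a multi-read container")
            _die(4, "no read_* groups found in %s" % fast5_path)
        keys.sort()
        run_attrs = {k: _decode(v) for k, v in h5[keys[0]].attrs.items()}
        with open(slow5_path, "w") as out:
            out.write("#slow5_version\t1.0.0\n#num_read_groups\t1\n")
            for name in sorted(run_attrs):
                out.write("@%s\t%s\n" % (name, run_attrs[name]))
            out.write(PRIMARY_TYPES + "\n" + PRIMARY_NAMES + "\n")
            for key in keys:
                grp = h5[key]
                if "Raw" not in grp or "Signal" not in grp["Raw"]:
                    _die(4, "read group %s lacks a Raw/Signal dataset" % key)
                sig = np.asarray(grp["Raw"]["Signal"][()], dtype=np.int64)
                cal_grp = grp["channel_id"] if "channel_id" in grp else grp
                cal = {n: _get_cal(cal_grp, n) for n in ATTRIBUTE_MAP}
                read_id = key[len("read_"):]
                if "read_id" in grp["Raw"].attrs:
                    read_id = _decode(grp["Raw"].attrs["read_id"])
                out.write("%s\t0\t%r\t%r\t%r\t%r\t%d\t%s\n" % (
                    read_id, cal["digitisation"], cal["offset"],
                    cal["range"], cal["sampling_rate"], sig.size,
                    ",".join(str(int(x)) for x in sig)))


def _parse_slow5(path):
    header = {"attrs": [], "ngroups": 1}
    records = []
    with open(path) as fh:
        in_header, schema_rows = True, 0
        for line in fh:
            line = line.rstrip("\n")
            if in_header:
                if line.startswith("@"):
                    cells = line.split("\t")
                    header["attrs"].append((cells[0][1:], cells[1:]))
                elif line.startswith("#num_read_groups"):
                    header["ngroups"] = int(line.split("\t")[1])
                elif line.startswith("#slow5_version"):
                    pass
                elif line.startswith("#"):
                    schema_rows += 1
                    if schema_rows == 2:
                        in_header = False
                continue
            if not line:
                continue
            cells = line.split("\t")
            sig = ([] if cells[7] == "" else
                   [int(x) for x in cells[7].split(",")])
            records.append({
                "read_id": cells[0], "read_group": int(cells[1]),
                "digitisation": float(cells[2]), "offset": float(cells[3]),
                "range": float(cells[4]), "sampling_rate": float(cells[5]),
                "signal": sig})
    return header, records


def build(slow5_path, fast5_path):
    header, records = _parse_slow5(slow5_path)
    with h5py.File(fast5_path, "w") as h5:
        h5.attrs["file_type"] = "multi-read"
        for rec in records:
            grp = h5.create_group("read_" + rec["read_id"])
            g = rec["read_group"]
            for name, values in header["attrs"]:
                grp.attrs[name] = values[g] if g < len(values) else values[0]
            ch = grp.create_group("channel_id")
            ch.attrs["digitisation"] = rec["digitisation"]
            ch.attrs["offset"] = rec["offset"]
            ch.attrs["range"] = rec["range"]
            ch.attrs["sampling_rate"] = rec["sampling_rate"]
            raw = grp.create_group("Raw")
            raw.attrs["read_id"] = rec["read_id"]
            raw.create_dataset("Signal",
                               data=np.asarray(rec["signal"],
                                               dtype=np.int16))


def main(argv):
    if len(argv) != 4 or argv[1] not in ("dump", "build"):
        _die(2, __doc__)
    if argv[1] == "dump":
        dump(argv[2], argv[3])
    else:
        build(argv[2], argv[3])


if __name__ == "__main__":
    main(sys.argv)
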