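"""JPEG2000 encode/decode worker.

Reads a JSON job list and executes it in one process so that callers can
batch hundreds of images without per-image interpreter startup.

Usage: python jp2_codec.py JOBS.json REPORT.json

Each job is an object:
  {"op": "encode"|"decode"|"roundtrip",
   "src": path, "dst": path,
   "jp2": path (roundtrip: where the codestream is written),
   "ratio": number (<=1 or missing => lossless)}

encode:    src PNG -> dst JPEG2000 codestream
decode:    src JPEG2000 -> dst PNG
roundtrip: src PNG -> jp2 -> dst PNG (decoded)

The report lists, per job, the stored byte size and image dimensions.
"""
import json
import sys

from PIL import Image


def _encode(src, dst, ratio):
    im = Image.open(src).convert("RGB")
    if ratio is None or ratio <= 1:
        im.save(dst, "JPEG2000", irreversible=False)
    else:
        im.save(dst, "JPEG2000", irreversible=True,
                quality_mode="rates", quality_layers=[float(ratio)])
    return im.size


def _decode(src, dst):
    im = Image.open(src)
    im.load()
    im.convert("RGB").save(dst, "PNG")
    return im.size


def main(jobs_path, report_path):
    with open(jobs_path) as fh:
        jobs = json.load(fh)
    if isinstance(jobs, dict):
        jobs = [jobs]
    report = []
    for job in jobs:
        op = job["op"]
        ratio = job.get("ratio")
        if op == "encode":
            w, h = _encode(job["src"], job["dst"], ratio)
            stored = job["dst"]
        elif op == "decode":
            w, h = _decode(job["src"], job["dst"])
            stored = job["src"]
        elif op == "roundtrip":
            _encode(job["src"], job["jp2"], ratio)
            w, h = _decode(job["jp2"], job["dst"])
            stored = job["jp2"]
        else:
            raise ValueError("unknown op: %r" % op)
        import os
        report.append({"op": op, "width": w, "height": h,
                       "stored_bytes": os.path.getsize(stored)})
    with open(report_path, "w") as fh:
        json.dump(report, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
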