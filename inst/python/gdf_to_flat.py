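"""Convert a GDF motor-imagery recording into a flat float32 dump + JSON header.

Called by mifuse::load_gdf_epochs(); not a user-facing script.
Usage: python gdf_to_flat.py <in.gdf> <out-prefix> <code,code,...> <window_s>
"""
import json
import sys

import numpy as np
import mne


def main():
    path, prefix, codes_arg, window_arg = sys.argv[1:5]
    codes = [int(c) for c in codes_arg.split(",")]
    window = float(window_arg)

    raw = mne.io.read_raw_gdf(path, preload=True, verbose="error")
    # Drop EOG channels; keep EEG only.
    eog = [ch for ch in raw.ch_names if "EOG" in ch.upper()]
    if eog:
        raw.drop_channels(eog)
    fs = raw.info["sfreq"]
    data = raw.get_data()  # channels x samples
    n_samp = int(round(window * fs))

    events, event_id = mne.events_from_annotations(raw, verbose="error")
    # GDF annotation descriptions are the original codes as strings.
    wanted = {}
    for desc, eid in event_id.items():
        try:
            code = int(desc)
        except ValueError:
            continue
        if code in codes:
            wanted[eid] = codes.index(code)

    trials, labels, skipped = [], [], 0
    for onset, _, eid in events:
        if eid not in wanted:
            continue
        if onset + n_samp > data.shape[1]:
            skipped += 1
            continue
        trials.append(data[:, onset:onset + n_samp])
        labels.append(wanted[eid])

    arr = np.asarray(trials, dtype=np.float32)
    arr.tofile(prefix + ".f32")
    hdr = {
        "n_trials": int(arr.shape[0]),
        "n_channels": int(arr.shape[1] if arr.ndim == 3 else 0),
        "n_samples": int(arr.shape[2] if arr.ndim == 3 else 0),
        "fs": float(fs),
        "labels": [int(l) for l in labels],
        "channel_names": list(raw.ch_names),
        "subject_id": path.rsplit("/", 1)[-1],
        "n_skipped": int(skipped),
    }
    with open(prefix + ".json", "w") as fh:
        json.dump(hdr, fh)


if __name__ == "__main__":
    main()
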