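{
  "spots": [
    {
      "label": "C1",
      "role": "control_positive",
      "analyte": null,
      "replicate": null,
      "x": 608,
      "y": 760,
      "radius": 48
    },
    {
      "label": "C2",
      "role": "control_positive",
      "analyte": null,
      "replicate": null,
      "x": 2028,
      "y": 760,
      "radius": 48
    },
    {
      "label": "C3",
      "role": "control_positive",
      "analyte": null,
      "replicate": null,
      "x": 3448,
      "y": 760,
      "radius": 48
    },
    {
      "label": "C4",
      "role": "control_positive",
      "analyte": null,
      "replicate": null,
      "x": 608,
      "y": 1125,
      "radius": 48
    },
    {
      "label": "VSIG4-r1",
      "role": "test",
      "analyte": "VSIG4",
      "replicate": 1,
      "x": 1014,
      "y": 1125,
      "radius": 48
    },
    {
      "label": "OPN-r1",
      "role": "test",
      "analyte": "OPN",
      "replicate": 1,
      "x": 1521,
      "y": 1125,
      "radius": 48
    },
    {
      "label": "VCAM1-r1",
      "role": "test",
      "analyte": "VCAM1",
      "replicate": 1,
      "x": 2028,
      "y": 1125,
      "radius": 48
    },
    {
      "label": "ALCAM-r1",
      "role": "test",
      "analyte": "ALCAM",
      "replicate": 1,
      "x": 2535,
      "y": 1125,
      "radius": 48
    },
    {
      "label": "TNFRSF1B-r1",
      "role": "test",
      "analyte": "TNFRSF1B",
      "replicate": 1,
      "x": 3042,
      "y": 1125,
      "radius": 48
    },
    {
      "label": "C5",
      "role": "control_negative",
      "analyte": null,
      "replicate": null,
      "x": 3448,
      "y": 1125,
      "radius": 48
    },
    {
      "label": "C6",
      "role": "control_negative",
      "analyte": null,
      "replicate": null,
      "x": 608,
      "y": 1490,
      "radius": 48
    },
    {
      "label": "VSIG4-r2",
      "role": "test",
      "analyte": "VSIG4",
      "replicate": 2,
      "x": 1014,
      "y": 1490,
      "radius": 48
    },
    {
      "label": "OPN-r2",
      "role": "test",
      "analyte": "OPN",
      "replicate": 2,
      "x": 1521,
      "y": 1490,
      "radius": 48
    },
    {
      "label": "VCAM1-r2",
      "role": "test",
      "analyte": "VCAM1",
      "replicate": 2,
      "x": 2028,
      "y": 1490,
      "radius": 48
    },
    {
      "label": "ALCAM-r2",
      "role": "test",
      "analyte": "ALCAM",
      "replicate": 2,
      "x": 2535,
      "y": 1490,
      "radius": 48
    },
    {
      "label": "TNFRSF1B-r2",
      "role": "test",
      "analyte": "TNFRSF1B",
      "replicate": 2,
      "x": 3042,
      "y": 1490,
      "radius": 48
    },
    {
      "label": "VSIG4-r3",
      "role": "test",
      "analyte": "VSIG4",
      "replicate": 3,
      "x": 1014,
      "y": 1854,
      "radius": 48
    },
    {
      "label": "OPN-r3",
      "role": "test",
      "analyte": "OPN",
      "replicate": 3,
      "x": 1521,
      "y": 1854,
      "radius": 48
    },
    {
      "label": "VCAM1-r3",
      "role": "test",
      "analyte": "VCAM1",
      "replicate": 3,
      "x": 2028,
      "y": 1854,
      "radius": 48
    },
    {
      "label": "ALCAM-r3",
      "role": "test",
      "analyte": "ALCAM",
      "replicate": 3,
      "x": 2535,
      "y": 1854,
      "radius": 48
    },
    {
      "label": "TNFRSF1B-r3",
      "role": "test",
      "analyte": "TNFRSF1B",
      "replicate": 3,
      "x": 3042,
      "y": 1854,
      "radius": 48
    },
    {
      "label": "C7",
      "role": "control_positive",
      "analyte": null,
      "replicate": null,
      "x": 3448,
      "y": 1854,
      "radius": 48
    }
  ],
  "n_rows": 4,
  "anchor_labels": ["C1", "C2", "C3"],
  "bound_labels": ["C4", "C7"],
  "search_range": 1200,
  "ref_width": 4056,
  "ref_height": 3040
}
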