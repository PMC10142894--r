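{
  "version": "0.1.0",
  "config": {
    "baseline_stride_s": 60,
    "seed": 424242
  },
  "sessions": [
    {
      "session_id": "sim-no_nodding_video-second-730204497",
      "condition": "no_nodding_video",
      "half": "second",
      "n_beats": 494,
      "n_rejected_beats": 0,
      "n_nods": 0,
      "n_nod_effects": 0,
      "n_nod_excluded": 0,
      "n_baseline": 5,
      "n_all_per_s": 3.40586728832267e-05
    },
    {
      "session_id": "sim-no_nodding_video-second-1433619262",
      "condition": "no_nodding_video",
      "half": "second",
      "n_beats": 495,
      "n_rejected_beats": 0,
      "n_nods": 0,
      "n_nod_effects": 0,
      "n_nod_excluded": 0,
      "n_baseline": 5,
      "n_all_per_s": 0.000219270491302353
    },
    {
      "session_id": "sim-with_video_not_forced-second-1188438606",
      "condition": "with_video_not_forced",
      "half": "second",
      "n_beats": 493,
      "n_rejected_beats": 0,
      "n_nods": 12,
      "n_nod_effects": 8,
      "n_nod_excluded": 4,
      "n_baseline": 1,
      "n_all_per_s": 0.000310052056874475
    },
    {
      "session_id": "sim-with_video_not_forced-second-293239817",
      "condition": "with_video_not_forced",
      "half": "second",
      "n_beats": 493,
      "n_rejected_beats": 0,
      "n_nods": 11,
      "n_nod_effects": 8,
      "n_nod_excluded": 3,
      "n_baseline": 1,
      "n_all_per_s": 0.000342645826586755
    },
    {
      "session_id": "sim-with_video_forced-second-706162022",
      "condition": "with_video_forced",
      "half": "second",
      "n_beats": 490,
      "n_rejected_beats": 0,
      "n_nods": 7,
      "n_nod_effects": 7,
      "n_nod_excluded": 0,
      "n_baseline": 0,
      "n_all_per_s": -0.000214760060243249
    },
    {
      "session_id": "sim-with_video_forced-second-2091216621",
      "condition": "with_video_forced",
      "half": "second",
      "n_beats": 494,
      "n_rejected_beats": 0,
      "n_nods": 7,
      "n_nod_effects": 7,
      "n_nod_excluded": 0,
      "n_baseline": 0,
      "n_all_per_s": 0.000160604044901322
    }
  ],
  "groups": [
    {
      "group": "baseline_no_nod_trend",
      "n": 12,
      "mean_per_s": 0.000123438713255912
    },
    {
      "group": "not_forced_effect",
      "n": 16,
      "mean_per_s": -0.000283353298088379
    },
    {
      "group": "forced_effect",
      "n": 14,
      "mean_per_s": 7.67177201825337e-05
    }
  ],
  "kruskal": {
    "H": 2.22195855086221,
    "df": 2,
    "p": 0.329236390050225
  },
  "omnibus_alpha": 0.05,
  "omnibus_significant": false,
  "pairwise": null
}
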