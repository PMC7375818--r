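{
  "comment": "Per-layer synapse population profiles for the human CA1 neuropil, transcribed/calibrated from the published per-layer table (corrected values). intensity: synapses/um^3 (mean over stacks); intensity_sd: between-stack SD, metadata only (the generator is a homogeneous Poisson process at the mean); size: SAS-area summary per polarity (mean nm^2, SEM nm^2, n synapses) from which log-normal parameters are derived by method of moments with SD = SEM*sqrt(n). target/shape probabilities are pooled across layers where the per-layer split was not published.",
  "layers": {
    "SO":  { "intensity": 0.45, "intensity_sd": 0.19, "as_fraction": 0.9410,
             "size": { "AS": { "mean": 86716.52, "sem": 1371.02, "n": 2648 },
                       "SS": { "mean": 85737.60, "sem": 5869.60, "n": 166 } } },
    "dSP": { "intensity": 0.69, "intensity_sd": 0.22, "as_fraction": 0.9320,
             "size": { "AS": { "mean": 92045.29, "sem": 1192.92, "n": 3849 },
                       "SS": { "mean": 74764.69, "sem": 3057.33, "n": 281 } } },
    "sSP": { "intensity": 0.99, "intensity_sd": 0.18, "as_fraction": 0.9636,
             "size": { "AS": { "mean": 88061.63, "sem": 1038.49, "n": 5183 },
                       "SS": { "mean": 58305.43, "sem": 2612.01, "n": 196 } } },
    "SR":  { "intensity": 0.67, "intensity_sd": 0.19, "as_fraction": 0.9571,
             "size": { "AS": { "mean": 82841.26, "sem": 1201.47, "n": 3836 },
                       "SS": { "mean": 63183.20, "sem": 2734.96, "n": 172 } } },
    "SLM": { "intensity": 0.52, "intensity_sd": 0.08, "as_fraction": 0.8924,
             "size": { "AS": { "mean": 91419.95, "sem": 1376.38, "n": 2622 },
                       "SS": { "mean": 57390.19, "sem": 2071.04, "n": 316 } } }
  },
  "target_probs": {
    "AS": { "spine_head": 0.404255, "spine_neck": 0.002031,
            "shaft_spiny": 0.035719, "shaft_aspiny": 0.023813,
            "unknown": 0.534182 },
    "SS": { "spine_head": 0.072499, "spine_neck": 0.015914,
            "shaft_spiny": 0.513221, "shaft_aspiny": 0.276350,
            "unknown": 0.122016 }
  },
  "shape_probs": {
    "AS": { "macular": 0.8595, "horseshoe": 0.0450,
            "perforated": 0.0813, "fragmented": 0.0142 },
    "SS": { "macular": 0.8055, "horseshoe": 0.1194,
            "perforated": 0.0500, "fragmented": 0.0251 }
  },
  "perimeter_model": {
    "AS": { "shape_factor": 1.3738, "sdlog": 0.15 },
    "SS": { "shape_factor": 1.4996, "sdlog": 0.15 }
  },
  "curvature_model": {
    "AS": { "alpha": 1.5, "beta": 28.5 },
    "SS": { "alpha": 1.5, "beta": 30.415 }
  }
}
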