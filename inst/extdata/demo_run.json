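{
  "stages": ["palm", "poses", "bret"],
  "seed": 1,
  "output_dir": "pipeline_out",
  "palm": {
    "sim": {
      "counts_per_size": {"1": 50, "2": 30, "3": 15, "5": 5},
      "cluster_radius_nm": 10,
      "loc_error_sd_nm": 5,
      "blink_rate": 0,
      "min_center_sep_nm": 300
    },
    "census": {
      "dedup_radius_nm": 20,
      "search_radius_nm": 50,
      "assignment_mode": "greedy_seed",
      "density_threshold_per_um2": 100,
      "max_reported_size": 10
    },
    "apply_dedup": false
  },
  "poses": {
    "sim": {
      "n_poses": 500,
      "tilt_range": [0, 0.8],
      "zoffset_range": [-12, 12]
    },
    "filter": {
      "tilt_max_rad": 0.4,
      "z_offset_max_A": 6.0,
      "keep_best": 4000
    },
    "rmsd_cutoff_A": 3.0
  },
  "bret": {
    "kinetics": {"k_per_s": 0.02, "plateau": 0.05, "dt_s": 3, "t_max_s": 300, "noise_sd": 0.002},
    "saturation": {"BRETmax": 0.3, "BRET50": 0.05, "n_x": 12, "x_max": 0.6, "noise_sd": 0.01},
    "dose_response": {"neg_log_ec50": 5.362, "Emax": 100, "baseline": 0, "noise_sd": 2}
  }
}
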