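{
  "succession_early": {
    "description": "Below-ground food-web functional group biomass, early succession (development stages 1-2)",
    "n": 159,
    "om": 6,
    "d_star": 0.782,
    "cohen_w": 0.184,
    "cohen_w_ci": [0.181, 0.186],
    "ssd": 38.4,
    "ssd_ci": [37.9, 38.9],
    "kl_d": 0.0071,
    "max_pr": 1.38
  },
  "succession_late": {
    "description": "Below-ground food-web functional group biomass, late succession (development stages 3-4)",
    "n": 208,
    "om": 6,
    "d_star": 0.664,
    "cohen_w": 0.171,
    "cohen_w_ci": [0.168, 0.175],
    "ssd": 21.2,
    "ssd_ci": [18.7, 23.7],
    "kl_d": 0.0068,
    "max_pr": 1.59
  },
  "diatoms_small": {
    "description": "Cells per diatom species colonizing small (12 mm2) glass-slide islands",
    "n": 105,
    "om": 6,
    "d_star": 0.759,
    "cohen_w": 0.25,
    "cohen_w_ci": [0.242, 0.257],
    "ssd": 54.9,
    "ssd_ci": [48.1, 61.7],
    "kl_d": 0.0125,
    "kl_d_recomputed": 0.0126,
    "max_pr": 1.87
  },
  "diatoms_large": {
    "description": "Cells per diatom species colonizing large (25 mm2) glass-slide islands",
    "n": 148,
    "om": 6,
    "d_star": 1.147,
    "cohen_w": 0.316,
    "cohen_w_ci": [0.308, 0.323],
    "ssd": 88.9,
    "ssd_ci": [79.7, 98.2],
    "kl_d": 0.0238,
    "max_pr": 1.98
  },
  "salamanders_pre1990": {
    "description": "Woodland salamander encounters per collector per site visit, persistent pre-1990 populations",
    "n": 96,
    "om": 2,
    "d_star": 0.783,
    "cohen_w": 0.195,
    "cohen_w_ci": [0.193, 0.197],
    "ssd": 63.9,
    "ssd_ci": [62.8, 65],
    "kl_d": 0.0083,
    "max_pr": 1.13
  },
  "salamanders_post1990": {
    "description": "Woodland salamander encounters per collector per site visit, declining post-1990 populations",
    "n": 173,
    "om": 3,
    "d_star": 1.437,
    "cohen_w": 0.328,
    "cohen_w_ci": [0.323, 0.332],
    "ssd": 119.4,
    "ssd_ci": [105.7, 133.1],
    "kl_d": 0.026,
    "max_pr": 2.23
  },
  "fish_ewh": {
    "description": "Relative weight (kg/km) of 141 fish species encounters from five exceptional-integrity Ohio streams",
    "n": 141,
    "om": 4,
    "d_star": 0.638,
    "cohen_w": 0.182,
    "cohen_w_ci": [0.177, 0.187],
    "ssd": 28.9,
    "ssd_ci": [26.4, 31.4],
    "kl_d": 0.0083,
    "max_pr": 1.46,
    "taylor": {
      "a": 3.36,
      "b": 2.07
    },
    "digit_means": [5.58, 3.28, 8.73, 7.68, 7.66, 13.28, 17.93, 20.46, 3.4],
    "digit_variances": [298, 43, 208, 274, 270, 658, 1213, 1619, 20]
  },
  "combined_steady_state": {
    "description": "Pooled digit counts of the four steady-state cases (succession early/late, pre-1990 salamanders, fish)",
    "n": 604,
    "om": null,
    "d_star": 0.632,
    "cohen_w": 0.091,
    "cohen_w_ci": [0.088, 0.093],
    "ssd": 6.62,
    "ssd_ci": [6.56, 6.68],
    "kl_d": 0.0019,
    "max_pr": 1.28
  }
}
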