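{
  "tallies/succession_early.csv": "6a92ae1d961c4239139b11e9725dd9d8",
  "tallies/succession_late.csv": "0fefe9d7094e58fa44774f22fa53dfcb",
  "tallies/diatoms_small.csv": "c5a8b56353f0e853f5b971b81fb07e00",
  "tallies/diatoms_large.csv": "715581b5d849e0411e89d79194ce7558",
  "tallies/salamanders_pre1990.csv": "bbd50221422fac6c09f737eaf3a12c1c",
  "tallies/salamanders_post1990.csv": "d315475376ebe048c0fcc8541244983f",
  "tallies/fish_ewh.csv": "ceabd66a6462e1dd5df89e2a58ee5237",
  "tallies/combined_steady_state.csv": "dafe5711c4141dd1301cafc30ca72683",
  "fish_ewh_biomass.csv": "a17339048a8efdb8bc8626a881e2e59c",
  "expected_stats.json": "0b986f192b9b5f9d2977c9fd1b173e10"
}
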