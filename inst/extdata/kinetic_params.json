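{
  "kon_hrg": 1.0,
  "koff_hrg": 3.0,
  "kon_het": 1.0,
  "koff_het": 1.0,
  "kon_hom": 0.05,
  "koff_hom": 1.0,
  "kon_tr": 5.0,
  "koff_tr": 0.05,
  "kon_pr": 1.0,
  "koff_pr": 0.1,
  "coop_ternary": 0.0065,
  "k_phos": 1.0,
  "k_dephos": 0.3,
  "kon_sos": 5.0,
  "koff_sos": 5.0,
  "k_sos_ras": 0.0055,
  "k_ras_het": 0.001,
  "k_ras_deact": 0.5,
  "k_raf_act": 0.002,
  "k_raf_deact": 0.5,
  "k_mek_act": 0.25,
  "k_mek_deact": 0.5,
  "k_erk_act": 0.005,
  "k_erk_deact": 0.3,
  "k_pi3k_act": 0.002,
  "k_pten": 0.005,
  "k_akt_act": 0.3,
  "k_akt_deact": 0.2,
  "ras_total": 100,
  "raf_total": 100,
  "mek_total": 120,
  "erk_total": 240,
  "pi3k_total": 100,
  "akt_total": 100,
  "pten_total": 100,
  "sos_total": 5.0
}
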