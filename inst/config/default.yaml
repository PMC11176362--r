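# Default run configuration. Section entries override the corresponding
# configuration constructors' defaults.
benchmark:
  hdac_like:
    number_of_signals: 275
    larmor_frequency_mhz: [600, 700, 800, 950]
    sw_h_hz: [2000, 5000]
    sw_c_hz: [2000, 5000]
    jcc_hz: {mean: 34, sd: 2}
    r2_h: {mean: 50, sd: 10}
    r2_c: {mean: 50, sd: 10}
  msg_like:
    number_of_signals: 600
    larmor_frequency_mhz: [600, 700, 800, 950]
    sw_h_hz: [2000, 5000]
    sw_c_hz: [2000, 5000]
    jcc_hz: {mean: 34, sd: 2}
    r2_h: {mean: 60, sd: 15}
    r2_c: {mean: 60, sd: 10}
training:
  full:
    n_train: 500000
    n_test: 50000
    write_planes: false
  reduced:
    n_train: 2000
    n_test: 200
    write_planes: true
model:
  r2_max_s: 25
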