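# Synthetic illumination-condition configuration for the four-arm maze.
#
# Anchors taken from the published testing parameters: the low condition is
# defined by 6 lx in the red arm and the high condition by ~100 lx; the
# red-high condition sets the red source high with the other three low; the
# equal condition targets ~3 cd/m2 (60 lx at the meter's lux/cd ratio of 20)
# in all four arms; the no-color condition leaves every arm unlit. Per-arm
# values not individually published (the other arms of L/M/H, which used "a
# similar setting" to the red source) are representative stand-ins, hence
# the _synthetic file name.
spectra:
  B: {peak_nm: [452], fwhm_nm: [22]}
  G: {peak_nm: [517], fwhm_nm: [31]}
  R: {peak_nm: [628], fwhm_nm: [17]}
  W: {peak_nm: [441, 533], fwhm_nm: [19, 104], weights: [0.3, 0.7]}
conditions:
  NC:
    B: {lux: 0.0}
    G: {lux: 0.0}
    R: {lux: 0.0}
    W: {lux: 0.0}
  L:
    B: {lux: 6.0}
    G: {lux: 6.0}
    R: {lux: 6.0}
    W: {lux: 6.0}
  M:
    B: {lux: 25.0}
    G: {lux: 25.0}
    R: {lux: 25.0}
    W: {lux: 25.0}
  H:
    B: {lux: 100.0}
    G: {lux: 100.0}
    R: {lux: 100.0}
    W: {lux: 100.0}
  RH:
    B: {lux: 6.0}
    G: {lux: 6.0}
    R: {lux: 100.0}
    W: {lux: 6.0}
  E:
    B: {cd_m2: 3.0}
    G: {cd_m2: 3.0}
    R: {cd_m2: 3.0}
    W: {cd_m2: 3.0}
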