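# Default run configuration: one experiment per reference constant,
# module default grids and noise levels. Tolerances are relative.
seed: 1
tolerances:
  default: 0.10
  Ea: 0.10
  Tm_apo: 0.05
  Tm_emd: 0.05
  KM_actin: 0.20
  k_rescue: 0.15
  k_off_rescue: 0.30
experiments:
  - name: actin activation (control)
    type: actin_activation
    condition: control
    noise_sd: 0.01
  - name: actin activation (+EMD)
    type: actin_activation
    condition: emd
    noise_sd: 0.01
  - name: ATP dependence of transients (control)
    type: atp_dependence
    condition: control
    noise_sd: 0.01
  - name: ATP dependence of transients (+EMD)
    type: atp_dependence
    condition: emd
    noise_sd: 0.01
  - name: phosphate release (control)
    type: pi_release
    condition: control
    noise_sd: 0.01
  - name: phosphate release (+EMD)
    type: pi_release
    condition: emd
    noise_sd: 0.01
  - name: ADP release from myosin (control)
    type: adp_release
    which: kD
    condition: control
    noise_sd: 0.01
  - name: ADP release from actomyosin (control)
    type: adp_release
    which: kAD
    condition: control
    noise_sd: 0.01
  - name: Arrhenius (control)
    type: arrhenius
    condition: control
    noise_sd: 0.02
  - name: Arrhenius (+EMD)
    type: arrhenius
    condition: emd
    noise_sd: 0.02
  - name: dose-response (beta-cardiac S1)
    type: dose_response
    condition: emd
    noise_sd: 0.01
  - name: binding isotherm (beta-cardiac S1)
    type: binding_isotherm
    param: KD_S1
    condition: emd
    noise_sd: 0.01
  - name: thermal melt (apo)
    type: melt
    condition: control
    noise_sd: 0.01
  - name: thermal melt (+EMD)
    type: melt
    condition: emd
    noise_sd: 0.01
  - name: refolding rescue kinetics
    type: rescue
    condition: emd
    noise_sd: 0.01
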