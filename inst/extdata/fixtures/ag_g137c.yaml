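# (AG)6(AG-G137C): cysteine moved to 137 near the narrowest point of the
# barrel. Diastereomer pairs resolved for all straight-chain aldehydes
# (splits within the published 0.4-1.6% range); published anchors: butanal-B
# 95.9, pentanal-A 95.8, butanal-B vs 2-methylpropanal-B split 0.25%.
pore:
  name: (AG)6(AG-G137C)
  open_current_pA: -129.0
  potential_mV: -50.0
  rms_noise_pA: 1.0
  provenance:
    open_current_pA: interpolated
    potential_mV: printed
    rms_noise_pA: derived
analytes:
  - name: ethanal
    khyd: 1.2
    k_on_obs: 0.25
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 98.3, k_off: 9.4, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 97.9, k_off: 9.4, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: propanal
    khyd: 0.67
    k_on_obs: 0.30
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 97.5, k_off: 8.8, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 97.0, k_off: 8.8, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: 2-methylpropanal
    khyd: 0.45
    k_on_obs: 0.30
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 96.75, k_off: 7.7, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 96.15, k_off: 7.7, fraction: 0.5,
         provenance: {ires_pct: derived, k_off: interpolated}}
  - name: butanal
    khyd: 0.50
    k_on_obs: 0.31
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 96.6, k_off: 7.6923, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: derived}}
      - {label: B, ires_pct: 95.9, k_off: 7.6923, fraction: 0.5,
         provenance: {ires_pct: printed, k_off: derived}}
  - name: pentanal
    khyd: 0.45
    k_on_obs: 0.29
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 95.8, k_off: 6.3, fraction: 0.5,
         provenance: {ires_pct: printed, k_off: interpolated}}
      - {label: B, ires_pct: 94.9, k_off: 6.3, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: hexanal
    khyd: 0.45
    k_on_obs: 0.26
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 94.8, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 93.7, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: heptanal
    khyd: 0.42
    k_on_obs: 0.21
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 93.6, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 92.3, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: octanal
    khyd: 0.42
    k_on_obs: 0.20
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 92.2, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 90.6, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
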