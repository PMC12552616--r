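# (MK)6(MK-T115C): methionine reintroduced at 113 narrows the barrel near the
# sensing cysteine; diastereomer pairs resolved for all straight-chain
# aldehydes (splits within the published 0.3-1.0% range; the butanal-B vs
# 2-methylpropanal-A isomer gap of 0.43% is the published anchor).
pore:
  name: (MK)6(MK-T115C)
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
      - {label: A, ires_pct: 99.2, k_off: 9.4, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 98.9, k_off: 9.4, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: propanal
    khyd: 0.67
    k_on_obs: 0.30
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 98.4, k_off: 8.8, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 98.0, k_off: 8.8, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: 2-methylpropanal
    khyd: 0.45
    k_on_obs: 0.30
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 97.53, k_off: 7.7, fraction: 0.5,
         provenance: {ires_pct: derived, k_off: interpolated}}
      - {label: B, ires_pct: 97.03, k_off: 7.7, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: butanal
    khyd: 0.50
    k_on_obs: 0.31
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 97.6, k_off: 7.6923, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: derived}}
      - {label: B, ires_pct: 97.1, k_off: 7.6923, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: derived}}
  - name: pentanal
    khyd: 0.45
    k_on_obs: 0.29
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 96.7, k_off: 6.3, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 96.1, k_off: 6.3, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: hexanal
    khyd: 0.45
    k_on_obs: 0.26
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 95.9, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 95.2, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: heptanal
    khyd: 0.42
    k_on_obs: 0.21
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 95.0, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 94.2, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: octanal
    khyd: 0.42
    k_on_obs: 0.20
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 94.1, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
      - {label: B, ires_pct: 93.1, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
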