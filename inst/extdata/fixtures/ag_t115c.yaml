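# (AG)6(AG-T115C) heteroheptamer: single cysteine at position 115 in the
# AG (K8A-M113G-K131G-K147G) background. Reference sensor variant.
# provenance flags: printed (value as published), interpolated (filled in by
# the ~0.7% per CH2 level rule or by smooth trends), derived (computed from a
# published quantity, e.g. k_off = 1/lifetime or k_on = k_on'/(1+K_hyd)).
pore:
  name: (AG)6(AG-T115C)
  open_current_pA: -129.0
  potential_mV: -50.0
  rms_noise_pA: 1.0
  provenance:
    open_current_pA: printed
    potential_mV: printed
    rms_noise_pA: derived
analytes:
  - name: ethanal
    khyd: 1.2
    k_on_obs: 0.25
    typical_conc_mM: 5.8
    provenance: {khyd: interpolated, k_on_obs: interpolated, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 99.4, k_off: 9.4, fraction: 1.0,
         provenance: {ires_pct: interpolated, k_off: printed}}
  - name: propanal
    khyd: 0.67
    k_on_obs: 0.30
    typical_conc_mM: 5.8
    provenance: {khyd: interpolated, k_on_obs: derived, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 98.7, k_off: 8.8, fraction: 1.0,
         provenance: {ires_pct: printed, k_off: interpolated}}
  - name: 2-methylpropanal
    khyd: 0.45
    k_on_obs: 0.30
    typical_conc_mM: 6.1
    provenance: {khyd: interpolated, k_on_obs: interpolated, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 98.1, k_off: 7.7, fraction: 1.0,
         provenance: {ires_pct: printed, k_off: interpolated}}
  - name: butanal
    khyd: 0.50
    k_on_obs: 0.31
    typical_conc_mM: 5.8
    provenance: {khyd: interpolated, k_on_obs: derived, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 97.9, k_off: 7.6923, fraction: 1.0,
         provenance: {ires_pct: printed, k_off: derived}}
  - name: benzaldehyde
    khyd: 0.01
    k_on_obs: 0.30
    typical_conc_mM: 5.7
    provenance: {khyd: interpolated, k_on_obs: interpolated, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 97.5, k_off: 7.0, fraction: 1.0,
         provenance: {ires_pct: printed, k_off: interpolated}}
  - name: pentanal
    khyd: 0.45
    k_on_obs: 0.29
    typical_conc_mM: 5.5
    provenance: {khyd: interpolated, k_on_obs: interpolated, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 97.2, k_off: 6.3, fraction: 1.0,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
  - name: phenylacetaldehyde
    khyd: 0.50
    k_on_obs: 0.28
    typical_conc_mM: 5.5
    provenance: {khyd: interpolated, k_on_obs: interpolated, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 96.6, k_off: 6.0, fraction: 1.0,
         provenance: {ires_pct: printed, k_off: interpolated}}
  - name: hexanal
    khyd: 0.45
    k_on_obs: 0.26
    typical_conc_mM: 2.7
    provenance: {khyd: interpolated, k_on_obs: interpolated, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 96.1, k_off: 5.0, fraction: 1.0,
         provenance: {ires_pct: printed, k_off: printed}}
  - name: heptanal
    khyd: 0.42
    k_on_obs: 0.21
    typical_conc_mM: 1.5
    provenance: {khyd: interpolated, k_on_obs: derived, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 95.70, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: printed, k_off: printed}}
      - {label: B, ires_pct: 95.41, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: derived, k_off: printed}}
  - name: octanal
    khyd: 0.42
    k_on_obs: 0.20
    typical_conc_mM: 1.3
    provenance: {khyd: interpolated, k_on_obs: interpolated, typical_conc_mM: printed}
    diastereomers:
      - {label: A, ires_pct: 95.00, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: printed}}
      - {label: B, ires_pct: 94.61, k_off: 5.0, fraction: 0.5,
         provenance: {ires_pct: derived, k_off: printed}}
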