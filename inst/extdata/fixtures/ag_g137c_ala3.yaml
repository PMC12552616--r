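# (AG)6(AG-G137C-Ala3): three asparagine-to-alanine mutations around the 137
# sensing site. Chain-isomer fixture: butanal vs 2-methylpropanal resolved by
# their diastereomer-A levels (published split 0.42%).
pore:
  name: (AG)6(AG-G137C-Ala3)
  open_current_pA: -129.0
  potential_mV: -50.0
  rms_noise_pA: 1.0
  provenance:
    open_current_pA: interpolated
    potential_mV: printed
    rms_noise_pA: derived
analytes:
  - name: butanal
    khyd: 0.50
    k_on_obs: 0.31
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 96.50, k_off: 7.6923, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: derived}}
      - {label: B, ires_pct: 95.80, k_off: 7.6923, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: derived}}
  - name: 2-methylpropanal
    khyd: 0.45
    k_on_obs: 0.30
    provenance: {khyd: interpolated, k_on_obs: interpolated}
    diastereomers:
      - {label: A, ires_pct: 96.92, k_off: 7.7, fraction: 0.5,
         provenance: {ires_pct: derived, k_off: interpolated}}
      - {label: B, ires_pct: 96.10, k_off: 7.7, fraction: 0.5,
         provenance: {ires_pct: interpolated, k_off: interpolated}}
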