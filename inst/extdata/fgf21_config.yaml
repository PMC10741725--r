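# Desk-scale characterization config for FGF 21 using published scalar
# parameters; traces, when wanted, can be added as owls_trace/qcm_trace/
# streaming_potential blocks with CSV paths.
protein:
  name: "FGF 21"
  molar_mass: 19400        # g mol^-1
  density: 1.35            # g cm^-3
  cross_section_area: 17   # nm^2
charge_polynomial:
  c0: 55.9
  c1: 15.9
  ph_range: [4, 8]
conditions:
  temperature: 298.15      # K
  ionic_strength: 0.01     # mol L^-1
  ph: 7.4
qcm_constants:
  hydration: 0.5
calibration:               # serum albumin reference in the same flow cell
  d_h0: 7.5                # nm
  slope0: 5.5e-3           # mg m^-2 s^-1
  flow_rate0: 2.5e-3       # cm^3 s^-1
  concentration0: 5        # mg L^-1
theta: 0.547
seed: 1
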