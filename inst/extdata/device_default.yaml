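# Example device configuration (schema_version 1). All omitted fields fall
# back to the package defaults; lengths accept mm/um suffixes.
schema_version: 1
geometry:
  ecm_channel_width: 2 mm
  ecm_channel_height: 1 mm
  medium_channel_width: 4 mm
  medium_channel_height: 1.2 mm
  channel_length: 10 mm
  medium_reservoir_diameter: 4 mm
  ecm_reservoir_diameter: 1 mm
  n_reservoirs_per_channel: 2
fluid:
  density: 1000
  viscosity: 1.0e-3
  surface_tension: 0.072
  g: 9.81
layers:
- name: COL1
  thickness: 2 mm
  permeability: 1.04e-13
  diffusivity: 6.5e-11
- name: endothelium
  thickness: 10 um
  permeability: 2.46e-16
  diffusivity: 1.0e-11
solutes:
- name: dextran-40k
  molecular_weight: 40
  gel_diffusivity: 6.5e-11
  monolayer_permeability: 1.0e-8
- name: dextran-10k
  molecular_weight: 10
  gel_diffusivity: 1.3e-10
  monolayer_permeability: 2.0e-8
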