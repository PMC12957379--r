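# DG250-Y-Mixer: 100 x 100 um aqueous mixing channel joining a 150 x 150 um
# oil/droplet channel. Units are encoded in the key suffixes.
name: DG250-Y
sections:
- label: A
  length_um: 528
  shape: rectangular
  width_um: 100
  height_um: 100
  flow_scope: aqueous_only
- label: B
  length_um: 285
  shape: rectangular
  width_um: 150
  height_um: 150
  flow_scope: total
- label: C
  length_um: 15400
  shape: circular
  diameter_um: 100
  flow_scope: total
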