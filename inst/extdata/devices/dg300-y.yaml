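# DG300-Y-Mixer: capillary-coupled Y-mixer droplet generator, all mixer
# channels 150 x 150 um. Units are encoded in the key suffixes.
name: DG300-Y
sections:
- label: A            # substrate and crystal streams meet and mix (aqueous flow)
  length_um: 528
  shape: rectangular
  width_um: 150
  height_um: 150
  flow_scope: aqueous_only
- label: B            # droplet formed and accelerated by the oil phase
  length_um: 285
  shape: rectangular
  width_um: 150
  height_um: 150
  flow_scope: total
- label: C            # joining capillary + device to the nozzle orifice
  length_um: 15400
  shape: circular
  diameter_um: 100
  flow_scope: total
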