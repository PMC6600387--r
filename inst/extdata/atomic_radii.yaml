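# Van der Waals radii (Angstrom) for the rolling-probe accessible-surface
# calculation; a fixed published set (Bondi-type values commonly used for
# protein SASA). Editable.
probe_radius: 1.4
radii:
  C: 1.70
  N: 1.55
  O: 1.52
  S: 1.80
  P: 1.80
  H: 1.20
  B: 1.92
  F: 1.47
  Cl: 1.75
  Br: 1.85
  I: 1.98
  Se: 1.90
default: 1.70
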