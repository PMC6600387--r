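# Heteroresidue codes treated as buffer/crystallization agents (not cofactors)
# by the cofactor-proximity filter. Editable.
buffer_agents:
  - GOL
  - EDO
  - PEG
  - PG4
  - MPD
  - DMS
  - ACT
  - FMT
  - CIT
  - TRS
  - EPE
  - MES
  - IMD
  - NO3
  - SO4
  - PO4
  - BME
  - SCN
  - ACY
  - IPA
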