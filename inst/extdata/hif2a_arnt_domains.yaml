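# Domain architecture of the drug-bound HIF-2a:ARNT heterodimer with
# the six interfaces analyzed by the comparative pipeline.
# Chain A = HIF-2a (carries the PAS-B drug pocket), chain B = ARNT.
domains:
  A_bHLH: {chain: A, start: 14, end: 70}
  A_PASA: {chain: A, start: 85, end: 200}
  A_PASB: {chain: A, start: 240, end: 350}
  B_bHLH: {chain: B, start: 90, end: 140}
  B_PASA: {chain: B, start: 160, end: 345}
  B_PASB: {chain: B, start: 356, end: 470}
interfaces:
  - {id: 1, a: A_bHLH, b: B_bHLH}   # bHLH:bHLH
  - {id: 2, a: A_PASA, b: B_PASA}   # PAS-A:PAS-A
  - {id: 3, a: A_PASB, b: B_PASA}   # HIF-2a PAS-B : ARNT PAS-A
  - {id: 4, a: A_PASB, b: B_PASB}   # PAS-B:PAS-B
  - {id: 5, a: A_PASB, b: A_PASA}   # intrachain HIF-2a PAS-B:PAS-A
  - {id: 6, a: A_PASA, b: A_bHLH}   # intrachain HIF-2a PAS-A:bHLH
disordered: []
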