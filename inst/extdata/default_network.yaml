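compartments:
- serum
- liver
- heart
- vastus
- adipose
- CNS
edges:
- - adipose
  - serum
- - CNS
  - serum
- - heart
  - serum
- - liver
  - serum
- - serum
  - vastus
termini:
  liver: synthesis; fatty acid oxidation
  CNS: structural
  heart: fatty acid oxidation
  vastus: fatty acid oxidation
  adipose: storage
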