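stacks:
  AU:
    AU: -0.9
    UA: -1.1
    CG: -2.2
    GC: -2.1
    GU: -0.6
    UG: -1.4
  UA:
    AU: -1.3
    UA: -0.9
    CG: -2.4
    GC: -2.1
    GU: -1.0
    UG: -1.3
  CG:
    AU: -2.1
    UA: -2.1
    CG: -3.3
    GC: -2.4
    GU: -1.4
    UG: -2.1
  GC:
    AU: -2.4
    UA: -2.2
    CG: -3.4
    GC: -3.3
    GU: -1.5
    UG: -2.5
  GU:
    AU: -1.3
    UA: -1.4
    CG: -2.5
    GC: -2.1
    GU: -0.5
    UG: -0.4
  UG:
    AU: -1.0
    UA: -0.6
    CG: -1.5
    GC: -1.4
    GU: -0.6
    UG: -0.5
loops:
  hairpin:
    base: 3.5
    per_nt: 0.3
  internal:
    base: 2.0
    per_nt: 0.35
  bulge:
    base: 3.0
    per_nt: 0.35
  min_hairpin: 3
  max_internal: 30
multiloop:
  a: 3.4
  b: 0.4
  c: 0.1
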