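constructs:
- name: dualmark
  elements:
  - kind: lox
    id: loxP.1
    orientation: forward
    sequence: ATAACTTCGTATAGCATACATTATACGAAGTTAT
  - kind: marker
    id: mO.cassette
    orientation: forward
    marker: mO
  - kind: lox
    id: loxN.1
    orientation: forward
    sequence: ATAACTTCGTATAGTATACCTTATACGAAGTTAT
  - kind: lox
    id: loxP.2
    orientation: forward
    sequence: ATAACTTCGTATAGCATACATTATACGAAGTTAT
  - kind: marker
    id: mC.cassette
    orientation: forward
    marker: mC
  - kind: lox
    id: loxN.2
    orientation: forward
    sequence: ATAACTTCGTATAGTATACCTTATACGAAGTTAT
- name: cre.helper
  elements:
  - kind: cassette
    id: cre.cassette
    orientation: forward
  - kind: marker
    id: mCe.cassette
    orientation: forward
    marker: mCe
- name: dualmark.nested
  elements:
  - kind: lox
    id: loxP.1.a
    orientation: forward
    sequence: ATAACTTCGTATAGCATACATTATACGAAGTTAT
  - kind: marker
    id: mO.cassette.a
    orientation: forward
    marker: mO
  - kind: lox
    id: loxN.1.a
    orientation: forward
    sequence: ATAACTTCGTATAGTATACCTTATACGAAGTTAT
  - kind: lox
    id: loxP.2.a
    orientation: forward
    sequence: ATAACTTCGTATAGCATACATTATACGAAGTTAT
  - kind: marker
    id: mC.cassette.a
    orientation: forward
    marker: mC
  - kind: lox
    id: loxN.2.a
    orientation: forward
    sequence: ATAACTTCGTATAGTATACCTTATACGAAGTTAT
  - kind: backbone
    id: vector.backbone
    orientation: forward
  - kind: lox
    id: loxP.1.b
    orientation: forward
    sequence: ATAACTTCGTATAGCATACATTATACGAAGTTAT
  - kind: marker
    id: mO.cassette.b
    orientation: forward
    marker: mO
  - kind: lox
    id: loxN.1.b
    orientation: forward
    sequence: ATAACTTCGTATAGTATACCTTATACGAAGTTAT
  - kind: lox
    id: loxP.2.b
    orientation: forward
    sequence: ATAACTTCGTATAGCATACATTATACGAAGTTAT
  - kind: marker
    id: mC.cassette.b
    orientation: forward
    marker: mC
  - kind: lox
    id: loxN.2.b
    orientation: forward
    sequence: ATAACTTCGTATAGTATACCTTATACGAAGTTAT
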