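# Swapped-gender control: the same F3-to-F7 procedure with the parental
# genders exchanged at every asymmetric step (the paternal germline now
# carries Cre in the F4 cross). For autosomal loci the step distributions
# are identical to the canonical plan.
name: swapped-gender-f3-f7
params:
  p: "1"
  b: "1/2"
alleles:
  WT: {markers: []}
  DM-full: {markers: [mO, mC], resolved_mO: DM-mO, resolved_mC: DM-mC}
  DM-mO: {markers: [mO]}
  DM-mC: {markers: [mC]}
  HELPER-mCe: {markers: [mCe], cre: true}
loci:
  dm: autosome-1
  helper: autosome-2
lines:
  founder_male: {sex: male, alleles: {dm: [DM-full, WT], helper: [WT, WT]}}
  helper_female: {sex: female, alleles: {dm: [WT, WT], helper: [HELPER-mCe, HELPER-mCe]}}
  wt_female: {sex: female, alleles: {dm: [WT, WT], helper: [WT, WT]}}
  wt_male: {sex: male, alleles: {dm: [WT, WT], helper: [WT, WT]}}
steps:
- id: F3
  mother: {source: helper_female}
  father: {source: founder_male}
- id: F4
  mother: {source: wt_female}
  father: {source: F3, class: mCe+mO+mC, sex: male}
- id: F5
  mother: {source: F4, class: mC, sex: female}
  father: {source: F4, class: mO, sex: male}
- id: F6-S
  mother: {source: wt_female}
  father: {source: F5, class: mO+mC, sex: male}
- id: F6
  mother: {source: F5, class: mO+mC, sex: female}
  father: {source: F5, class: mO+mC, sex: male}
- id: F7-O
  mother: {source: wt_female}
  father: {source: F6, class: mO, sex: male}
- id: F7-C
  mother: {source: wt_female}
  father: {source: F6, class: mC, sex: male}
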