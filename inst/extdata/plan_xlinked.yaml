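# X-linked variant: the dual-marker transgene sits on the X chromosome
# (female XX / male Xy; the y carries no loci), the Cre helper on an
# autosome. This plan is a reconstruction by enumeration: transgenic males
# are hemizygous X-carriers and can never pass the transgene to sons, so
# homozygosity is reached in females first (F6: heterozygous female x
# post-recombination hemizygous male), and the mC-homozygous branch needs
# the extra F6-C step because mC-carrying males first appear among F6 sons.
name: xlinked-f3-f7
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
  dm: X
  helper: autosome-1
lines:
  founder_female: {sex: female, alleles: {dm: [DM-full, WT], helper: [WT, WT]}}
  helper_male: {sex: male, alleles: {dm: [WT], helper: [HELPER-mCe, HELPER-mCe]}}
  wt_female: {sex: female, alleles: {dm: [WT, WT], helper: [WT, WT]}}
  wt_male: {sex: male, alleles: {dm: [WT], helper: [WT, WT]}}
steps:
- id: F3
  mother: {source: founder_female}
  father: {source: helper_male}
- id: F4
  mother: {source: F3, class: mCe+mO+mC, sex: female}
  father: {source: wt_male}
- id: F5
  mother: {source: F4, class: mO, sex: female}
  father: {source: F4, class: mC, sex: male}
- id: F6
  mother: {source: F5, class: mO+mC, sex: female}
  father: {source: F5, class: mO, sex: male}
- id: F6-C
  mother: {source: F5, class: mO+mC, sex: female}
  father: {source: F6, class: mC, sex: male}
- id: F7-O
  mother: {source: F6, class: mO, sex: female}
  father: {source: wt_male}
- id: F7-C
  mother: {source: F6-C, class: mC, sex: female}
  father: {source: wt_male}
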