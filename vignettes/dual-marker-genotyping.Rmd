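---
title: "Direct zygosity genotyping with interweaved Lox pairs: the model behind loxcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct zygosity genotyping with interweaved Lox pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxcross)
```

## The genetic design

A transgene carries two eye-expressed fluorescent markers, mOrange (`mO`)
and mCherry (`mC`), arranged as

LoxP — mO — LoxN — LoxP — mC — LoxN.

Lox sites are 34-bp Cre recognition sequences: two 13-bp arms around an
asymmetric 8-bp spacer. Recombination requires identical spacers, so the
LoxP pair and the LoxN pair are each self-compatible but mutually
incompatible. Because the pairs interweave, any single excision removes one
marker *plus one site of each type*, leaving the surviving marker flanked by
an incompatible LoxP/LoxN pair: no further recombination is possible. Which
marker survives reads out in the eyes under appropriate filter sets, so
zygosity becomes visible phenotype across a four-generation crossing
procedure run against a Cre-expressing helper line (marked `mCe`):

* F3: pre-recombination hemizygous female ((mO-mC)/+) × mCe/mCe helper male
  → half the progeny are double hemizygotes (all three markers).
* F4: double-hemizygous female × wild-type male; Cre acts in her germline,
  so transmitted transgenes arrive resolved → (mO) and (mC)
  post-recombination hemizygotes.
* F5: (mO) female × (mC) male siblings → a quarter of progeny are mO/mC
  *trans* heterozygotes, recognizable by carrying both markers without mCe.
* F6: heterozygote × heterozygote siblings → mO/mO and mC/mC homozygotes,
  each a quarter, recognized by displaying a single marker.
* F6-S, F7-O, F7-C: control test crosses against wild type (0% wild-type
  progeny from a heterozygote; 100% single-marker progeny from a
  homozygote).

`loxcross` implements this as three exact layers — a Cre event engine on
constructs, a Mendelian cross enumerator on genotypes, and a plan runner
over multi-generation schemes — plus a seeded brood simulator and the
statistics used to compare scored broods with theory.

## Exactness

Every probability in the enumeration path is an exact rational number (a
small vectorized numerator/denominator class built into the package;
numerators and denominators live in the exactly-representable double range
and any overflow aborts rather than rounding). Floats appear in exactly two
places: display, and multinomial sampling in the simulator. This is why the
package can assert, rather than approximate, statements like "the F6-S
cross produces 0% wild-type progeny".

## The Cre engine and its one modeling assumption

`stable_products()` explores the full recombination event graph:
states are constructs (canonicalized by element ids and orientations),
events are unordered compatible site pairs (same orientation → excision,
opposite → inversion; excised circles are discarded). At every non-terminal
state each available event is **equally likely** — the uniform-event-choice
model. The design's published theoretical ratios presuppose exactly the
1/2 : 1/2 marker split this model yields; real Cre kinetics (site affinity,
distance effects, induction strength) are not modeled, and no probability
model for competing excisions is given in the source material. Downstream,
the germline parameters make the assumption explicit and overridable:

* `p` ∈ [0, 1]: probability that a transmitted resolvable allele is resolved
  at all (default 1, "complete recombination");
* `b` ∈ [0, 1]: probability that resolution retains mO (default 1/2).

Graphs with inversion cycles that can still reach a terminal state are
solved by exact rational Gaussian elimination of the absorbing-chain
equations; a state set from which no terminal state is reachable (a pure
inversion loop) is reported as non-terminating with the cycling states
listed.

The tandem-duplicated construct bundled as `dualmark.nested` models a
nested insertion (transgene inserted into another vector copy): it has 12
compatible pairs, yet every stable product carries exactly one marker —
the engine reproduces the observation that the procedure "self-corrects"
nested insertions.

## Mendelian layer

Loci are pairwise unlinked (the two transgenes sit on independent
autosomes; no recombination map is needed or modeled). Sex is female XX /
male Xy with a locus-free y — sufficient for the X-linked plan variant and
for the invariant that a transgenic father's sons never inherit his X-borne
transgene. Germline Cre resolution applies independently to each
transmitted resolvable allele, only in parents that actually carry a Cre
allele (one efficiency `p` is used for both sexes; the swapped-gender
control plan is distribution-identical to the canonical plan, which the
tests assert). Phenotype is the dominant union of allele markers — loss of
information by design: a cis (mO-mC) allele and a trans mO/mC pair look
identical, and the plan layer is what distinguishes them.

Selecting parents "by phenotype" in a plan conditions the exact offspring
distribution on class and sex, weighting the genotypes hidden inside a
class by their conditional probabilities. This mirrors what a researcher
picking beetles under a fluorescence stereomicroscope actually does, and it
is what makes the F6-S test cross informative: a cis carrier would give 50%
wild-type progeny, a trans heterozygote gives none.

Viability and fertility enter as genotype predicates. Viability filtering
renormalizes to survivor-conditional ratios (a homozygote-lethal hemizygote
sibling cross shows a 2/3 carrier fraction instead of 3/4 — the basis of
the ≥70% viability rule). Fertility is only consulted by the simulator,
where a sterile pair produces a zero-size brood and the subline is marked
aborted at that step; aborts are data, mirroring the one published subline
whose procedure stopped at the heterozygote cross.

## The simulator and what it does and does not emulate

`generate_score_table()` emulates the published score tables: per subline
and step, a brood is drawn multinomially from the exact offspring
distribution of one concrete parent pair, itself sampled from the realized
counts of the selected class in the source brood. Brood sizes default to
uniform draws from 50–132, the range of the published broods; fixed sizes
are supported. One seed governs a run; each subline derives its own stream
from the seed and its index, so adding sublines never perturbs earlier
ones.

Simulated data share the real tables' shape and sampling noise but not
their biology: there is no egg-to-adult mortality, no overlapping
generations, no scoring error, and parents for different crosses may be
drawn from the same brood slot independently. Passing recovery tests on
simulated data therefore demonstrates that the statistical pipeline is
calibrated against the generative model, not that real broods are free of
the biological deviations the diagnostics look for.

## Statistical choices

* Percentages are reported to one decimal, rounded half away from zero —
  the convention that reproduces the printed per-subline percentages (e.g.
  46/96 → 47.9).
* Across-subline mean and sample SD (n − 1 denominator) are computed over
  the *rounded* per-subline percentages, i.e. over the values a reader of
  the printed table sees; this reproduces 18 of the 19 printed mean ± SD
  cells exactly. The one exception is the both-marker class of the
  heterozygote sibling cross (computed 52.5 ± 4.9 vs printed 52.4 ± 4.9),
  which traces to a printed percentage inconsistent with its own count and
  total (53/103 = 51.5%, printed as 51.4%); the transcription bundled with
  the package keeps the counts, which are internally consistent.
* The published comparison is a one-sample two-tailed Student's t-test of
  the class means against the theoretical ratios; `n` is the number of
  sublines, implemented via `stats::t.test()` and cross-checked against the
  textbook formula. Whether the source tested classes separately or pooled
  is not stated; both are provided. Per class (the package default), two of
  nineteen classes are in fact nominally significant on the published
  counts — a deficit of mO/mO homozygotes (20.7 ± 1.9% vs 25%, p = 0.0027)
  and of the mC post-recombination class (9.5 ± 2.1% vs 12.5%, p = 0.019)
  — so the blanket published conclusion of "no significant differences"
  holds only under the pooled reading (`pooled_deviation_test()`), which is
  non-significant everywhere. No multiple-testing correction is applied by
  default, matching the source; the diagnostics' X-linkage family is the
  one place a Bonferroni correction is built in, because a plan scan runs
  many Fisher tests and a spurious linkage flag is worse than a missed one.
* Per-brood goodness of fit uses the chi-square statistic with an exact
  multinomial p-value when the brood is enumerable (total ≤ 200 and at most
  5 × 10⁵ compositions — with six support classes the composition count is
  astronomically large, so such broods fall back to the asymptotic
  chi-square p). A class observed where theory says zero is reported as a
  model violation, not squeezed into a p-value; on the published counts the
  single violation is exactly the incomplete-recombination subline.
* The germline resolution efficiency estimator is
  p̂ = 1 − both-marker carriers / transgene carriers, with a Clopper–Pearson
  interval (reversed from the binomial interval of the residual fraction).
  On the affected published subline: 7/71, p̂ = 0.901, residual 7.0% of
  progeny.
* Classification rules are inclusive at their thresholds: carrier fraction
  ≤ 60% → single insertion; ≥ 70% → homozygous viable.

## Problem sizes and numerical notes

The exact runner enumerates a seven-step plan in well under a second; the
bundled analysis and recovery studies use 100 seeded six-subline
experiments with broods of 100 (the published design), and law-of-large-
numbers checks pool ≥ 10⁴ simulated progeny (84 sublines × 120). In the
recovery study the per-class t-tests are expected to reject at the nominal
5% rate — the study asserts the aggregate non-significance rate over all
seeds and classes (≈95%), since with ~19 classes per experiment the
probability that *every* test in an experiment is non-significant is only
about 0.95¹⁹ ≈ 0.38 even under a perfectly calibrated null.

Ties in exact probabilities need no care (rationals compare exactly); the
exact multinomial p-value includes outcomes whose probability equals the
observed one up to a 1e-9 relative guard against float log-probability
ties.

## The X-linked plan is a reconstruction

The source describes an X-linked variant of the procedure only in outline.
The bundled `xlinked` plan is reconstructed by enumeration from first
principles: transgenic males are hemizygous X-carriers and never transmit
to sons, so the mO-homozygous females arise in F6 from a heterozygous
female × (mO) male sibling cross, and the mC branch needs one extra step
(`F6-C`) because mC-carrying males first appear among F6 sons. The plan
validates and reaches 100% single-marker control-cross progeny, but it
should be read as *a* correct procedure, not necessarily *the* published
one.

## Known limitations

* Uniform event choice is an assumption, not a measurement; `p` and `b`
  are the only kinetic knobs.
* Somatic/zygotic mosaicism (patchy marker expression in the hybrid
  generation) is a display phenomenon in the source and is not a state in
  the model.
* Fitness is binary (viable/fertile predicates); graded viability and
  sex-specific effects are out of scope.
* Linkage between loci is not modeled; placing two loci on the same
  autosome label still assorts them independently.
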