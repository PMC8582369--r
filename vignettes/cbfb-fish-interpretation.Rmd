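---
title: "Interpreting CBFB break-apart FISH: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting CBFB break-apart FISH: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfbfish)
```

## The diagnostic problem

Acute myeloid leukemia with inv(16)(p13.1q22) or t(16;16)(p13.1;q22) is
defined by the *CBFB-MYH11* fusion, and confirming the *CBFB*
rearrangement decides clinical management. Two assays dominate routine
practice: a break-apart FISH probe flanking *CBFB* (red on the 5′
centromeric side, green on the 3′ telomeric side), and quantitative
RT-PCR for the *CBFB-MYH11* transcript. A normal nucleus shows two fusion
signals (2F); the typical rearranged nucleus shows one red, one green and
one fusion (1R1G1F). Everything else — 1R1F, 1G1F, 1F, extra copies, 5′
gains — is an *atypical* pattern whose interpretation requires karyotype
and RT-PCR context. This package implements that interpretive framework
as a tested rule engine: ISCN karyotype parsing, signal-pattern
classification under validated cutoffs, assay concordance and
confirmation, detection of additional chromosome 16 aberrations (AC16As),
complex-karyotype classification, NGS-detectability prediction, and
cohort tabulation.

## Signal-pattern classification

Each test scores `total_scored` nuclei (200 by default) and records how
many show each configuration. A pattern is reported when its percentage
is **at or above** its validated cutoff — the validated normal ranges are
stated as strict `<`, so the abnormal comparison is `>=`:

| pattern | meaning | cutoff (% nuclei) |
|---|---|---|
| 1R1G1F (`R1G1F1`) | typical rearrangement | 4.2 |
| 1R1F (`R1F1`) | 3′CBFB deletion | 0.4 |
| 1G1F (`G1F1`) | 5′CBFB deletion | 0.4 |
| 1F (`F1`) | loss of one copy | 5 |
| ≥3F (`F3plus`) | extra copies | 5 (not validated; symmetry default) |
| 1G2F (`G1F2`) | 5′ gain | 5 (not validated; symmetry default) |

Category precedence is positive (typical pattern exceeded) over abnormal
over normal, and simultaneous loss and gain subclones are reported as
`gain_plus_loss`. The extra-copy and 5′-gain cutoffs have no published
validation; 5% mirrors the loss cutoff and both are configurable through
`fish_cutoffs()`. A reported 5′-gain subclone of 9% implies the working
cutoff is below 9%, so 5% is compatible with practice, but it remains a
placeholder rather than a validated value.

```{r}
classify_fish(parse_nuc_ish("nuc ish(5'CBFBx2,3'CBFBx1)(5'CBFB con 3'CBFBx1)[104/200]"))
```

Boundary behaviour matters at the 200-cell denominator: 8/200 nuclei is
4.0% (below the 4.2% cutoff, normal) while 9/200 is 4.5% (positive).
Classification is invariant under scaling counts and denominator by a
common factor.

## ISCN parsing

`parse_iscn()` covers the dialect seen in this disease's clinical
reports: modal numbers and ranges (both `43~45` and `43–46` punctuation),
whole-chromosome gains and losses (ASCII hyphen, Unicode minus and en
dash all accepted), markers including `+1~2mar`, `inv`/`t`/`del`/`add`,
compound `der` chromosomes whose embedded events are decomposed,
`idem`/`sl` stemline references, composite `[cp..]` clones, and chimeric
donor clones after `//` (excluded from all counting). It is not a full
ISCN 2020 grammar — `ider`, `dic`, `hsr`, fragile sites and uniparental
notation are out of scope.

Published tables contain typography that a strict parser must reject: a
cell count printed `[1 2]`, a clone with a missing bracketed count, a
damaged `nuc ish` bracket (`l200}`), a sub-band printed `p13,1`. The
parsers accept bracket whitespace always; the other artifacts are
recovered only in lenient mode (`pipeline_config(lenient = TRUE)`, the
default for table processing), while strict mode raises an error naming
the offending token and offset and `call_cases()` turns such failures
into per-row error records.

Counting follows top-level tokens: a compound derivative such as
`der(16)inv(16)(p13.1q22)del(16)(q22q34)` is **one** abnormality. This is
a documented choice, not an externally fixed rule — nothing in routine
reporting states whether such a derivative counts as one or two events —
and it matches the observed practice of not calling such cases complex.
Constitutional polymorphisms (`inv(9)(p12q13)` by default) are excluded
from counts; the exclusion list is a `counting_policy()` option, as is
whether `+mar` can satisfy the structural requirement of the complex
rule (default no, since marker origin is unknown).

Band matching is prefix-based at sub-band resolution: a printed `p13`
matches `p13.1` and `p13.3`, but `q13` never matches `q22`. The
CBFB-compatible "primary" signature is an inversion of 16 with
breakpoints in the p13 family and at q22, `t(16;16)(p13;q22)`, or any
translocation with a 16q22 breakpoint. Everything else touching
chromosome 16 — embedded deletions inside derivatives, `add(16)`,
`del(16)`, non-q22 translocations, whole-chromosome 16 gains/losses — is
an additional chromosome 16 aberration. A derivative none of whose
embedded events match the signature (e.g. an inversion at
`p13.3q13`, a different band level) is reported whole as one AC16A.

## Integration rules

**Confirmation.** A case is confirmed when FISH is positive or RT-PCR
detects the transcript at a level at/above the FISH-equivalence
threshold of 4.2% (a detected screen result with no ratio counts as
detected). The same threshold drives concordance: RT-PCR is so much more
sensitive than FISH (10⁻⁴–10⁻⁵ vs 4.2%) that a PCR positive below 4.2%
is deliberately treated as concordant with a negative FISH.

**Concordance.** FISH-positive/PCR-detected is concordant;
FISH-positive/PCR-negative and FISH-*normal*/PCR-positive are the two
discordance classes. An *abnormal* (atypical) FISH with a positive PCR
is not a discordance — both assays flag the gene — and instead receives a
cause annotation. This is a deliberate reading: the alternative (treating
atypical-FISH/PCR-positive as discordant) would contradict the
case-accounting this framework is built to reproduce, in which exactly
the typical-pattern mismatches are "discordant" and the 3′-deletion
cases are "atypical".

**Cause annotation** is a decision tree over FISH, PCR and karyotype:
FISH-pos/PCR-neg with `t(16q22;v)` → novel partner gene; with
inv(16)/t(16;16) → rare/novel transcript variant; FISH-normal/PCR-pos →
cryptic insertion; 3′-deletion pattern with PCR-pos → unbalanced
*CBFB-MYH11* rearrangement; 3′/5′-deletion with PCR-neg → a chromosome 16
event in which a non-MYH11 *CBFB* rearrangement cannot be excluded. When
the karyotype is missing or failed, the FISH-pos/PCR-neg branches cannot
distinguish their causes and return `none`. Evidence flags (dual-fusion
FISH, chromosome 16 painting, aCGH notes) ride along as advisory
annotations and never change a call: in every packaged case FISH and
RT-PCR already determine the verdict, which mirrors how those assays are
used confirmatorily.

**Balance and AC16As.** A confirmed case whose only exceeded pattern is
1R1G1F is a *balanced* rearrangement; any other exceeded pattern makes it
*unbalanced*, implying simultaneous gain or loss of CBFB material. An
AC16A is *apparent* when the karyotype shows it, *cryptic* when only the
unbalanced FISH pattern reveals it (requiring a confirmed
rearrangement). A confirmed case with no exceeded pattern at all (the
insertion scenario) has balance `not_applicable`: FISH saw nothing, so
the balance dichotomy does not apply, and such a case is not counted as
a cryptic AC16A. The interaction of a 5′-gain pattern with cryptic AC16A
counting is unresolved in practice; this package treats any non-typical
exceeded pattern as unbalanced.

**Complex karyotype.** Standard rule: ≥3 abnormalities with ≥1
structural, evaluated per clone with the case flag the OR over clones
(the clinical convention — a complex subclone makes a complex case).
Re-defined rule: because the CBFB-rearranging event is usually a simple
balanced aberration, it is treated as numerical-equivalent, so a clone
needs ≥3 events with ≥1 structural among the *non-primary* events. The
source formulation ("at least one structural ACA and another numerical
ACA") is ambiguous about whether the third event must be numerical; the
default here reads it permissively (primary + structural ACA + any other
ACA), and `redefined_strict = TRUE` demands a numerical ACA. Re-defined
complexity implies standard complexity on the same clone by
construction.

**NGS detectability** follows the published analytical parameters of the
three sequencing approaches (CNAs > 5 Mb and SVs > 100 kb for WGS;
fusion-transcript detection for WTS and partner-agnostic targeted
RNA-Seq): the fusion itself is detectable by all three in every
confirmed case; the underlying structural configuration only by WGS;
apparent AC16As by WGS but cryptic AC16As by none; other ACAs by WGS
only as a function of clone size (uncertain).

## The synthetic cohort generator

`simulate_cohort()` exists so every pipeline stage can be validated in a
closed loop without patient data. Its defaults *are* the cohort
composition the analysis assumes: category prevalences 262/1234/34/84/2/
11/1/1 over 1629; karyotype mix 240:17:3:3 (inv(16) : t(16;16) :
t(16q22;v) : cryptic-normal) among rearranged cases; trisomy 22/8 rates
21%/20.2%; discordance rates 4/262 (FISH-pos/PCR-neg), 1/645
(FISH-normal/PCR-pos) and 8/11 (3′-deletion PCR-positive), with 5/8 of
the latter showing the deletion in the karyotype. Nucleus counts are
drawn multinomially with the true pattern at a fraction uniform on
10–95% (each component of a gain+loss mixture on 10–45% so the two
subclones fit in one test). No per-case distribution of abnormal-nucleus
fractions is published; 10–95% spans the observed worked examples
(20/200 to 200/200) and is a package choice.

Background noise defaults to one quarter of each pattern's cutoff —
except the two deletion patterns, whose 0.4% cutoff is *below the
one-nucleus resolution* of a 200-cell score: any single background
nucleus would cross the reporting threshold, so their background rate is
0. At these settings false calls are only possible at cutoff boundaries
and category recovery at n = 2000 exceeds 99%; with noise switched off
entirely, recovery is exact by construction. Karyotype synthesis uses a
fixed template library modelled on observed clone structures rather than
a free grammar sampler, guaranteeing parseability and clinical
plausibility; every emitted string round-trips through `parse_iscn()`.

What the generator does **not** emulate: clonal evolution (subclones are
at most a stem plus a normal sideline), probe physics, inter-observer
scoring variation, per-patient repeat testing, and the long tail of rare
karyotypes. Passing closed-loop tests therefore demonstrates the
correctness of the rule engine on well-formed inputs, not the behaviour
of the assays on real specimens.

## Numerical and formatting choices

Percentages are rounded half-away-from-zero (`proportion()`), the
convention that reproduces the published summary arithmetic
(16.1, 8.2, 98.5, 73, 53, 20.2, 6.6); base R's `round()` rounds half to
even and does not. A small number of printed percentages (91.2, 31.2,
75.7) are internally inconsistent with their own numerators and
denominators under any half-rounding rule and are treated as source
artifacts, not targets. The 2×2 comparisons use the uncorrected Pearson
chi-square: the continuity-corrected variant fails to reproduce the
published p = 0.127 for the ACA comparison (7/9 vs 132/254). For the
complex-karyotype comparison (6/9 vs 75/254) the uncorrected statistic
gives p = 0.0177 where 0.017 is printed — a truncation or a different
exact procedure; that value is held to the qualitative claim (p < 0.05)
only. JSON reports fix key order and float precision so identical inputs
produce byte-identical output.

## Problem sizes used in the test suite

The packaged checks run the 17-case worked example exactly, simulation
recovery at n = 2000 (one seeded cohort), closed-loop zero-noise
recovery at n = 400–500, and expectation checks over 2000 multinomial
draws. These sizes give stable stochastic margins (the recovery
criterion has ≥ 1% headroom at n = 2000) while keeping the default test
run fast.

## Known limitations

* The ISCN grammar is deliberately partial (the constructs above plus
  whole-chromosome events); unknown tokens are parse errors, not silent
  skips.
* Patient-level aggregation assumes the case table marks repeat tests
  with a shared `patient_id`; without it every row is a patient.
* The 5′-gain and extra-copy cutoffs are unvalidated defaults.
* Cause annotation without a karyotype cannot separate novel-partner
  from rare-variant discordances.
* aCGH evidence is carried as free-text notes only; copy-number calling
  is out of scope.
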