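---
title: "Co-linear assembly and retrobiosynthesis of trans-AT PKS-NRPS clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-linear assembly and retrobiosynthesis of trans-AT PKS-NRPS clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palcolin)
```

## The model

palcolin treats a hybrid *trans*-AT PKS-NRPS gene cluster as a small program
and its product as that program's output.  The program text is the ordered
list of catalytic domains along the core biosynthetic genes; the interpreter
is the co-linearity assumption: one chain extension per elongation module,
with the module's accessory domains fixing the chemistry of the unit.

Three assumptions are load-bearing and worth stating explicitly:

* **Strict co-linearity.** Modules act once, in gene order.  Iteratively
  acting ("stuttering") modules, module skipping, and *trans*-complementation
  of whole modules are not modelled.
* **Site-of-action annotations are data.** Which module a *trans*-acting ER
  or the HCS cassette services cannot be read from domain order; these sites
  are carried as explicit `site_annotations` in the architecture fixture
  (modules 8/12 and module 6 in the pal BGC 4 fixture) rather than inferred.
* **Stereochemistry is carried as the assembly-line L/D labels** attached to
  ketoreductase types, not converted to CIP R/S descriptors (that conversion
  depends on substituent priorities the feature table does not track).

## Module segmentation

The flat domain stream of the non-*trans*-acting genes is cut at every KS
and every full condensation (C) domain; a trailing truncated condensation
domain opens the termination module; whatever precedes the first boundary is
the loading module.  One refinement handles starter loading: when the
pre-boundary prefix contains a β-branch-accepting carrier (`ACP_beta`, the
GXDS starter dock) *and* the first KS chunk is chemically silent (KS plus
carriers only), that KS receives the starter unit rather than extending the
chain and is absorbed into the loading module.  This is what places KS1 and
its trailing carrier protein inside module 1 of the pal clusters, giving the
14-module segmentation, while a generic stream such as
`[ACP, KS, KR, ACP]` still splits into a loading module and one elongation
module.  The rule is deterministic and purely structural; no chemistry is
consulted.

Module boundaries are never stored in fixtures — they are always recomputed —
so the segmentation rule itself is regression-tested against the shipped
clusters and against a brute-force boundary scan on simulated streams.

## Backbone numbering

Numbering starts at the ester carbonyl (C1) laid down by the final
elongation and increases toward the starter: elongation *e* of *E*
contributes carbons `2(E−e)+1` and `2(E−e)+2`, and writes its β-state onto
`β(e) = 2(E−e)+3`, the carbonyl carbon donated by the upstream unit (for
*e* = 1, by the amino acid).  Amino-acid backbone carbons follow C(2E) in
chain order; starter carbons sit beyond the amide nitrogen and are excluded
from the numbered backbone (which is why the pal BGC 4 product has a
24-carbon backbone: 22 polyketide + 2 glycine carbons).  Substituent methyls
(the β-branch methyl and SAM-derived α-methyls) are numbered after the
backbone in order of increasing host carbon, reproducing C-25/C-26/C-27 of
palmerolide A.  Olefins are named by their lower carbon (Δn = bond Cn–Cn+1).
Elongation modules that occur *before* the NRPS module extend the starter
instead (the extra module of pal BGCs 1/3); their carbons are counted in the
molecular total but not numbered.

## Per-module chemistry and its tunable parameters

| domain set | β-state | parameter |
|---|---|---|
| KS only | ketone | — |
| + KR (A-type) | L-hydroxyl | — |
| + KR (B-type) | D-hydroxyl | — |
| + KR (C-type / inactive) | ketone | — |
| + KR + DH | olefin (*cis* if A, *trans* if B) | `geometry_override` per module |
| + DH, no KR | olefin (*trans*) | `permissive_dh`, default `TRUE` |
| + *trans*-ER annotation | saturated | fixture `site_annotations` |
| + shift-flagged DH | olefin moved to (β, β+1) | `shift` flag on the domain |
| + cMT / + LLM | α-methyl / α-hydroxyl | — |
| ketone + `hcs_site` | β-methyl branch | in-line ECH ⇒ internal olefin |

`permissive_dh = TRUE` is the default because the shipped pal fixtures need
the KR-less DH of module 3 to dehydrate (there are characterised clusters on
both sides of this question; the strict behaviour is one flag away and the
validator flags every module that depends on the permissive rule).  The DHt
domain kind is treated as chemically inactive — in module 5 it would
otherwise destroy the C-19 macrolactonisation hydroxyl; whether such domains
instead perform the β,γ-olefin shifts is genuinely open, so the shift is
attached to modules 3/4 via a `shift` flag and both hypotheses are
representable in fixtures.  The C-10 α-hydroxyl is produced by the module-9
LLM in the shipped fixture; the alternative hydroxymalonate/trans-hydroxylase
route is representable as a `hydroxylase` tailoring record.

Motif classification parameters: the condensation truncation threshold is
250 residues (midpoint between the 133-residue termination domain and the
~450-residue canonical length); degenerate HHXXDDG matching tolerates two
mismatches outside the catalytic second histidine, which must match; KR/AT
active-site windows default to the whole domain sequence because the motifs
are defined residue-wise, not coordinate-wise — curated profiles can pass
explicit windows to tighten behaviour.  When both the LDD motif and a
tryptophan are present, LDD wins (B-type is defined positively by LDD).

Macrolactonisation under `nucleophile = "auto"` picks the hydroxyl-bearing
backbone carbon giving the largest ring of at least 12 atoms (ring size =
n backbone carbons + the ester oxygen).  This selects C-19 for the pal BGC 4
product without hard-coding the site, and correctly leaves the five-module
pal BGC 2 product linear (its hydroxyls at C-7/C-10 cannot reach the
minimum).  Tailoring targets are consumed: decorating the same hydroxyl
twice is an error, which makes tailoring application non-idempotent by
design.  A `"default"` carbamoyl-transfer target resolves to the β-hydroxyl
of the LLM-containing module (C-11 in pal BGC 4) and falls back to the
highest-numbered free hydroxyl when that position is off the numbered
backbone (C-10 for pal BGC 2).

## Retrobiosynthesis and the congruence score

`retro_predict()` inverts the table above position by position.  Inverse
rules emit capability *requirements*, not exact domain strings, and
degeneracies are kept explicit as requirement alternatives:

* a ketone admits either a KR-less module or one with a C-type/inactive KR;
* a *trans* olefin admits B-type-KR + DH or a permissive KR-less DH;
* a β-state on the starter side of the numbered backbone (the first
  elongation of an amino-acid-free cluster) is unrecoverable and matches any
  module content, including an HCS cassette acting there;
* an α-hydroxyl admits an in-module LLM or a *trans*-acting hydroxylase.

`congruence_score()` matches requirements against module capabilities
(choosing, per position, the alternative minimising disagreement) plus
cluster-level requirements (starter, NRPS glycine, HCS cassette, CT,
termination), and reports `matched / (matched + missing + extra)`.
Congruence between a retrobiosynthetic prediction and a cluster is otherwise
a qualitative notion; this Jaccard-style statistic is the package's own
construction and is labelled as such in all output.  Sulfation is treated as genome-encoded rather than cluster-encoded,
so a sulfate requirement is matched with a provenance note instead of
penalising the cluster.  The test suite asserts score 1.0 on
forward-assembled products of 100+ simulated clusters against their own
generating architectures — i.e. the inverse rules are exact up to the
documented degeneracies — and monotone non-increase as capabilities are
deleted.

## Variant mapping

The family mapping enumerates variant products per cluster along the three
diversity mechanisms, counted as *classes* toward `variant_budget`
(default 2): `trans_site` (carbamoyl-transfer target swap C-11↔C-7 with
sulfation of the freed hydroxyl, hydroxylase site swap C-10↔C-8 with
repositioning of the clashing olefin), `starter` (swap to the terminal-olefin
isomer 3-methyl-3-butenoic acid), `core_geometry` (a *cis* override on the
shift-flagged KR+DH module), and `amide_hydrolysis`.  Class counting is what
makes the budget of 2 sufficient for every shipped assignment: the H-type
analogue needs three individual swaps but only two classes.  Amide
hydrolysis is enumerated only for clusters that lack a starter (no loading
module): it is speculative, is flagged as such in output, and restricting it
this way prevents every 24-carbon product from trivially matching the
hydrolysed 22-carbon analogue.  Analogue definitions are data
(`inst/extdata/analogues.yaml`) in the same feature vocabulary the assembler
emits, so the mapping is a pure set-membership check over computed
structures.

## Phylogenetics

Distances use the equal-rates (Jukes-Cantor) correction,
`d = −((k−1)/k)·log(1 − p·k/(k−1))`, with `k = 4` for nucleotide input and
the 20-letter generalisation for protein input, chosen by alphabet
detection; gap/ambiguous columns are pairwise-deleted; `p ≥ (k−1)/k` is a
saturation error, not a clamp.  Tree building delegates to the standard
neighbour-joining implementation in `ape` (Q-matrix tie-breaking is
therefore ape's); negative branch lengths are clamped to zero with a
warning, never silently.  Bootstrap support resamples columns with
replacement (default 100 replicates, per the study design this models),
rebuilds the distance + NJ tree, and scores each internal bipartition of the
full-data tree; replicates whose resampled distances saturate are skipped
and count against support, which is the conservative choice.  Clade
classification assigns the label of the smallest non-trivial bipartition
side enclosing the query whose other members carry one label, with the
bootstrap percentage of that bipartition as support; ties across labels and
label-mixed minimal groups return `unclassified` with diagnostics.  A query
identical to a reference is conclusive and short-circuits to that
reference's label with support 100, rather than leaving a zero-length branch
to tie-breaking.  Alignment construction is out of scope: input is
pre-aligned, and queries must match the reference column count.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of `(cfg, seed)`; each derives a private
RNG stream from the seed, so adding a generator never perturbs existing
draws, and the caller's RNG state is restored.

`simulate_architecture()` draws from the structural grammar of the modelled
clusters — loading module, optional NRPS glycine module (probability 0.5),
3–8 elongation modules, truncated-condensation termination, plus a
*trans*-acting HCS cassette when any module is branch-flagged — with domain
probabilities P(KR) = 0.7, P(DH|KR) = 0.5, P(cMT) = 0.2, P(trans-ER) = 0.1,
P(hcs site) = 0.1, P(LLM) = 0.1, P(shift|DH) = 0.1 and KR types A/B/C at
0.45/0.45/0.10.  These defaults are fixed study conditions chosen to
exercise every rule with realistic frequency (reductive loops common,
branching and shifts rare), not dials.  Ground truth comes from
`naive_product()`, a deliberately naive straight-line interpreter that
shares no helpers with the assembly engine; the suite asserts equality of
the two routes on 500 draws.  `simulate_proteins()` embeds one verified
motif instance per sequence at a known offset and rejection-samples decoys
until motif-free, so scanner precision/recall against labels is meaningful.
`simulate_alignment()` evolves i.i.d. columns under the same equal-rates
substitution process the distance correction assumes.

What passing these tests does *not* show about real data: real clusters
violate strict co-linearity, real domain annotations are noisy upstream of
this package (annotation itself — antiSMASH, BLASTP, profile HMMs — is out
of scope), real carrier-protein alignments are longer and gappier than the
simulated ones, and the motif grammar cannot capture profile-level signal.
The generators validate the interpreter's internal consistency, not the
biology of any particular cluster.

## Problem sizes and numerical choices

The default test run uses 500 simulated architectures for the dual-route
oracle, 100 for the retro round trip, 30 random additive matrices (4–8
taxa) for NJ exactness, 100 five-taxon alignments of 300 columns for
topology recovery (asserting ≥95% recovery), and 1000 labelled protein
sequences for scanner precision/recall — sizes at which every property is
stable run-to-run under the fixed seeds while the whole suite stays fast.
Floating-point comparisons use exact equality only where the computation is
exact (counts, positions, set membership) and closed-form tolerances of
1e-12 for the distance correction.

## Known limitations

* Strict co-linearity; no iterative modules, no module skipping.
* KS substrate-specificity (clade-based) prediction is limited to the
  carrier/KS clade classifier given user-supplied references; no
  substrate-specificity model is shipped.
* SMILES output is constitutionally faithful (heavy atoms, ring, branch,
  decorations) but emits only L/D-derived tetrahedral stereo under a fixed
  arbitrary mapping and no olefin geometry.
* The congruence statistic has no calibration against a null distribution;
  it is a descriptive score for ranking candidate clusters.
* Nucleotide-level analysis (SNPs between cluster copies, operon length,
  coverage) requires the deposited sequences and is out of scope.
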