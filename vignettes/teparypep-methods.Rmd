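---
title: "Methods: in silico proteolysis, peptide screening, and protein-quality indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico proteolysis, peptide screening, and protein-quality indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teparypep)
```

teparypep models the desk half of a food-protein bioactivity study: given a
protein sequence, which small peptides would gastrointestinal digestion
release, which of them are worth pursuing as receptor ligands given external
docking scores, and how good is the parent material as dietary protein? The
bundled study system is the seed lectin of tepary bean (*Phaseolus
acutifolius*), digested in silico and screened against the antiadipogenic
binding region of the nuclear receptor PPAR-γ, but every stage accepts
arbitrary inputs of the same shape.

## The cleavage model

Protease specificity is expressed in the P1/P1′ formalism. A rule is a set
of P1 residues (the bond after such a residue is scissile) and an optional
set of P1′ exclusions (residues that, sitting immediately C-terminal to the
bond, block that rule's cut). A panel is a list of rules that act
*concertedly*: one exhaustive pass cuts at the union of all rules' sites.
There is no partial or missed cleavage, no kinetics, and no pH dependence —
the model is the idealised end point of digestion, which is also what makes
it exactly reproducible.

Fragments are maximal substrings between consecutive cut sites. Two
invariants define correctness and are enforced by property tests:

* **Partition** — fragment coordinates are contiguous half-open intervals
  covering the parent, and their concatenation reproduces it exactly.
* **Completeness** — no fragment contains a cut-eligible bond before its
  last residue.

Coordinates are 0-based and half-open (`start` inclusive, `end` exclusive;
cut position *b* is the bond between residues *b* and *b+1* in 1-based
sequence numbering). A P1 residue at the C-terminus produces no cut, so
empty fragments cannot occur. Duplicate peptides are first-class: the digest
is a multiset, and the bundled lectin releases both AF and SIK twice.

### The calibrated gastrointestinal panel

`gi_panel()` ships pepsin, trypsin and chymotrypsin with the union cut-after
set {F, L, W, Y, K, R, N, H} and no P1′ exclusions, attributed as pepsin
{F, L}, trypsin {K, R}, chymotrypsin {F, Y, W, N, H}. Public protease
databases do not agree on a single specificity table for these enzymes, so
the panel was calibrated against the lectin's published digest inventory:
this union set — and, among simple P1 sets, only this one — yields exactly
88 fragments in length classes 30 (free amino acids) / 45 (2–5 residues) /
13 (longer), and exactly the published 45-peptide multiset. The presence of
fragments such as PK and PEW shows that K|P and L|P bonds are cut, ruling
out the proline exclusions some trypsin tables carry. Only the union is
fixed by the data; which enzyme contributes the N and H cuts is a
convention. Other specificity tables (e.g. proline-blocking trypsin) can be
configured through `cleavage_rule()` / `enzyme_panel()` or a YAML config
read by `read_panel()`.

### Length classes and absorbability

Intestinal absorption of digestion products is length-structured: free
amino acids use amino-acid transporters, di- and tripeptides the
PepT1/PepT2 carriers, 4–5-mers the SOPT1/SOPT2 system, and longer peptides
have no dedicated carrier. `classify_lengths()` summarises a digest into
these classes; `transporter_class()` annotates individual peptides. The 2–5
window is therefore the default `fragment_multiset()` selection passed to
screening. Percentages are rounded half away from zero to 2 decimals; for
the lectin this gives 34.09 / 51.14 / 14.77 (45/88 is 51.136…, so a
published 51.13 for the same digest is a truncation artefact, not a
different count).

## The screening stage

Affinity scores (blind peptide–protein docking, kcal/mol, more negative =
stronger) and binding poses are produced by external docking programs and
are **ingested as data, never recomputed**. The package's contribution is
the triage logic:

1. **High affinity** — score strictly below −120 kcal/mol (no ingested
   score equals the threshold, so strictness is observationally safe but
   documented). On the bundled table this keeps 7 of 45 peptides.
2. **Binding-site contact** — the docking pose touches at least one residue
   of the screened site. The bundled site is the antiadipogenic region of
   PPAR-γ: Phe264, His266, Ile281, Cys285, Arg288, Ser289, Met348, His449.
   Residue identifiers compare case-insensitively as (3-letter code,
   number); chains are not modeled because the ingested tables print none.
3. **Control-referenced energy** — binding energy at least as negative as
   the weakest control ligand. The bundled controls are the PPAR-γ ligands
   GW9662 (−7.98 kcal/mol) and G3335 (−5.64 kcal/mol), so the default
   cutoff is −5.64.

The conjunction of the three clauses is the candidate rule of
`rank_candidates()`. It is a *reconstruction*: selecting "taking the
controls' energies and binding sites as reference" admits several
formalisations, and this is the simplest one that keeps TTPW (−5.96,
Cys285 contact) and ITY (−5.91, Cys285 contact) while excluding TSF
(−4.68) and ATSF (−3.89) on energy and PEW/PSQK/VSVGF on site contact.
`energy_cutoff`, `threshold` and `sites` are all configurable. Peptides are
further annotated with hydrophobic fraction (set {V, L, I, A, F, W, M, P},
relevant to activity at lipid-regulating receptors) and a proline flag
(proline-containing peptides resist intracellular peptidases).

## Protein-quality indices

* **Chemical score.** For each item of the FAO reference pattern (3 years
  and older: His 1.6, Thr 2.5, Met+Cys 2.3, Val 4.0, Phe+Tyr 4.1, Ile 3.0,
  Leu 6.1, Trp 0.66, Lys 4.8 g/100 g protein), the ratio
  100 · content/requirement is computed; the score is the minimum ratio
  rounded half away from zero to an integer, and the minimising item is the
  limiting amino acid (ties broken by pattern order). The sulfur and
  aromatic groups are atomic items — they are scored as printed, never
  split into residues. Amino acids without a requirement (Asp, Glu, Ser,
  Gly, Arg, Ala) do not participate. Half-away-from-zero rounding is what
  reproduces the published 72/87/82 family of scores (86.52 → 87).
* **Atwater energy.** 4 · protein + 4 · carbohydrate + 9 · fat, kcal/100 g,
  2 decimals. Dietary fiber is deliberately unassigned — this convention
  reproduces all four bundled energies to the cent.
* **IVPD.** 100 · (protein at the end of the duodenal phase)/(protein
  before digestion). Values above 100 are physically suspicious and warn
  but are not clamped.
* **C-PER.** Calculated protein efficiency ratio. The classical approach
  regresses rat-assay PER on essential-amino-acid scores and enzymatic
  digestibility, but the published regression coefficients vary between
  method revisions and none is printed with the bundled tables. Rather than
  guess coefficients, the package uses a transparent reconstruction,
  `cper = 2.5 · (EAAI/100) · (IVPD/90)`, where EAAI is the
  essential-amino-acid index (geometric mean of per-item ratios, each
  capped at 100), 2.5 is the PER of the casein reference protein, and 90 a
  typical in vitro casein digestibility. The prediction is linear — hence
  monotone — in IVPD, and the equation travels with the result as an
  attribute. C-PER should be read as a comparative index with a few tenths
  of uncertainty, and the test suite *reports* its deviation from the
  bundled reference values rather than asserting it.

The bundled composition table prints one amino acid (Thr) twice with
identical values; the loader deduplicates identical repeated rows and
errors on conflicting ones. One bundled sample (RPC) prints a lysine
content whose ratio (39) lies far below that sample's published score of 82
(which matches its Met+Cys ratio exactly); the min-rule therefore reports
Lys/39 for that sample, and the published 82 is recovered only as the
per-item sulfur score via `score_for_item()`. This looks like a
transcription slip in the source table and is surfaced rather than patched.

## Synthetic data and what the tests show

All generators are pure functions of an explicit seed (the caller's RNG
state is saved and restored) and plant a known ground truth:

* `random_protein()` — i.i.d. residues from configurable frequencies
  (uniform by default). Real proteins have compositional bias,
  autocorrelation and domain structure; none of that matters to a
  position-local cleavage rule, which is exactly why i.i.d. sequences are a
  fair stress test for the engine.
* `oracle_digest()` — an independent per-bond re-statement of the cleavage
  semantics, kept deliberately naive (an explicit loop) so it shares no
  code with the vectorised engine. Engine–oracle equivalence is asserted on
  1,000 seeded random 60-mers.
* `synthetic_profile()` — plants a limiting amino acid at an exact target
  ratio with all other ratios at least 10 points higher; recovery must be
  100%.
* `synthetic_affinity()` — plants an exact count of sub-threshold scores;
  peptides are drawn from real digests of random proteins so lengths sit in
  the realistic 2–5 window.
* `synthetic_docking()` — plants exactly one record passing all three
  candidate clauses; every other record fails exactly one clause.

Passing these tests shows the machinery is correct under its stated
semantics. It does not validate the biology: docking scores are configured
draws, not physics, and i.i.d. sequences are not evolved proteins.

Problem sizes used by the default suite — 1,000 random 60-mers for the
engine–oracle property, 200 planted profiles, 100 round-tripped FASTA
records — keep the whole run under a minute while giving the properties
enough room to fail loudly.

## Numerical and degenerate-input choices

* Rounding is half away from zero everywhere a table-facing value is
  produced (scores to integers, percentages to 2 decimals); `base::round`'s
  half-to-even would disagree on exact halves.
* The high-affinity threshold is a strict inequality.
* An empty panel is valid and releases the whole sequence as one fragment;
  an empty digest cannot be classified (error), and an empty FASTA or
  affinity table is a validation error, not an empty result.
* Sequences are upcased before validation; the alphabet is strictly the 20
  canonical letters, and ambiguity codes are rejected rather than coerced
  so cleavage semantics stay unambiguous.
* The bundled lectin is the recombinant construct as deposited (leading
  EAEA remnant and C-terminal His tag included): that is the sequence the
  bundled inventory was generated from, and digesting the mature chain
  instead would change the fragment counts.

## Known limitations

* Exhaustive digestion is an idealisation; no missed cleavages, enzyme
  ratios, or time courses.
* The candidate rule is a reconstruction constrained by seven docked
  peptides and two controls; with richer docking data a probabilistic or
  pose-aware triage would be preferable.
* C-PER is a reconstructed index (see above), not a drop-in replacement for
  an official collaborative-study regression.
* No structure files are parsed; binding-site residues are identifiers, not
  coordinates, so "contact" is whatever the upstream docking report says
  it is.
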