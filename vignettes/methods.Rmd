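---
title: "Methods: distance-criterion bond detection and comparative proteome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-criterion bond detection and comparative proteome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermbond)
```

## Scope and model

`thermbond` re-implements, as a library, the analysis style used in
proteome-scale surveys of protein temperature adaptation: count hydrogen
bonds and salt bridges in hundreds of per-protein structure models for two
species, normalize per amino acid, and ask where the two species differ —
in the whole proteome, in ortholog pairs, or only in the upper tail of the
bond-rate distribution. Structure models and their quality scores (QMEAN)
are *inputs*: homology modeling itself, and any retrieval from sequence or
annotation databases, are out of scope.

## Detection criteria and their assumptions

Both detectors are deliberately distance-only, mirroring the widely used
web-tool criteria they replace:

* **Hydrogen bond**: donor heavy atom and acceptor heavy atom within
  **3.5 Å** (inclusive); when the model contains explicit hydrogens, a
  donor-attached hydrogen (within 1.2 Å of the donor) must additionally be
  within **2.5 Å** of the acceptor. No angle criterion. Since
  crystallography-derived templates usually lack hydrogens, the default
  policy (`auto`) applies the hydrogen rule only when hydrogens are
  present; `never`/`always` are available.
* **Salt bridge**: Asp/Glu side-chain carboxyl oxygen (OD1/OD2, OE1/OE2)
  within **4.0 Å** (inclusive) of a side-chain nitrogen of Arg
  (NH1/NH2/NE), Lys (NZ) or His (ND1/NE2). His inclusion is switchable
  (`include_his`), because protonation is not modeled.

Distance-only criteria over-count relative to energetic or
angle-dependent definitions (DSSP-style); that is intentional — the
comparisons are between two species quantified under the *same* rule, so
a consistent over-count cancels.

Decisions the criteria themselves leave open, and what we chose:

* **Boundary**: cutoffs are inclusive ("maximum distance"), with a 1e-9 Å
  epsilon so pairs constructed exactly at the cutoff at PDB 3-decimal
  precision are detected deterministically.
* **Covalent exclusion**: intra-residue pairs, plus backbone N(i)→O(i−1) —
  the only inter-residue donor/acceptor pair within two covalent bonds of
  a polypeptide (the peptide-bond geometry sits near 2.25 Å and would
  otherwise register in every protein). Adjacency requires both file-order
  and author-numbering (resseq) adjacency, so numbering gaps (chain
  breaks) are not mistaken for peptide bonds. No further sequence
  separation is imposed: i,i+2 contacts count.
* **Counting unit**: hydrogen bonds are counted per heavy-atom pair (a
  donor contacting two acceptors yields two bonds); each unordered atom
  pair is reported once, with a canonical orientation, so bifunctional
  atoms (His ND1/NE2, hydroxyls) cannot double-count. Salt bridges default
  to one event per (acidic residue, basic residue) pair — the criterion's
  "at least one atom pair" phrasing — with `atom_pair` available.
* **Sulfur**: Cys SG / Met SD participate only on request; the default
  targets conventional O/N bonds.
* **Ligands**: non-water HETATM N/O atoms act as both donors and acceptors
  for hydrogen bonds (models may legitimately include ligands); they are
  excluded from salt bridges, whose criterion names protein residues only.
  Water is excluded at parse time — protein–solvent bonds are out of scope
  by construction.

Two search routes exist: a cell-list spatial index (default) and the
O(n²) all-pairs route. They are required — and continuously tested — to
return bit-identical results; exact pair distances are recomputed from
coordinate differences so the route cannot affect boundary decisions.

## Feature table, filters, subsets

Each protein contributes: ID, annotation, FASTA length, QMEAN, bond
counts, rates, and 20 residue counts. The **denominator of both rates is
the full-length FASTA sequence length**, not the modeled residue count.
This matters for biounit models: a homodimer model contributes the bonds
of both chains against a single-chain length, which is how per-amino-acid
rates above 4 arise, and it preserves comparability with the sequence-side
composition analysis.

Quality control, in order: (1) among records whose annotation strings are
identical after case-folding and whitespace collapsing, keep the single
highest-QMEAN record (ties: lexicographically smallest ID); (2) drop
records with QMEAN < −5, keeping −5 exactly ("less than −5" governs);
(3) drop records annotated "uncharacterized protein". The order — dedup
before the QMEAN filter — follows the accounting convention of the
pipelines this mirrors (inputs → unique → quality-passing). The filter is
idempotent and logs per-stage counts.

Orthologs are pairs with identical normalized annotations — an
operational, annotation-based definition, not sequence-based orthology.

Upper-quantile subsets keep the top ⌈f·n⌉ records by a rate, ties broken
by ascending protein ID (determinism). Ceiling reproduces the published
arithmetic for the motivating set sizes (482 → 121/241, 58 → 15/29).
Threshold percentages use strict `>` ("more than"); list overlap is
reported as a percentage of the union, rounded to an integer.

## Statistical engine

* **Mann–Whitney U** from midranks; exact null distribution when
  n1+n2 ≤ 20 without ties (the small-sample regime where exactness
  matters and enumeration is checkable), otherwise the normal
  approximation with tie correction and continuity correction. The
  nonparametric path is the primary comparison because per-protein bond
  rates are right-skewed; `normality_check()` (Anderson–Darling +
  Lilliefors, documented substitutes for a proprietary third test)
  gates a recommendation message only.
* **Chi-square test of independence** on the 20×2 residue count matrix
  with standard contingency expectations E = row·col/total. The source
  methodology's prose description of expected values is ambiguous as
  written; standard expectations are the only self-consistent reading
  (deviations then sum to zero per species, which the published
  deviation tables satisfy). Per-cell deviations (raw counts, matching
  the published tables) and column-proportion differences (percentage
  points) accompany the test.
* **Spearman rho** as Pearson correlation of midranks; exact permutation
  p for n < 10 (the 20-residue analyses use the t approximation at
  n = 20).
* **Over-representation**: per-term one-sided Fisher exact
  (hypergeometric upper tail). The universe is the *annotated* background
  only — the convention of the GO-enrichment tool family, and the reason
  published expected counts are not reproducible from raw list sizes
  alone. No GO-graph propagation (annotations are taken as given) and no
  multiple-testing correction, matching the "classic, unadjusted"
  protocol.

No multiplicity adjustment is applied anywhere, by design fidelity.

## Synthetic data: what it emulates, what it does not

`make_ideal_helix(n)` builds an n-residue poly-Ala backbone from internal
coordinates (NeRF placement, bond lengths/angles from standard peptide
geometry) and guarantees: i→i+4 N–O distances in [2.8, 3.3] Å, every
other non-covalent backbone N–O pair > 3.5 Å — hence exactly n−4 bonds
under the 3.5 Å rule. The textbook α-helix torsions (−57°, −47°) do *not*
satisfy the second guarantee: they put i+2/i+3 N–O separations at
3.37/3.21 Å, inside a distance-only cutoff (real helices are detected
with bifurcated contacts by such criteria). We therefore build at
(−70°, −41°), still within the α-helical Ramachandran basin, where the
margins are ≥ 0.06 Å on every constraint; the guarantee is re-verified by
brute force at generation time, so a regression cannot silently produce a
different bond count.

`make_salt_bridge_dimer()` builds full idealized side chains on two
chains, orients the charged groups along a common axis, and places them so
the minimum qualifying O–N distance equals the request to 1e-3 Å (unique
minimizing pair, all other pairs farther, verified at generation).
Requests below 2 Å are rejected as van der Waals clashes.

`make_ensemble()` generates the statistical world: two species of
(default) 300 proteins with uniform lengths 80–500, proteome-average
residue frequencies, and per-protein bond *rates* drawn log-normally.
The log-normal parameters are fixed once from the upper-tail behaviour
proteome surveys report — medians 2.5 H-bonds/aa and 0.08 salt
bridges/aa with spreads placing ≈5% of proteins above 4.0 H-bonds/aa and
≈6.6% above 0.14 salt bridges/aa. Planted effects multiply both rates by
`top_multiplier` (default 1.5) in the `top_fraction` of species A ranked
by hydrogen-bond rate, and/or shift species-B residue frequencies.
Bond counts are planted integers attached to proteins — they deliberately
bypass the geometric detectors, which are validated on the structure
fixtures instead; this separates the two test surfaces cleanly. QMEAN
scores are simulated N(−2, 1.5²), so a realistic few percent fail the −5
filter.

What a green ensemble test does **not** establish: the generator has no
protein folds, no length–composition coupling, no annotation structure
beyond shared labels, and independent proteins (no phylogenetic
correlation). It validates the statistical machinery and the
subset-versus-full-set logic, not biological effect sizes.

Calibration measured during the build (and locked): under the null,
Mann–Whitney and chi-square reject in 4.7% of seeded replicates at
α = 0.05 (5000 seeds); with the default planted effect (×1.5 in the top
20%, n = 300/species) the upper-quartile comparison rejects in ~100% of
replicates while the full-set comparison rejects in ~10% — the
"difference lives in a subset" signature.

## Numerical and interface choices

* Cutoff comparisons carry a 1e-9 Å epsilon (PDB coordinates have 3
  decimals; the epsilon is far below coordinate precision and makes
  boundary fixtures deterministic).
* Altloc resolution: highest occupancy, ties to the lexicographically
  first altloc; multi-model files keep the first model only — one
  coordinate set per protein, as the detectors require.
* Element symbols missing from old-dialect PDB files are inferred from the
  atom name (first non-digit character), sufficient for the H/C/N/O/S
  vocabulary of protein models.
* Residue property ranks ship as editable TSVs: hydrophobicity from the
  Kyte–Doolittle ordering, volume from standard residue volumes, ties
  broken alphabetically so each is a permutation of 1..20. Published rank
  scales vary, so the tables are user-replaceable and provenance-stamped
  rather than hard-coded.
* The ensemble generator is a pure function of (spec, seed) and restores
  the caller's RNG state.
* Pipeline configuration is JSON; all outputs are sorted, fixed-precision
  TSVs, byte-reproducible for fixed inputs.

## Known limitations

* Distance-only criteria cannot distinguish genuine hydrogen bonds from
  close polar contacts with poor geometry; counts are comparable across
  proteins, not absolute.
* Annotation-string orthology misses true orthologs with divergent
  annotations and can pair paralogs annotated alike.
* The Fisher universe excludes unannotated background proteins; results
  depend on annotation completeness.
* Anderson–Darling/Lilliefors p-value formulas are published
  approximations; they gate a message, not an inference.
* mmCIF input, assembly expansion, hydrogen placement, pKa modeling and
  terminal-group salt bridges are out of scope.
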