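# thermbond

Quantifying hydrogen bonds, salt bridges and amino-acid use across protein
structure sets, and testing for signatures of protein temperature
adaptation between two species.

## The problem

Closely related species that evolved in thermally distinct environments
often show adaptive differences in protein structure: warm-adapted
orthologs tend to carry more stabilizing non-covalent interactions
(hydrogen bonds, salt bridges) that protect against heat denaturation,
while cold-adapted orthologs stay more flexible. Classic comparative work
examined one ortholog at a time; detecting proteome-scale signatures
requires counting these interactions in *hundreds* of structure models per
species and comparing the per-protein rates statistically. `thermbond` is
that pipeline: it consumes PDB-format structure models (e.g. homology
models built in their biological assembly), FASTA sequences, and
model-quality metadata, and produces the per-protein feature tables and
the full comparative analysis.

## What it computes

**Detection** (distance-only criteria, no angle term):

* *Hydrogen bond*: donor heavy atom D (N/O bearing hydrogen) and acceptor
  heavy atom A (N/O with a lone pair) with ‖D−A‖ ≤ 3.5 Å; when explicit
  hydrogens are modeled, additionally some donor-attached H with
  ‖H−A‖ ≤ 2.5 Å. Intra-residue pairs and the covalent backbone pair
  N(i)–O(i−1) are excluded; ligand N/O atoms participate.
* *Salt bridge*: Asp/Glu side-chain carboxyl oxygen within 4.0 Å of an
  Arg/Lys/His side-chain nitrogen (one event per residue pair by default).

**Per-protein normalization**: each protein's bond counts are divided by
its full-length FASTA sequence length, giving hydrogen bonds (or salt
bridges) per amino acid — the unit of all comparisons.

**Statistics**: Mann–Whitney U (exact for small untied samples, otherwise
tie- and continuity-corrected normal approximation) comparing full sets,
ortholog pairs (identical annotations) and upper quantile subsets
(top ⌈f·n⌉ by rate); chi-square tests of independence on the 20×2
amino-acid count matrix with observed−expected deviations; Spearman rank
correlations of usage deviations against residue hydrophobicity and volume
ranks; per-term one-sided Fisher exact GO over-representation against an
annotated background ("classic" per-term testing, no multiplicity
adjustment); Anderson–Darling and Lilliefors normality checks.

**Synthetic fixtures**: ideal α-helices with a guaranteed n−4 backbone
hydrogen-bond count, salt-bridge dimers built at an exact prescribed O–N
distance, and seeded two-species proteome ensembles with planted effects —
these double as geometric and statistical oracles for the test suite.

## Worked example

```r
library(thermbond)

# a 12-residue ideal helix has exactly 12 - 4 = 8 backbone hydrogen bonds
helix <- make_ideal_helix(12)
bonds <- detect_hbonds(helix)
head(bonds[, c("donor_resseq", "donor_atom", "acceptor_resseq",
               "acceptor_atom", "distance")], 3)
#>   donor_resseq donor_atom acceptor_resseq acceptor_atom distance
#> 1            5          N               1             O 2.896036
#> 2            6          N               2             O 2.895494
#> 3            7          N               3             O 2.896487
nrow(bonds)
#> [1] 8

# a salt-bridge dimer at a prescribed 3.8 A minimum O-N distance
detect_salt_bridges(make_salt_bridge_dimer("ASP", "LYS", 3.8))[,
  c("donor_resname", "donor_atom", "acceptor_resname", "acceptor_atom",
    "distance")]
#>   donor_resname donor_atom acceptor_resname acceptor_atom distance
#> 1           LYS         NZ              ASP           OD1      3.8

# two-species ensemble, bond rates inflated x1.5 in the top 20% of A only
e <- make_ensemble(ensemble_spec(n_proteins = 300, top_fraction = 0.2,
                                 top_multiplier = 1.5, seed = 7))
a <- apply_quality_filters(e$a)   # QMEAN >= -5, dedup, drop uncharacterized
b <- apply_quality_filters(e$b)
attr(a, "filter_log")
#>                     stage   n
#> 1                   input 300
#> 2       unique_annotation 300
#> 3              qmean_pass 294
#> 4 uncharacterized_removed   0
#> 5                   final 294

mann_whitney_u(a$hbonds_per_aa, b$hbonds_per_aa)
#> Mann-Whitney U (normal approximation, tie-corrected, continuity-corrected)
#>   statistic = 45614.5, p = 0.14329, n1 = 294 , n2 = 290, ...
ua <- upper_fraction(a, "hbonds_per_aa", 0.25)
ub <- upper_fraction(b, "hbonds_per_aa", 0.25)
mann_whitney_u(ua$hbonds_per_aa, ub$hbonds_per_aa)
#> Mann-Whitney U (normal approximation, continuity-corrected)
#>   statistic = 4269, p = 1.2569e-09, n1 = 74 , n2 = 73, ...
```

The two tests together show the planted signature: the full proteomes do
not differ significantly (p = 0.14), but the upper quartiles do
(p ≈ 1e-9) — stabilization concentrated in a subset of proteins, invisible
to a whole-proteome comparison. Composition analysis on the same tables:

```r
u <- count_usage(a, b)
attr(u, "test")$p_value                 # chi-square on the 20x2 matrix
#> [1] 0.62           # no composition shift was planted here
deviation_rank_correlation(u, property_ranks(), "hydrophobicity")$rho
#> [1] 0.056          # and no hydrophobicity trend
```

## Command line

```sh
Rscript inst/cli/thermbond.R simulate --out ens/ --seed 1 --n 300
Rscript inst/cli/thermbond.R quantify --config config.json
Rscript inst/cli/thermbond.R compare  --config config.json
Rscript inst/cli/thermbond.R usage    --config config.json
Rscript inst/cli/thermbond.R enrich   --config config.json --annotations ann.tsv
```

`config.json` holds the fields of `pipeline_config()`: FASTA paths, PDB
directories, QMEAN metadata TSVs, detection cutoffs, and output directory.
All outputs are deterministic TSVs.

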