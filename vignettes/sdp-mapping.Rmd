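---
title: "Mapping partner-selecting positions of paralogous receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping partner-selecting positions of paralogous receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpmapper)
```

## The problem and the model

Paralogous receptors that bind distinct ligands must encode that choice
somewhere in their sequence. A specificity-determining position (SDP) is
an alignment position conserved *within* a paralog subfamily but
substituted *between* subfamilies; partner-selecting SDPs additionally
sit where they can do the selecting - at the protein-protein interface.
The motivating system is the TAM receptor family (Tyro3, Axl, Mer) and
its ligands: Gas6 binds Axl strongly, Pros1 does not bind Axl at all,
which supplies a built-in positive/negative-control contrast
(`Axl:Gas6` binder vs `Axl:Pros1` non-binder).

sdpmapper implements the full evidence cascade:

1. **Sequence stage.** Columns of a grouped MSA are scored three ways.
   Mutual information between the residue symbol $a$ and the group
   label $i$,
   $$I_p = \sum_{i=1}^{N} \sum_a f_p(i)\, f_p(a \mid i)
     \log \frac{f_p(a \mid i)}{f_p(a)},$$
   is zero iff the per-group symbol distributions are identical and is
   bounded by the group entropy $\sum_i f(i)\log 1/f(i)$. Multi-RELIEF
   updates a per-column weight vector from nearest-hit/nearest-miss
   Hamming comparisons, $w \in [-1, 1]$; higher weight means more
   group-separating. Sequence harmony is a symmetrised
   relative-entropy (Jensen-Shannon-style) divergence mapped to
   $[0,1]$, where 1 means identical group distributions and 0 disjoint
   supports; *low* harmony marks candidates.
2. **Interface stage.** Solvent-accessible surface area by
   Shrake-Rupley quadrature classifies residues into core
   (burial fraction $\Delta$SASA/unbound SASA $\geq 0.95$), rim
   (interface but less buried) and non-interface. Partner-selecting
   SDPs are expected at the rim, so rim membership is a filter.
3. **Contact stage.** Inter-side hydrophobic contacts (non-polar atom
   pair within 4.4 Å), hydrogen bonds (H···acceptor $\leq$ 2.5 Å and
   donor-H-acceptor angle $\geq 120°$) and salt bridges (oppositely
   charged group atoms within 4.0 Å) are detected per frame.
4. **Trajectory stage.** Contacts are tracked across replica MD
   ensembles; a contact is *stable* in a replica when present in
   strictly more than 25% of analysed frames and *consistent* when
   stable in every replica.
5. **Consensus.** Receptor residues forming consistent salt bridges in
   the binder survive; positions with the same evidence in the
   non-binder control are eliminated; positions whose residue letter
   recurs in any other paralog are eliminated; ortholog conservation is
   reported as supporting evidence. The final verdict requires rim
   membership (when structural evidence is supplied), consistency in
   the binder, absence in the control and paralog uniqueness.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `core_burial` | 0.95 | fraction | burial fraction at/above which an interface residue is core |
| `delta_tol` | 0.1 | Å² | minimum ΔSASA counted as interface (quadrature noise guard) |
| `probe` | 1.4 | Å | water-probe radius for SASA |
| `points` | 960 | count | quadrature points per atom (deterministic Fibonacci spiral) |
| `hydrophobic_cutoff` | 4.4 | Å | non-polar pair distance |
| `hbond_cutoff` | 2.5 | Å | hydrogen-acceptor distance (see below) |
| `hbond_min_angle` | 120 | degrees | minimum D-H-A angle |
| `saltbridge_cutoff` | 4.0 | Å | charged-group atom distance |
| `stability threshold` | 25 | % occupancy | strict `>` per replica |
| `whisker_iqr_mult` | 2 | IQR units | box-plot whisker length for outlier flags |
| `pseudocount` | 0 | count | added to per-group symbol counts |
| `alpha` | 0.05 | level | permutation significance for the MI call |

All comparisons against distance cutoffs are inclusive (`<=`); the
stability threshold is strict (`>`), which is what makes an occupancy
of 25.14% stable while exactly 25% is not.

## Interpretation decisions

Several upstream conventions are ambiguous; the package fixes them as
follows and echoes each choice in its outputs.

* **MI normalisation.** The mutual-information score mixes counts and
  ratios in some published descriptions; sdpmapper computes proper
  mutual information with the joint weighted by group fraction, which
  guarantees non-negativity and the independence-zero fixed point the
  method needs. Natural logarithm; the base is recorded in the score
  table metadata.
* **RELIEF sign convention.** The canonical RELIEF update *increases*
  a weight when the nearest miss differs and *decreases* it when the
  nearest hit differs; that is the `standard` default, matching
  "higher weight = more likely SDP". The opposite (`as_printed`)
  convention is available for comparison with sources that display the
  signs flipped.
* **Sequence harmony formula.** The original harmony formula is not
  fully specified in the method descriptions this package follows; a
  symmetric Jensen-Shannon-style divergence normalised to $[0,1]$ is
  used as a documented stand-in with the same fixed points (1 for
  identical distributions, 0 for disjoint supports).
* **Hydrogen-bond distance.** A 2.5 Å cutoff is geometrically
  impossible for donor-acceptor separation (covalent N-H/O-H plus a
  bond), so the default mode measures the hydrogen-acceptor distance,
  consistent with the D-H-A triplet language; a `donor-acceptor` mode
  exists for hydrogen-free models and should be paired with a larger
  cutoff (about 3.5 Å).
* **"At least two non-polar atoms within 4.4 Å"** is read as one
  cross-side *pair* of non-polar atoms (the two atoms are the two
  partners); the strict two-pair reading is available behind
  `strict_hydrophobic_pairs`.
* **Burial.** ">95% buried" is read as burial *fraction*
  ΔSASA/unbound SASA ≥ 0.95 - the only reading that makes "buried" a
  fraction of the residue's own free-state area.
* **Histidine charge** is off by default (protonation unknown);
  terminal charges likewise.
* **Quartiles** use linear interpolation (type 7). Outlier sets depend
  on the quartile method, so it is fixed and documented.
* **Paralog identity** is per-letter equality: conservative
  substitutions (E vs D) count as *different*, so a position whose
  acidic residue is acidic-but-different in a sister paralog survives
  the uniqueness filter.
* The distribution-association `r` between two per-frame count series
  is the Pearson correlation of the aligned series when lengths match
  and of their percentile profiles otherwise; the variant used is
  recorded in the result.

## What the synthetic generators emulate

`make_grouped_msa()` plants fully group-separating columns on a
group-independent background whose per-column conservation is a single
probability; defaults (5 vs 10 sequences, 100 columns, conservation
0.85) mirror a small mammalian ortholog pull for one receptor
subfamily against its two pooled sister paralogs over an Ig-like
domain. It does **not** emulate phylogenetic correlation between
sequences, indels beyond the planted pattern, or rate variation across
sites - so passing recovery tests shows scorer correctness on the
assumed exchangeable background, not robustness to tree structure.

`make_toy_interface()` builds chemically minimal residues (only the
atoms detectors read: CB, OE1/NZ, OG-HG, backbone O) on two chains
with planted geometries and a guaranteed absence of unplanned
cross-side contacts; packing is verified after construction and
violations raise an infeasible-packing error. Real side-chain
flexibility, secondary structure and crystallographic artifacts are
out of scope.

`make_ensemble()` switches each planted contact between an on-geometry
and an off-geometry independently per frame (Bernoulli at the target
occupancy) with small Gaussian jitter; margins of at least eight
jitter standard deviations to the cutoff are enforced. Frame-to-frame
autocorrelation is deliberately absent - occupancy statistics, not
kinetics, are the target - so occupancy standard errors are exactly
binomial.

`make_energy_table()` draws Gaussian per-residue electrostatics with
planted outlier rows.

Every generator is seed-reproducible and returns a machine-readable
truth record.

## Numerical choices and degenerate inputs

* SASA quadrature is a deterministic Fibonacci spiral; a point is
  buried when strictly inside a neighbour's expanded sphere. At 960
  points per atom the per-residue agreement with a 10,000-point
  reference is within 2% on random clusters. Exactly coincident atoms
  split exposure numerically (the degenerate limit reports about one
  sphere of total area for two coincident atoms).
* `delta_tol = 0.1` Å² keeps quadrature noise from minting phantom
  interface residues.
* RMSD-to-average uses two superposition passes (all frames onto frame
  1, then each frame onto the average); rigid-body motion therefore
  contributes nothing.
* Ranking ties (equal scores, equal model scores) break by lower
  column index / lexicographic id, making selections stable.
* All-gap columns are legal and score as a single-symbol profile on
  the gap; gaps are ordinary scoring symbols throughout, because
  deletions can be group-specific.
* The MI permutation call special-cases `alpha >= 1` to "flag
  everything" (the degenerate quantile); at ordinary levels a
  signal-free alignment yields no flags.
* A candidate position that the structure cannot resolve is carried
  through with an `unresolved` flag and excluded from the final
  verdict, never silently dropped.

## Small-sample MI saturation

One property worth knowing when simulating: with fully uniform
background noise (conservation 0), a 20-letter alphabet and few
sequences per group, a substantial fraction of *random* columns have
disjoint group letter supports, and any such column scores exactly the
group-entropy bound $\log 2$ - the same value as a planted fully
separating column. Mutual information therefore cannot rank the
planted column strictly first in that regime, and its permutation null
saturates at the same bound. Multi-RELIEF does not suffer from this
(random mismatches cancel between hit and miss), and at realistic
background conservation (the 0.85 default) MI recovers planted columns
reliably. The test suite probes MI recovery at the realistic default
and Multi-RELIEF recovery under full noise.

## Problem sizes used by the test suite

The suite exercises the statistical properties at deliberately small
scales chosen for tight guarantees rather than realism: 1000 random
profiles for the MI oracle agreement (1e-12), 100 seeded runs for
planted-column recovery (expected $\geq$ 95 successes), single
350-frame replicas for occupancy recovery (3 binomial standard
errors), 30-frame/2-replica ensembles for the end-to-end verdict
recovery, and 50-atom clusters for the SASA oracle. The packaged
occupancy, paralog-correspondence and refinement-pair tables let the
replica-consistency filter and the consensus cascade be replayed
exactly at full scale in milliseconds.

## Known limitations

* Only two-class grouping is first-class for harmony; $k$-group
  Multi-RELIEF averages one-vs-rest runs, a composition whose exact
  published counterpart is undocumented.
* No sequence weighting is applied across redundant orthologs (the
  grouping data this design targets mixes five mammals per paralog);
  strongly unbalanced species sampling will bias all three scorers.
* The trajectory stage reads multi-model PDB files or directories of
  PDB frames only; binary trajectory formats are upstream conversions.
* Force-field energies are parsed, never computed; refinement and MD
  engines are out of scope.
* mmCIF, crystallographic assembly inference and the
  evolutionary-score half of core/rim pipelines are not implemented;
  only the geometric burial rule is.
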