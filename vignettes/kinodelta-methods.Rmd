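---
title: "Methods: deletion-panel TMT proteomics, from reporter ions to networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deletion-panel TMT proteomics, from reporter ions to networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinodelta)
```

## The measurement model

The package analyzes panels of single-gene deletion strains profiled by
isobaric (TMT) labeling. Each 11-plex carries up to ten deletion-strain
samples plus one wild-type *bridge* channel; the bridge is the common
reference that makes ratios comparable across plexes. Strains are grown in
biological duplicate, and the duplicate of each assignment group is run as a
second plex with the same membership — the default design (110 strains in 14
assignment groups, duplicated) yields 28 plexes.

For a molecule $i$ (protein or phosphosite) in sample channel $c$ of plex
$p$, the modeled reporter intensity is

$$ y_{icp} = b_i \cdot 2^{\beta_{is}} \cdot \ell_{cp} \cdot 2^{\varepsilon_{icp}}, $$

where $b_i$ is a baseline abundance, $\beta_{is}$ the planted log2 effect of
strain $s$ on molecule $i$, $\ell_{cp}$ a per-channel loading factor, and
$\varepsilon \sim N(0, \sigma)$ multiplicative log-normal noise on the log2
scale. A phosphosite's signal compounds the cognate protein's abundance
effect and the phosphorylation-stoichiometry effect. The deleted gene's own
product is suppressed by $2^{-5}$ in its cognate strain — a strong,
detectable decrease without exact zeros that would break the log transform.

## Normalization chain

Each plex passes through, in order:

1. *Isotopic impurity correction*: reporter channels bleed into neighbors
   according to the label's impurity specification; with observed vector
   $y = M \beta$ per molecule, the linear system is solved per molecule and
   rare negative solutions are clamped to zero.
2. *Peptide filtering and rollup* (when starting from peptide tables):
   summed signal-to-noise ≥ 200 across channels, isolation specificity ≥
   0.5, both inclusive; unique peptides are summed into protein values,
   shared peptides discarded.
3. *Loading equalization*: channels are scaled so summed protein quantities
   (over molecules observed in every channel of the plex, so missingness
   cannot bias the factors) are equal; the same factors are applied to the
   plex's phosphosite table, because both tables derive from one labeled
   digest.
4. *Bridge ratios*: log2(sample) − log2(bridge) per molecule; zeros become
   missing before the log.
5. *Trimmed-mean centering*: each sample column is shifted so its 5%-trimmed
   mean is zero. This absorbs residual measurement error in the bridge
   sample and any per-channel offset that equalization leaves behind. Each
   column is centered separately — centering a plex globally would leave
   channel-specific bridge error in place.
6. *Joining*: plexes are joined by molecule identification into a strains ×
   replicates ratio matrix, missing where a molecule was not identified in a
   plex.
7. *Protein normalization of phosphosites*: the cognate protein's log2 ratio
   is subtracted per (strain, replicate) wherever it exists; entries without
   a protein ratio pass through unchanged and are flagged, and the fraction
   of normalizable entries is reported (≈95% under the default generator,
   matching the coverage structure of real panels).

An exactness property anchors the chain: on noiseless input whose planted
effects are sparser than the trim fraction in every column, the full chain
returns every planted log2 effect exactly (tolerance 1e-9), because loading
and equalization offsets are constant per column and the trimmed mean sees
only null molecules.

## Event calling and attribution

Molecules quantified in at least 50% of strains are analyzed. Replicates
are merged by arithmetic mean; each molecule's variability yardstick is the
SD of its merged strain profile after removing the top and bottom
`floor(0.05 n)` values. A strain regulates a molecule when every available
replicate clears 3·SD *with consistent sign* (opposite-sign excursions are
irreproducibility, not regulation), or a lone replicate clears 6·SD, and the
merged ratio clears the fold-change floor — log2 0.38 for proteins and 0.5
for phosphosites, i.e. minimum fold changes of 1.3 and 1.4. The floor is
applied to the merged ratio because merging precedes thresholding in the
procedure this package implements. The deleted gene's own product is never
an effector call; it is logged separately as a deletion confirmation.

Attribution compares calls on raw phosphosite ratios with calls on
protein-normalized ratios over the same site universe: raw-only events are
*protein-driven*, events in both sets are *phospho-driven*, and
normalized-only events are *newly captured* (stoichiometry changes that a
protein change masked). Note that sites riding on an abundance-regulated
protein are genuine protein-driven events even when no site-level effect was
planted; recovery of the planted protein-driven *fraction* is therefore
measured over the planted target set, against the generator's truth table.

## Networks

**Strain–strain correlations.** On the deletion-masked, merged matrix
(deleted genes are set missing in their own strains so the perturbation
itself cannot correlate), every strain pair is correlated over molecules
measured in both strains and responsive (|log2| above the floor) in *at
least one* of the two — requiring both would bias pairs toward shared
responders and starve the 25-molecule minimum. Pearson p-values use the t
transform with n − 2 degrees of freedom; BH adjustment spans all evaluated
pairs within a level; edges require |r| ≥ 0.6, and low or insufficient
pairs are recorded as 0 in the symmetric, unit-diagonal matrix.

**Molecule covariance.** Every molecule pair with shared measurements in ≥
50% of strains is correlated across strains; the Bonferroni factor is the
number of pairs actually evaluated (pairs failing the overlap gate are not
tests); edges require |r| ≥ 0.7 and adjusted p ≤ 0.001. The permutation
null shuffles each molecule's strain order independently — this preserves
every marginal distribution while destroying cross-molecule structure,
which is exactly the structure the network claims. The false-positive rate
is the mean permuted edge count as a percentage of the observed count.
Masking matters here too: unmasked deletion-suppression spikes realign by
chance under permutation and inflate the permuted edge count.

**Edge attribution** is multi-label (an edge counts toward every annotation
class whose term both endpoints share, or whose interaction list contains
the pair), with an "any known" union and an unexplained remainder; for
phosphosite networks the fraction of same-protein edges is also reported.

## Enrichment

All three modes use the hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ with BH control at 1%:

* *regulator mode*: does the set of strains regulating a molecule
  over-represent a pathway's regulators, against the background of all
  regulators active at that level? Molecules whose call directions conflict
  across the pathway strains are removed after testing (an automated,
  reproducible version of what is otherwise manual curation; it can be
  disabled).
* *effector mode*: per strain and direction, are a strain's up- or
  down-regulated proteins enriched in a term? Phosphosites collapse to
  proteins (multiple sites count once); the background is the union of all
  perturbed proteins; BH spans all strains, directions and terms per
  database.
* *neighbor mode*: are a protein's positively correlated network neighbors
  enriched in a term, against all positively connected proteins minus the
  surveyed node? BH spans all nodes and terms per database.

Term universes are intersected with the relevant background before $K$ is
computed, so annotation-only genes cannot inflate the background. BH ties
are broken by term/molecule ID for determinism.

## The synthetic-data generator

The generator emulates what the pipeline consumes, not how a mass
spectrometer works: opaque molecule IDs, no spectra, no sequences.
Distributional choices the underlying experiments do not pin down are
stand-ins chosen once:

* baselines log-uniform over three orders of magnitude (realistic dynamic
  range);
* loading factors log-normal with configurable CV (default 0.1);
* measurement noise log-normal on the log2 scale (default SD 0.1), attached
  to sample channels; replicate-difference SDs therefore calibrate to
  $\sigma\sqrt{2}$, and bridge-sample error is represented by the centering
  step that exists to absorb it;
* missingness plex-structured — a molecule drops out of a whole plex, as
  identification-based joining produces — rather than cell-random;
* planted effects drawn from a discrete grid (default |log2| ∈ {0.6, 1});
  phospho targets are planted on sites whose cognate proteins are distinct
  and otherwise unperturbed in that strain, so every target has a clean
  attribution class (60% protein-driven, 10% compensated, the rest pure
  stoichiometry, by default);
* co-regulated modules add a shared per-strain $N(0, 0.5)$ effect to their
  members, creating the covariance structure the network stage detects.
  Module members are drawn from unplanted molecules, so discrete-target
  recovery and module recovery are measured on disjoint surfaces.

What passing tests on this generator do **not** show: robustness to
co-isolation interference, to peptide-level disagreement within a protein,
to non-log-normal noise tails, or to biologically correlated (rather than
planted) effects. The generator is a contract for the pipeline's
arithmetic, not a simulator of yeast.

## Numerical choices and problem sizes

* Trim counts use `floor(0.05 n)` per tail everywhere, ties broken by value
  then ID; degenerate columns (fewer than `1/(2·trim)` values) fall back to
  the plain mean.
* Zero intensities become missing before logs; zero-variance profiles yield
  r = 0 (degenerate, never an edge); molecule pairs are evaluated once in
  lexicographic order.
* Correlation p-values come from the t transform; with 100+ strains the
  |r| cutoffs (0.6, 0.7) bind long before the adjusted-p cutoffs do.
* Verification runs use: the full 110-strain × 2,000-protein ×
  3,000-phosphosite design for recovery and attribution; a 110 × 500 panel
  with one 20-member module and 200 permutations for covariance
  calibration; 200 seeded repetitions for null enrichment. These sizes give
  stable estimates (binomial SE below half a point on all reported
  fractions) while keeping a complete verification run within a few
  minutes.
* The attribution study uses |log2| = 1 effects so that classification
  error at the 0.5 phosphosite floor (noise SD 0.1 implies a merged-ratio
  SD of ~0.07, and a 0.6 effect sits only ~1.4 SD above the floor after
  normalization doubles the variance) does not confound the planted
  fraction being estimated.

## Known limitations

* Impurity correction skips rows with partial missingness (the generator
  never produces them; real partially-missing rows pass through
  uncorrected).
* The regulator-enrichment consistency filter automates what is in practice
  a judgment call; borderline molecules differ from hand curation.
* Permutation FPR estimates are undefined on empty observed networks and
  are flagged rather than forced to zero.
* With very small panels (< 20 strains) the 5% trim removes nothing, so
  per-molecule SDs absorb planted effects and calling becomes conservative;
  the thresholds were designed for ~110-strain panels.
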