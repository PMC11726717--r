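---
title: "Dynamical networks and allosteric pharmacology with allodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical networks and allosteric pharmacology with allodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodyn)
```

## The problem

Positive allosteric modulators (PAMs) of G protein-coupled receptors bind
outside the orthosteric pocket and reshape the receptor's response to its
agonist. Two complementary kinds of evidence describe how: functional
pharmacology (concentration--response surfaces quantifying how much the
modulator shifts agonist potency and efficacy) and molecular dynamics
(MD), where the question is *which residues carry the allosteric signal*
between the modulator site and the orthosteric site, for example through
transmembrane helix 7 of the adenosine A1 receptor.

`allodyn` implements both layers as one tested pipeline:

* **Structural metrics** over multi-replica trajectories: RMSD, RMSF,
  side-chain rotamer occupancies, contact and hydrogen-bond persistency,
  and between-condition contact differences.
* **Dynamical network analysis**: residues (C-alpha atoms) are nodes;
  residue pairs in persistent contact are joined by edges weighted by the
  correlation of their motion; optimal/suboptimal paths, edge
  betweenness, Girvan--Newman communities and per-helix subnetworks
  interrogate the graph.
* **Allosteric pharmacology**: the 3-parameter logistic equation and the
  operational model of allosterism, reporting pEC50 and the composite
  cooperativity Log(alphabeta).

Because microsecond membrane-protein trajectories cannot be regenerated
at desk scale, validation rests on synthetic generators with analytic
ground truth, described at the end.

## The dynamical network model

For residues $i, j$ the correlation of motion is

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle |\Delta r_i|^2\rangle\,\langle |\Delta r_j|^2\rangle}},$$

with $\Delta r_i$ the displacement of residue $i$'s C-alpha from its
time-mean position over the merged replicas (frames may first be
superposed on a fit selection; a two-pass scheme aligns to the mean
structure). An edge joins $i$ and $j$ iff

* the residues were in contact (any heavy-atom pair within 4.5 Å,
  closed interval) in at least 75% of the merged frames,
* they are not sequence neighbours ($|i-j| > 1$), and
* $|C_{ij}|$ exceeds a small floor (default $10^{-6}$) below which the
  edge weight would be effectively infinite; such pairs are dropped with
  a warning.

The edge weight is $W_{ij} = -\log|C_{ij}|$: strongly correlated pairs
are "short" edges, so minimum-weight paths are maximum-correlation
communication routes. The logarithm base (natural by default) only
rescales all weights uniformly; shortest-path node sequences, betweenness
rankings and community partitions are provably invariant to it, and the
test suite checks this invariance explicitly.

**Paths and "structural information".** Between a configured source and
sink, `suboptimal_paths()` enumerates every simple path within a weight
tolerance of the optimum (depth-first search pruned by the remaining
shortest distance, with a configurable path-count guard that flags
truncation). The per-edge usage count across this ensemble is what the
package renders as edge thickness ("structural information"). This is a
documented convention of the package: published network figures do not
always state whether thickness encodes path usage, betweenness or
correlation magnitude, so the choice is recorded in output metadata
rather than guessed. Source and sink node sets likewise have no default:
a biological choice (e.g. the PAM site and the G protein interface) must
be named in the configuration.

**Communities.** Girvan--Newman removal of the highest-betweenness edge,
with two deliberately different weight semantics: betweenness treats $W$
as a distance, while modularity scores each partition with the
correlation magnitudes $|C| = b^{-W}$ as edge strengths. (Using distances
as strengths would reward weakly coupled modules -- the opposite of the
intent.) Ties in betweenness are broken by the lexicographically smallest
residue pair, so the hierarchy is deterministic and invariant to node
relabelling. The partition at maximum modularity is returned, preferring
the coarser partition on ties; on a complete graph this correctly returns
a single community.

## The pharmacology model

The 3-parameter logistic with unit Hill slope,
$E = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1 + \mathrm{EC}_{50}/[A]),$
is fitted per replicate and summarised as mean ± SEM, the form in which
potency tables are conventionally reported.

The operational model of allosterism predicts the response surface over
agonist $[A]$ and modulator $[B]$:

$$E = \frac{E_m\,\big(\tau_A [A](K_B+\alpha\beta[B]) + \tau_B [B] K_A\big)^n}
{\big([A]K_B + K_A K_B + K_A[B] + \alpha[A][B]\big)^n +
 \big(\tau_A [A](K_B+\alpha\beta[B]) + \tau_B [B] K_A\big)^n}$$

with operational efficacies $\tau_A, \tau_B$, dissociation constants
$K_A, K_B$, affinity cooperativity $\alpha$ and efficacy cooperativity
$\beta$. At $[B]=0$ this reduces *algebraically* to the operational
model of agonism; the suite verifies the identity to $10^{-12}$ relative
error across random parameter sweeps.

**Identifiability and the default constraint set.** Functional data
identify $\alpha$ and $\beta$ only through their product, so the model is
parameterised directly in $\log_{10}(\alpha\beta)$ and the default
constraints fix $n = 1$ and $\log_{10}\alpha = 0$; freeing both
cooperativities without binding data is rejected with an error naming the
aliased pair. Unlike the common practice of fixing $K_A$ to a
vehicle-derived estimate, $K_A$ is left free by default: a vehicle curve
pins only the combination $K_A/(1+\tau_A)$, so "fixing $K_A$ from the
vehicle fit" silently presumes $\tau_A$; with several modulator
concentrations and $\tau_B$ free, the surface identifies $E_m$, $\tau_A$
and $K_A$ jointly. Any parameter can still be fixed through the
`fixed` argument.

**Numerics.** All positive-scale parameters are fitted in log10 space;
Levenberg--Marquardt (via `minpack.lm`) minimises the residuals with
objective tolerances of $10^{-12}$ and starting values derived from
per-curve logistic fits (vehicle potency; potency shift at the highest
modulator concentration for the cooperativity start), plus a small
multi-start grid over the agonist efficacy ($\tau_A \in \{0.5, 3, 30\}$)
keeping the best residual sum of squares. Noiseless surfaces are
recovered to machine precision; fits that fail to converge are retained
but flagged and excluded from summaries with a warning. Degenerate
inputs (constant responses, fewer than 4 concentrations, fewer than 3
modulator levels) raise errors rather than returning nonsense.

Condition comparisons use two-way ANOVA on per-replicate pEC50 with
Dunnett contrasts against the control level (via `emmeans`); a
Monte-Carlo test confirms the family-wise error rate stays near nominal.

## What the synthetic generators emulate

* `gen_harmonic_trajectory()` draws i.i.d. frames about a mean structure
  in which each residue's displacement along every Cartesian axis is
  $\sigma_i z_i$ with one latent vector $z \sim N(0, R)$ shared across
  axes. Under this model $C_{ij} = R_{ij}$ exactly and the RMSF equals
  $\sqrt{3}\sigma_i$, giving closed-form truth for the estimators; at
  $10^5$ frames the suite requires $|C - R| < 0.03$ and RMSF within 2%.
  Frames are independent -- no autocorrelation, no anharmonicity, no
  periodic boundary artefacts -- so passing tests validate estimator
  correctness, not robustness to slow conformational exchange.
* `gen_planted_network()` builds stochastic block models with high
  within-block and low between-block correlation magnitudes, for
  community-recovery studies (3 blocks, $p_{in} = 0.9$,
  $p_{out} = 0.05$, 20 seeds, requiring $\ge 90\%$ label agreement).
* `gen_dose_response()` draws operational-model surfaces plus i.i.d.
  Gaussian noise. The study conditions are fixed once: agonist
  1 pM--1 µM in log10 steps, modulator 0/10 nM/100 nM/1 µM/10 µM,
  4 replicates, responses on a 0--100 normalized scale with noise sd 5
  (about 5% of the system maximum, which yields replicate-level scatter
  of fitted potencies of the same order as published SEMs). Parameters
  not constrained by the reference table use one realistic regime:
  $\tau_A = 3$ (vehicle plateau at 75% of $E_m$,
  $pK_A = \mathrm{pEC}_{50} - \log_{10}(1+\tau_A)$), $K_B = 100$ nM,
  $\tau_B = 0.2$ (the modulator shows weak direct agonism).
  Recovery studies use 25 seeded datasets and report the median.

Ensembles can be written to disk (PDB topology + DCD per replica) so
synthetic data enter through the same readers as real trajectories.

## Conventions and scope decisions

* **Residue keys** are the author (PDB) numbering; Ballesteros--Weinstein
  labels are an overlay for selection (`bw 7.40-7.49`) and reporting,
  never a primary key. Atom indices are 1-based, the R ecosystem's
  convention.
* **Ligand RMSD** is provided both after receptor superposition and in
  the laboratory frame (`fit_sel = NULL`); which mode a result used must
  be named, since published values do not always say.
* **Supported dialects**: plain PDB (no insertion codes or altlocs,
  rejected loudly) and CHARMM/NAMD DCD. Hydrogen-bond criteria default
  to 3.5 Å / 120° and are configuration-exposed, because the tools that
  produced published persistency values do not print their thresholds.
* **Determinism**: every stochastic routine takes a seed; pipeline runs
  with identical configuration and seed produce byte-identical outputs.

## Known limitations

Time-correlated motion, water-mediated or typed interactions
(pi-stacking, salt bridges), generalized-correlation edge weights,
trajectory formats beyond DCD, and kinetic BRET modelling are out of
scope. Fitted cooperativities describe the Gaussian-noise, unit-slope
regime of the generators; real plate data with plate effects or biased
normalization need the raw-scale fitting flag and care.
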