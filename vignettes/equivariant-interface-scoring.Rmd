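---
title: "Equivariant scoring of protein-protein interfaces at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivariant scoring of protein-protein interfaces at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(equiscore)
```

## The problem

Docking programs and generative structure predictors emit many candidate
models ("decoys") of a protein-protein complex, most of them wrong. A scoring
function assigns each decoy a quality estimate so that near-native models
rise to the top of the ranking. `equiscore` implements such a scoring
function as an SO(3)-equivariant graph attention network over a
residue-level representation of the complex, together with everything needed
to train and evaluate it end to end: ground-truth interface quality metrics
(fnat, interface RMSD, ligand RMSD, CAPRI classes, DockQ), a ranking
evaluation stack (ROC/AUC, step-wise average precision, threshold-swept MCC
and F1, top-N hit curves, DeLong comparisons with Bonferroni correction),
and a seeded synthetic decoy generator so the whole pipeline runs on a
laptop with no external data.

## Input representation

A complex is two binding partners at residue level. Each residue contributes
one node carrying:

* its CA coordinate (3-vector, Å);
* a 21-way one-hot amino-acid identity (20 canonical types plus unknown, so
  every row sums to 1);
* a binary **interface flag**: 1 when any CA of the other partner lies
  within 16 Å;
* a binary partner identifier (the network must know which molecule a
  residue belongs to);
* a per-residue embedding row of width 32 by default. Real deployments would
  use protein-language-model embeddings; the package ships a deterministic
  synthetic provider (per-type seeded vectors plus a small positional
  component) so the channel is always populated and the plumbing is
  exercised;
* a unit CA-trace direction vector (previous CA to next CA, zero at
  termini), the one geometric vector input, used to seed the order-1
  features.

Edges connect residues within 12 Å (CA-CA), capped at the 24 nearest
incoming neighbours per node. The 16 Å interface cutoff is the one the
method is defined with; the edge radius and neighbour cap are implementation
choices sized so that toy complexes stay connected across the interface
while node degree stays bounded.

## The network

Node states are banks of rotation-order features: for each order
$l = 0, 1, 2$ ("lmax = 2") the node carries 16 channels of a
$(2l+1)$-dimensional vector that transforms under the order-$l$ Wigner
matrix $D_l(R)$ when the input coordinates rotate by $R$. Order-0 states are
initialized from a linear map of the scalar features, order-1 states from
the CA-trace vector gated by scalars, order-2 states at zero.

Three attention blocks follow. In each block, per-edge messages are
Clebsch-Gordan tensor products of the sender's features with the real
spherical harmonics of the edge direction, modulated per channel by a
Gaussian radial basis of the edge length (16 basis functions spanning
0-12 Å, width equal to the spacing). Attention weights come from the
invariant scalars only: an MLP over (sender scalars, receiver scalars,
radial features) produces per-head logits that are softmax-normalized over
each receiver's incoming edges. The weighted messages, a parallel
*unnormalized* message sum (scaled by 1/16), and a self-interaction are
mixed per order and added back residually; scalars pass through a SiLU,
higher orders are gated by sigmoids of the scalars. The unnormalized sum
route exists because a softmax average cannot represent neighbour *counts*,
and contact counts are exactly what distinguishes marginal decoys.

Two further interior choices help the same statistic reach the output:
an **edge-degree embedding** (the unweighted per-node sum of radial basis
values over incoming edges, split into same-partner and cross-partner
senders) is appended to the input scalars, and the readout is a small MLP
over the final scalars concatenated with the raw input block, so
input-level density statistics are one nonlinearity away from the score.
The readout is mean-pooled over nodes (interface-only pooling is available
as a configuration option) and passed through a sigmoid in binary mode or
reported raw in continuous mode.

Because every path from coordinates to the score factors through invariant
scalars, spherical harmonics contracted by Clebsch-Gordan couplings, and
Wigner-equivariant linear maps, the score is exactly invariant under rigid
motion of the whole complex — the test suite checks `< 1e-4` over random
rigid transforms and in practice observes machine precision, since all
arithmetic is double precision.

## Convention choices in the rotation-order algebra

Real spherical harmonics are used with a fixed component order
$m = -l..l$; the order-1 harmonic of a direction $(x, y, z)$ is
$(y, z, x)$, and each order's vector has unit Euclidean norm for every
direction. Wigner matrices are built from the ZYZ Euler decomposition with
closed-form z-rotation blocks and a frozen y/z basis-exchange involution;
the Clebsch-Gordan tensors for all 15 triangle-valid $(l_1, l_2, l_3)$
triples at $l \le 2$ were derived once as the null space of the
equivariance constraint and are hard-coded at full precision, normalized to
unit Frobenius norm with the first nonzero entry positive. Under this
normalization the $(1,1,0)$ path is the Euclidean dot product divided by
$\sqrt 3$ and the $(1,1,1)$ path is the cross product scaled by
$-1/\sqrt 6$. The message layer uses an 11-path subset of the 15 (every
output order is reachable from every sender order; the four highest-cost
$l=2 \times l=2$ mixing paths are omitted to bound the per-edge work);
the exported `tensor_product()` supports all 15.

Degenerate edge directions (two residues at identical coordinates, as can
happen in badly clashed decoys) are replaced by a fixed +z unit vector with
a warning, keeping training robust.

## Ground-truth quality

`quality_report()` computes, for a decoy against its native:

* **fnat** — the fraction of native cross-partner residue contacts (any
  heavy-atom pair within 5 Å) preserved in the decoy; a native with no
  contacts is an error, not 0.
* **iRMSD** — backbone (N, CA, C, O) RMSD over native interface residues
  (any heavy atom within 10 Å of the other partner) after optimal (Kabsch)
  superposition of those atoms.
* **LRMSD** — backbone RMSD of partner b after superposing on partner a's
  backbone only.
* **CAPRI class** — high / medium / acceptable / incorrect by the standard
  thresholds on (fnat, iRMSD, LRMSD); the binary training label is 1 iff
  the class is acceptable or better.
* **DockQ** — $(\mathrm{fnat} + 1/(1+(\mathrm{iRMSD}/1.5)^2) +
  1/(1+(\mathrm{LRMSD}/8.5)^2))/3$, with $\ge 0.23$ counted as a "hit".

For the distillation-style continuous mode, the regression target is the
AlphaFold-Multimer ranking confidence $0.8\,\mathrm{ipTM} +
0.2\,\mathrm{pTM}$ plus the decoy's DockQ, giving a target in $[0, 2]$.

## The synthetic decoy generator

`make_native()` builds two idealized helical mini-proteins (3.8 Å
consecutive-CA spacing with a small seeded jitter; N, C, O and CB placed by
ideal local frames) with random sequences, and docks the second against the
first so that at least 5 cross-partner residue pairs have heavy atoms within
5 Å while no CA pair comes closer than 3.5 Å. `make_decoys()` then applies a
graded rigid-body noise ladder to partner b — rotations about the interface
centroid by 0°, 5°, 15°, 60°, 180° paired with translations of 0, 1, 4, 15,
60 Å — cycling through the rungs. The default study conditions are 20
natives with 20 decoys each and chains of 16 and 12 residues, split 70/15/15
by native (never by decoy), so no native contributes to more than one
split. The zero rung reproduces the native (DockQ 1, class high); the
largest rung always destroys all contacts (incorrect); the middle rung
straddles the acceptable/incorrect boundary, which is what makes the
learning task non-trivial.

What the generator deliberately does **not** emulate: side-chain rotamers
and packing, backbone flexibility and refinement, sequence realism or
evolutionary signal in the embeddings, and redundancy structure beyond the
native-identity grouping. Passing the learning checks here therefore shows
that the architecture, labels, optimization and evaluation plumbing work
end to end on controllable geometry — not that the model would reach any
particular accuracy on experimental docking sets.

## Training

Binary mode minimizes cross-entropy on the acceptable-or-better label;
continuous mode minimizes mean-squared error on the confidence-plus-DockQ
target. Optimization is Adam at learning rate 1e-3 with default moment
coefficients and batches of 4 graphs, with global gradient-norm clipping at
5 and the best-validation-loss checkpoint returned. Defaults are 8 epochs —
validation loss plateaus after roughly 4 on the synthetic task — and a
train-time dropout of 0.6 on the identity channels (one-hot and embedding
blocks), which measurably improves transfer to unseen natives since in the
synthetic world those channels carry no label signal. A DropEdge-style
edge-subsetting option exists (`edge_dropout`) but is off by default, having
shown no benefit. Everything is reproducible bit for bit given the seed.

The two-stage curriculum used for the published systems (pretrain on one
decoy source, fine-tune on another) is expressed operationally — train,
then continue from a checkpoint on a second dataset — rather than as
bespoke machinery.

## Evaluation stack

Thresholds for every curve are the distinct observed scores in descending
order, with "score ≥ threshold" predicting positive. AUC is the trapezoid
area (equal to the Mann-Whitney pair statistic on tie-free data); average
precision is the step sum $\sum_n (R_n - R_{n-1}) P_n$ with $R_0 = 0$; MCC
with a zero denominator is defined as 0; top-N ties are broken by stable
input order; ensembling min-max normalizes each system's scores to [0, 1]
before averaging (the ensembled systems have incommensurate scales);
DeLong's test uses placement values with a two-sided normal p-value and
Bonferroni correction by multiplication.

## Known limitations

* The CA-only residue-level representation cannot see side-chain geometry;
  heavy atoms are retained solely for the quality metrics.
* On the default desk-scale conditions (20 natives, 14 of them for
  training), the binary scorer's held-out pooled AUC averages roughly
  0.85-0.92 across dataset seeds. The ranking information is present in the
  data — a logistic model on four hand-crafted cross-partner contact
  statistics (counts within 5/6/8 Å and the minimum cross distance) reaches
  about 0.96 on the same splits — and the network matches it on validation
  natives, but with so few training groups the learned statistic transfers
  imperfectly to test natives, concentrated in the 15°/4 Å rung where
  labels flip on fine contact detail. Scaling the number of natives up is
  the lever a larger study would pull; the desk-scale default is kept so
  the full pipeline runs in minutes.
* The DeLong variance check against a paired bootstrap is itself
  stochastic; agreement is asserted at 25% relative error with a fixed
  seed.
* The CLI writes one PDB per decoy; at desk scale this is a few hundred
  small text files, not a storage-efficient format.
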