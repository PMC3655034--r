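---
title: "Protein structure idealization in dihedral-angle space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein structure idealization in dihedral-angle space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protideal)
```

## The problem

High-resolution protein structures show that bond lengths and bond angles of
a given chemical type cluster tightly around their means (spreads of roughly
0.02 Å and 1.5–2.7°).  An *idealized* structure fixes every bond length and
angle at its tabulated mean, so the entire conformation is determined by
dihedral angles plus a rigid-body frame — about one tenth of the Cartesian
degrees of freedom.  Given an experimental target structure, `protideal`
finds an idealized structure that is simultaneously protein-like (favorable
backbone torsions) and close to the target.

## The backbone score

For a candidate idealized structure $P$ and target $P_0$, the backbone score
is

$$S_{BB}(P) \;=\; S_f(P) \;-\; w_1 D_\alpha(P, P_0) \;-\; w_2 D_\beta(P, P_0)
\;-\; w_3 D_H(P, P_0) \;-\; w_4 D_{\Phi,\Psi}(P, P_0),$$

with all weights 1 by default, where

* $S_f$ is a Ramachandran log-odds free-energy proxy: the $(\Phi,\Psi)$
  plane is discretized into $360 \times 360$ 1° bins per amino-acid type,
  and each interior residue contributes
  $\ln\,[P_{aa}(\Phi,\Psi) / (1/129600)]$;
* $D_\alpha$ and $D_\beta$ are the frame-fixed RMSDs of the C$\alpha$ and
  C$\beta$ atoms (no superposition — candidates are generated in the
  target's coordinate frame, which is what makes the score additive over
  chain segments);
* $D_H$ is the frame-fixed RMSD of the amide H and carbonyl O atoms that
  participate in the *target's* hydrogen bonds, detected once with the
  Kabsch–Sander electrostatic criterion
  ($E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) <
  -0.5$ kcal/mol, donors never proline, sequence separation $\ge 2$).
  Holding the target's atom set fixed keeps the term additive and
  expresses what the term is for: conserving the target's hydrogen bonds;
* $D_{\Phi,\Psi}$ is the RMSD of wrapped per-residue $(\Phi,\Psi)$
  differences.

### Units of the angular terms

The distance terms are combined with uniform weights, so their units must
be commensurate.  Angular squared deviations ($D_{\Phi,\Psi}$, and $D_\chi$
for side chains) are accumulated in **radians**: a typical noisy-target
angular deviation (tens of degrees ≈ tenths of a radian) then weighs
comparably to the Ångström-scale positional RMSDs.  Had degrees been used
with unit weights, the angular term would dominate by two orders of
magnitude and the optimizer would simply freeze the target's (noisy)
torsions, defeating the free-energy term entirely.  All user-facing reports
still print degrees.

## Candidate generation and the dynamic program

Backbone atoms (N, C$\alpha$, C per residue) are chained one at a time with
exact ideal internal coordinates; only torsions vary:

* atom 1: all $\varepsilon$-lattice points within radius $r$ of the
  target's first N (defaults $r = 1.6$ Å, $\varepsilon = r/5$); the lattice
  is anchored at the target's bounding-box corner;
* atom 2: the ideal-bond-length sphere around each atom-1 candidate,
  Fibonacci-sampled at arc spacing $\approx \varepsilon$;
* every later free atom (C via $\Phi$, N via $\Psi$): the ideal-geometry
  circle around its predecessor, swept at arc spacing $\approx
  \varepsilon$, i.e. $\lceil 2\pi\rho/\varepsilon \rceil$ samples for a
  circle of radius $\rho$;
* every C$\alpha$: at most two candidates, because the peptide torsion
  $\Omega$ is rounded to 180° (trans) or 0° (cis).  Cis is tried for
  proline always, and for other residues only when the target's own
  $\Omega$ lies within 30° of 0 — unrestricted cis doubling would waste
  beam width on conformations the data do not support.

Only the first atom is confined to the radius-$r$ ball; later atoms are
constrained implicitly through chain geometry.  Coordinates are **never
snapped** to the lattice — the lattice is purely a dedup/key device — so
every emitted structure satisfies the ideal-geometry invariant to 1e-6
(verified by tests on every output path).

The search is a dynamic program over prefixes.  Its state is the *tail
signature*: the $\varepsilon$-cell indices of the last $k$ atoms
($k = 5$ by default, and $k \ge 5$ is required so that the previous
residue's $(\Phi,\Psi)$ — the inputs of the score terms emitted at each
C$\alpha$ — are functions of the tail alone).  Two prefixes with the same
signature are interchangeable up to $O(\varepsilon)$ score differences, so
only the higher-scoring one is extended.  After deduplication the beam is
pruned to the top $m$ prefixes by prefix score ($m = 50{,}000$ by default;
the desk-scale experiments below use smaller beams).

Each score term is emitted at the first atom at which it is computable
from the $k$-atom window: the C$\alpha$ deviation at the C$\alpha$ itself;
the C$\beta$ deviation at the residue's C (C$\beta$ is built from N,
C$\alpha$, C); hydrogen-bond O/H deviations at the atom completing their
construction (the next residue's N, or the chain terminus); log-odds and
$(\Phi,\Psi)$ deviations at the C$\alpha$ that closes the previous
residue's angle pair, skipping residues whose $\Phi$ or $\Psi$ is
undefined (the chain termini).  Partial sums (squared deviations, counts,
log-odds) add across disjoint segments, so prefix scores combine exactly —
the additivity is tested against monolithic re-scoring to 1e-9.

Determinism: every tie (equal scores, equal keys) is broken
lexicographically by tail key and then generation order, so identical
inputs give bit-identical outputs.

## Side chains

With the backbone fixed, side chains are placed residue-by-residue,
independently (the score has no inter-residue side-chain terms, so the
optimum factorizes).  Side-chain atoms beyond C$\beta$ are built from an
internal-coordinate tree per residue type; ring torsions are fixed
(planar), branch atoms ride their defining $\chi$ with a fixed offset, and
arginine's two terminal guanidinium torsions are fixed at 0°/180° — so
each residue has at most four free $\chi$ angles.  For every rotamer of
the residue (from a backbone-dependent Dunbrack-format library if
supplied, else the packaged coarse backbone-independent table), each
$\chi$ is swept over mean $\pm 3\sigma$ in 10° steps, and the exhaustive
maximum of

$$S_{SC} = S_f^{\chi} - w_1\,D_{sc} - w_2\,D_\chi$$

is kept, where $S_f^\chi$ is a rotamer-density log-odds (rotamer
probability times independent Gaussians per $\chi$, against a uniform
null of $1/360$ per degree of freedom; the nearest rotamer under wrapped
$\chi$ distance is used), $D_{sc}$ is the frame-fixed RMSD over
side-chain heavy atoms present in the target, and $D_\chi$ the wrapped
$\chi$-difference RMSD (radians).  Missing target side chains drop the
distance terms.  Steric clash terms are deliberately absent — the
independence assumption excludes them.

## Iterative refinement

`refine()` repeats the backbone pass `n_iter` times (default 3), shrinking
both $r$ and $\varepsilon$ by 0.5 each round.  Candidate generation
re-centers on the previous iterate, whose backbone is also injected into
the beam (and protected from pruning), so the score is non-decreasing by
construction; scoring always remains against the *original* target — the
goal is similarity to the input, not to the incumbent.  Iteration stops
early once the score improves by less than 1e-6.  The final side-chain
pass shrinks the $\chi$ window and step by the same factor.

## Synthetic data and what the tests show

The package ships a deterministic generator used throughout the tests:

* `make_ideal_peptide()` builds exactly-ideal peptides at prescribed
  torsions (canonical α-helix −57/−47 by default), with optional side
  chains at prescribed $\chi$;
* `perturb()` adds i.i.d. Gaussian noise per coordinate — the simplest
  model of a target whose ideal ancestor is known, giving a
  parameter-recovery surface;
* `make_toy_tables()` builds Ramachandran tables from synthetic torsions:
  per amino acid, 20,000 samples, 60% in a helix basin centered at the
  canonical (−57, −47) with 8° spread and 40% in a sheet basin at
  (−120, 130) with 15° spread.  20,000 samples make in-basin bin counts
  dominate the unit pseudocount, giving a smooth, informative log-odds
  surface at the 1° bin scale.

The desk-scale experiments are sized for minutes on one CPU: the recovery
study idealizes an 8-residue helix perturbed at $\sigma = 0.3$ Å with
$r = 1.6$, $\varepsilon = 0.32$, beam 2000 and three shrink rounds; the
exhaustive cross-check enumerates all ~3,000 candidate chains of a
2-residue problem at $\varepsilon = 2$ Å and verifies the DP (unbounded
beam, exact tail keys) reproduces the optimum to 1e-9.  These sizes are
the package's chosen study conditions, not features of the method.

What passing these tests shows: the generator and optimizer are exactly
inverse-consistent on ideal inputs; the DP's incremental additive scoring
is exact; recovery beats both the raw noise and the rounded-torsion
baseline.  What they do not show: behavior on real crystallographic noise
(anisotropic, correlated along the chain), long multi-domain chains, cis
prolines in real frequency, or the quality of the toy probability tables
as stand-ins for tables trained on curated high-resolution sets — for real
use, build tables from a non-redundant high-resolution PDB subset with
`build_rama_table()` and supply a Dunbrack backbone-dependent rotamer
library to `read_rotamer_library()`.

## Numerical choices and degenerate inputs

* Torsions follow the IUPAC sign convention, degrees in all interfaces;
  bins over $(\Phi,\Psi)$ are half-open, $[k, k+1)$°, with +180 wrapping
  to the −180 bin (bin indices are computed modulo 360 to guard against
  floating-point wrap at the seam).
* Ideal values are the Engh–Huber means, shipped as a plain-text table
  with per-residue overrides for Gly/Pro (and Ala C$\beta$); users may
  supply their own table.
* C$\beta$ is placed by intersecting the two cones defined by the ideal
  N–CA–CB and C–CA–CB angles, taking the L-chirality branch
  (improper dihedral N–C–CA–CB ≈ −122°).
* O is placed in the peptide plane trans to the next N; H in the peptide
  plane trans to the carbonyl O; chain termini use the same in-plane rule
  with the only available neighbor, and no OXT is built.
* Proline gets no amide H (and so never donates a hydrogen bond); glycine
  gets no C$\beta$ (and contributes no $D_\beta$ term).
* An empty atom selection (e.g. $D_H$ with no detected hydrogen bonds)
  contributes an RMSD of exactly 0 — the neutral element of the score.
* Residues missing backbone atoms are dropped on input with a message;
  when chain breaks remain (peptide C–N distance over 2 Å), the longest
  gapless fragment is kept and renumbered 1..n with the original
  numbering preserved in a sidecar mapping.
* Alternate locations resolve to the highest occupancy, ties
  alphabetically; hydrogens in the input are ignored and rebuilt.
* Five-membered rings (His, Trp, Pro) are built as trees with fixed ring
  torsions; the ring-closing bond is implied rather than constructed, so
  closure is near-exact for the tabulated angles.  Proline's ring closure
  onto N is approximate in the same sense and its two $\chi$ angles are
  searched like any other.

## Known limitations

* The tail-signature interchangeability assumption can fail in
  adversarial geometries; such counter-examples are rare and no detection
  is attempted.
* The beam is a heuristic: with small $m$ the DP can return a
  score-suboptimal path (monotonicity in $m$ is guaranteed and tested).
* Hydrogen-bond conservation compares atom positions of the target's
  bond set; it does not re-detect bonds on candidates during the search
  (the evaluation report does re-count them).
* The side-chain independence assumption ignores steric clashes.
* External free-energy evaluation (e.g. dDFIRE) and secondary-structure
  typing are out of scope; the package computes everything it reports.
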