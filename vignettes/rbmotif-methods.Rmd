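---
title: "Ensemble RBM analysis of secondary-structure boundary motifs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble RBM analysis of secondary-structure boundary motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmotif)
```

## The problem

Short amino-acid stretches at the boundaries of secondary-structure
elements — the first or last $\Gamma = 5$ residues of an $\alpha$-helix or
$\beta$-strand — carry characteristic sequence patterns: amphiphilic
alternation of polar and nonpolar residues (period $\approx 2$ in helices,
period 1 in strands), helix-starting proline, alanine-rich helix endings.
`rbmotif` compresses such stretches into a handful of interpretable hidden
bits with restricted Boltzmann machines (RBMs), stabilises the
interpretation by training an *ensemble* of machines and keeping only the
hidden units that all of them agree on, and reads amino-acid similarity out
of the learned weights.

## The model

A stretch of $\Gamma$ residues is one-hot encoded over the 20-letter
alphabet with spin values: residue $k$ at position $\gamma$ sets visible
unit $i = 20(\gamma-1)+k$ to $+1$ and the other 19 units of the block to
$-1$, giving $N_v = 20\Gamma$ spins.  With hidden spins
$h_j = \pm 1$, $j = 1..N_h$, the model weight of a configuration is
$\exp(-E)$ with

$$E(v, h) = -\sum_i a_i v_i - \sum_j b_j h_j - \sum_{ij} w_{ij} v_i h_j .$$

Both conditionals are closed-form.  The $v \to h$ step is independent
per unit, $p(h_j = +1 \mid v) = e^{u_j} / (2\cosh u_j)$ with
$u_j = b_j + \sum_i w_{ij} v_i$.  For $h \to v$, each residue block is
drawn independently as a categorical over its 20 candidates with
probability $\propto \exp(2\varphi_k)$, where
$\varphi_k(h) = a_k + \sum_j w_{kj} h_j$ is the local field.  The factor 2
deserves a note: switching the block's $+1$ from residue $l$ to residue
$k$ changes the energy by $2(\varphi_l - \varphi_k)$ because one spin goes
up *and* one goes down; the shared $-\sum_{i \in \text{block}} \varphi_i$
background cancels in the conditional.  It does **not** cancel in
$h$-marginal quantities: the exact log-partition implemented in
`exact_log_partition()` is

$$\log Z = -\sum_i a_i + \log \sum_h \exp\Big[(b - c)\cdot h +
\sum_\gamma \log \sum_{k \in I(\gamma)} e^{2\varphi_k(h)}\Big],
\qquad c_j = \sum_i w_{ij},$$

where the $(b - c)\cdot h$ term is the one-hot background acting as an
effective hidden bias.  This form (and everything else that enumerates the
$2^{N_h}$ hidden states: the exact marginal, exact sequence generation,
`exact_loglik_grad()`) is verified in the test suite against brute-force
enumeration of all $20^\Gamma \cdot 2^{N_h}$ configurations on tiny models
to $10^{-10}$.  Enumeration-based operations are limited to
$N_h \le 12$.

## Training

`rbm_train()` maximises the data likelihood with contrastive divergence:
the positive statistics use the exact conditional expectations
$\tanh(u_j)$ (Rao–Blackwellised); the negative statistics come from chains
advanced by $n$ alternating block-Gibbs sweeps — CD-$n$ from the data, or
PCD-$n$ with chains that persist across updates.  Visible updates are
always blockwise-categorical, so chains never leave the one-hot manifold.
Updates go through Adam (default learning rate $5\times10^{-3}$, decays
0.9/0.999, minibatch 128).  Weights start i.i.d. Gaussian
(`init_scale = 0.01`), biases at zero.

Training quality is monitored by the pseudo-log-likelihood
$\mathrm{PLL} = \big\langle \sum_\gamma \log p(k_\gamma \mid v_{-\gamma})
\big\rangle$, computed *exactly* per residue block by renormalising the
free energy $F(v) = -a\cdot v - \sum_j \log 2\cosh u_j(v)$ over the 20
candidates of the block.  A uniform model gives $\Gamma\log(1/20)$
($\approx -14.98$ nats at $\Gamma = 5$).  For speed the per-epoch monitor
uses a capped subsample (`pll_samples`, default 2000); `pseudo_log_likelihood()`
on the full data is available whenever the exact value is wanted.

### Two optimisation traps worth knowing about

Working with planted ground-truth models exposed two stationary traps of
CD-with-Adam on this architecture, which motivated the defaults:

* **Dead units.** If the single-site means are already matched (e.g. after
  initialising the visible bias at the data log-odds), $w_j = 0$ is a
  stationary point, and Adam's sign-like normalised steps turn the tiny
  curvature signal into a random walk: the unit stays dead.  The default
  therefore starts the visible bias at zero — the large, structured
  mean-learning transient reliably carries every unit away from the
  saddle.
* **Units wasted on means.** Conversely, a dataset with extremely skewed
  single-site marginals can trap a unit *in* the mean-modelling role
  (frozen $h_j$, weights mimicking abundances).  A larger step size
  (`learning_rate = 1e-2`) and more epochs, or
  `init_visible_bias = TRUE`, both free it.
* Identical hidden units are a third, milder failure: with a very small
  `init_scale` all units follow the same dominant gradient direction and
  can converge as exact copies.  The ensemble machinery makes this visible
  (one group where there should be several).

## The ensemble and the consensus model

`train_ensemble()` trains $R$ independent realizations (default mirrors
the method's standard operating point, $R = 30$; the bundled analyses use
$R = 10$ for tractability).  Realization $r$ derives its seed as
`seed + r`, controlling both its own 80/20 train/validation split and its
initialisation — so realizations differ exactly the way the method
prescribes, and every result is reproducible from one base seed.

All $R \cdot N_h$ hidden units are pooled and compared by the Euclidean
distance between weight vectors.  Because the model is invariant under the
gauge flip $(w_{\cdot j}, b_j, h_j) \to -(w_{\cdot j}, b_j, h_j)$, two
units can be identical up to sign; by default distances are computed as
$\min(\lVert w_j - w_m \rVert, \lVert w_j + w_m \rVert)$ and members of a
group are sign-aligned to their largest-norm member before averaging
(`sign_align = FALSE` disables both).  Without alignment every planted
mode shows up as two antipodal clusters.

Units are grouped by DBSCAN (implemented in the package: core points have
`min_samples` neighbours within `eps`, groups are eps-connected components
of core points, the rest is noise).  Defaults are scale-free:
`min_samples = max(3, R/3)`, and `eps` is derived from the sorted
`min_samples`-nearest-neighbour distance curve by a *gap* rule — cut just
above the last value before the first large (3×) multiplicative jump in
the curve's upper half, or just above the curve's maximum when it is
smooth.  The textbook alternative, the knee (maximum-curvature point) of
the same curve, fails in precisely the regime a healthy ensemble
produces: when every unit belongs to a group, the between-group
separation never appears in the kNN curve at all, so the knee lands
inside the within-group spread and shears off the slowest-converging
group's members.  The gap rule instead lets between-group distances do
the separating (they are typically an order of magnitude above any
within-group spread) and reserves the cut for units that genuinely have
no neighbourhood.  Both parameters are overridable.  `build_arbm()` then averages sign-aligned weights within
each group, sign-aligned hidden biases over group members, and visible
biases over all realizations, yielding the consensus "average RBM".

`scan_model_complexity()` repeats ensemble + clustering over a range of
$N_h$ and recommends the largest $N_h$ whose group count equals $N_h$
with noise fraction below a threshold (default 0.1) — the most complex
model on which the ensemble still agrees unit-for-unit.  Past that point
the validation PLL plateaus while groups fragment or turn to noise.

## Reading the consensus model

`state_decomposition()` expands the aRBM into its $2^{N_h}$ hidden
states: each state $s$ induces a $20 \times \Gamma$ column-stochastic
residue table $P_s$ (`state_tables()`), and its frequency $f_s$ is the
dataset average of the posterior $\prod_j p(h_j = s_j \mid v)$ — the
model prior $p(h)$ is reported alongside.  States are ranked by
decreasing $f_s$ (ties broken by lexicographic state order) and labelled
`S1`, `S2`, ….  The mixture $\sum_s f_s P_s$ must reproduce the
empirical single-site frequencies if the model fits; `compare_frequency_tables()`
quantifies the match as per-position total-variation distance.  The
classical baseline, the $(20\Gamma)^2$ two-site correlation matrix of
one-hot indicators, is provided for comparison
(`two_site_correlations()`).

`arbm_weight_pca()` reshapes each group's weight vector into a
$20 \times \Gamma$ matrix (rows = amino acids) and runs a PCA with the
20 amino acids as observations and the $\Gamma$ positions as variables.
PC1 typically orders residues by how strongly they commit to the
hydrophobic or hydrophilic slots of the amphiphilic alternation — an
*effective hydrophobicity*.  PC1's sign is chosen so its Pearson
correlation with a hydrophobicity scale is non-negative (raw sign and
orientation are both kept).  The shipped scale is the Fauchère–Pliška
(1983) octanol/water side-chain partition scale, on which Trp is the most
hydrophobic residue and Arg/Lys the least; any two-column TSV can replace
it.  When the clustering is supplied, the reported explained variances are
the mean of the per-member-unit explained fractions, matching how an
ensemble-averaged variance should be read; the group-matrix fractions are
kept separately.

## Synthetic data: what it emulates and what it does not

`planted_spec()` / `make_planted_rbm()` / `sample_planted()` build RBMs
with hand-planted structure and sample from them *exactly* (enumerate
$2^K$ hidden states, then block-categorical draws — no burn-in).  The
default emulates the mode structure observed at real boundaries: two
period-2 polarity-alternation units in opposite phase (odd positions
`{1,3,5}` and even `{2,4}`, amplitude 1.0, residue pattern $+1$ on the
hydrophobic class C,F,I,L,M,V,W,Y and $-1$ on the polar class
D,E,H,K,N,P,Q,R,S,T, with Ala/Gly neutral) and an Ala-vs-Gly mode across
all positions (amplitude 1.2).  The amplitudes order the three modes
strictly by strength — odd alternation, then even alternation, then the
Ala mode.  That ordering is not cosmetic: when an RBM has fewer hidden
units than there are planted modes, each training realization keeps the
modes it can afford, and only a strict strength ordering makes all
realizations keep the *same* subset; with near-tied modes the ensemble
splits between subsets and under-capacity group counts lose their
meaning.

Three design constraints matter and are easy to violate:

* a unit whose mask covers a single position adds nothing an adjusted
  visible bias cannot express — planted units must create
  *cross-position* correlation;
* units sharing one residue pattern and differing only by masks sum to a
  single global-polarity direction, and the maximum-likelihood fit is then
  degenerate (collapsed duplicate units match the planted likelihood);
  the default units are mutually orthogonal in weight space instead;
* the one-hot $-1$ background makes $-c_j = -\sum_i w_{ij}$ act as an
  extra hidden bias, so `planted_spec()` hidden biases are specified in
  the background-absorbed gauge and `make_planted_rbm()` adds $c$ back.
  Without this, any unbalanced residue classification pins
  $p(h_j = +1)$ near 1 and the planted modes never alternate.

Distinct default hidden biases (0.5, −0.3, 0.5 in the absorbed gauge)
give the $2^3$ hidden states a unique frequency ranking, so
rank-by-frequency labelling is exercised meaningfully.
`mode_mixture_spec()` / `sample_mode_mixture()` provide a simpler
generator — draw a latent mode, then independent per-column residues —
with three amphiphilic default modes at probabilities 0.5/0.3/0.2 and a
10% uniform-noise floor.

What the generators do *not* emulate: real boundary stretches have
position-specific biases far richer than the planted zeros (Pro at helix
starts, Gly avoidance), long-range dependence on the rest of the protein,
database redundancy, and annotation noise.  Tests passing on planted data
therefore demonstrate that the machinery recovers structure *when the
model family is correct*, not that five residues of real protein are
RBM-distributed.

## Problem sizes and numerical choices

The bundled analyses (test suite and `scripts/acceptance.R`) run at
deliberately modest sizes chosen as the smallest at which the studied
effects are stable: planted $K = 3$, $\Gamma = 5$, $n = 50\,000$
stretches, ensembles of $R = 10$, a scan over $N_h \in \{1,\dots,4\}$
with CD-1, 25 epochs, minibatch 256, learning rate $10^{-2}$, weight
initialisation sd 0.1 (the larger step and init keep every unit of every
realization alive; see the traps above), PLL monitored on 1000-sample
subsets; mixture-closure checks use $n = 10^5$ exact draws.  Other
numerical choices: block softmaxes and $\log 2\cosh$ are computed in
overflow-safe shifted form; `eps = 0` distances and degenerate
(all-rows-equal) PCA inputs raise errors rather than returning nonsense;
diverged realizations (non-finite parameters) are dropped from ensembles
and counted, never retrained, so seeds keep their meaning.

## Limitations

* Exact partition functions, state decompositions and exact generation
  enumerate $2^{N_h}$ states and stop at $N_h = 12$; no annealed
  importance sampling is provided for larger models.
* The clustering defaults (gap-rule `eps`, `min_samples = max(3, R/3)`)
  are heuristics; pathological ensembles may need manual `eps`.
* CD-1 with Adam can leave hidden units collapsed or dead on hard
  landscapes (see the traps above); the ensemble analysis is the intended
  diagnostic, not a cure.
* DSSP parsing supports the classic column format only, and
  secondary-structure classes are strict (`H` for helices, `E` for
  strands); 3-10 helices (`G`) and bridges (`B`) are never merged in.
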