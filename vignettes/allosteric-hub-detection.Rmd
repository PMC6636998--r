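---
title: "Detecting allosteric hub fragments from coarse-grained MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allosteric hub fragments from coarse-grained MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allohubr)
```

## The problem and the model

Allosteric regulation transmits the effect of a ligand binding at one site
to a distal functional site. In many enzymes — pyruvate kinase M2 is the
motivating example, where fructose 1,6-bisphosphate activates and
phenylalanine inhibits catalysis without large conformational changes — the
signal travels through subtle, correlated backbone motions rather than a
rigid-body rearrangement. `allohubr` detects the residues ("hub fragments")
that carry such a signal, from Cα molecular-dynamics trajectories of the
protein in two liganded states.

The method works on a discretised representation of backbone geometry:

1. **Structural-alphabet encoding.** Every overlapping 4-residue window of
   each chain is assigned the letter of a prototype 4-Cα fragment library
   (25 letters by default) with minimal Kabsch RMSD. A trajectory becomes a
   stacked alignment: frames × fragment positions of letters.
2. **Coupling networks.** For every pair of fragment columns $C_i, C_j$ the
   normalised mutual information is computed per trajectory block $B$:
   $$ I^n_B(C_i;C_j) = \frac{I_B(C_i;C_j) - \varepsilon_B(C_i,C_j)}{H_B(C_i,C_j)},
   \qquad \varepsilon_B = \frac{B_{ij}^* - B_i^* - B_j^* + 1}{2N}, $$
   with plug-in mutual information $I_B$ and joint entropy $H_B$ in natural
   logarithms, and $\varepsilon_B$ the first-order finite-sample bias of the
   plug-in estimator ($B^*$ counts occupied joint/marginal states, $N$ is the
   block's frame count). Values are clamped to $[0,1]$; two constant columns
   have $I^n = 0$ by convention.
3. **Conformational substates.** Each trajectory is cut into contiguous,
   equal-length blocks (20 in the reference protocol) and the per-block
   matrices are compared in time order with the covariance overlap
   $$ \Omega_{A;B} = 1 - \sqrt{\frac{\operatorname{tr}A + \operatorname{tr}B
      - 2\operatorname{tr}(A^{1/2}B^{1/2})}{\operatorname{tr}A +
      \operatorname{tr}B}}, $$
   a spectral similarity that is 1 for identical and 0 for orthogonal
   matrices. Contiguous runs of mutually similar blocks
   ($\Omega \ge$ threshold against the running mean) form substates, each
   with an occupancy probability. Substate matrices pooled across replicas
   and states can be compared by complete-linkage clustering on
   $1 - \Omega$.
4. **Difference network and hub calling.** Per state, substate
   representative matrices are averaged with probability weights into an
   ensemble network. Pairs are contrasted as
   $\log_2[(I^n_{holo} + c)/(I^n_{apo} + c)]$ and tested with a two-sided
   Wilcoxon rank-sum over the per-substate samples, Benjamini–Hochberg
   corrected. Fragments incident to significant pairs are hubs, ranked by
   their largest significant $|\log_2$fc$|$.
5. **Companions.** Minimal communication pathways (Dijkstra on
   $-\ln I^n$ edge costs over contact-gated fragment pairs), per-fragment
   positional entropy, Schlitter's configurational-entropy upper bound
   $S' = \tfrac{k_B}{2}\ln\det(\mathbf 1 + \tfrac{k_B T e^2}{\hbar^2}
   M^{1/2}\sigma M^{1/2})$, the allosteric coupling coefficient
   $Q = K_{ia}/K_{ia/x}$, and MSA-based suggestions of tolerated hub
   substitutions.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_blocks` | 20 | trajectory blocks per replica (20 × 20 ns in the reference protocol); MI estimates inside a block trade variance (small blocks) against temporal resolution |
| `omega_threshold` | 0.85 | covariance overlap above which consecutive blocks share a substate. The source protocol states only "a high degree of similarity", so this is necessarily a tuning parameter; it directly controls the substate count |
| `min_run` | 2 blocks | substates shorter than this merge into the more similar neighbour (suppresses single-block flicker) |
| `pseudocount` | 1e-3 | additive regulariser on nMI before the log-ratio; nMI can be exactly 0 |
| `lfc_min`, `q_max` | 2, 5e-4 | volcano-plot hub filter (log2 fold-change and BH-adjusted FDR). `p_max` switches to the raw rank-sum p filter (protocol variant "p < 0.01"); note the exact two-sided rank-sum p cannot fall below `2/choose(n1+n2, n1)`, so small sample stacks (e.g. 5 vs 5 substates, floor 7.9e-3) *require* the `p_max` route |
| `cutoff`, `min_nmi` | 0.75 nm, 0.01 | pathway edges exist only between fragment pairs in spatial contact (minimum inter-Cα distance in a reference structure) with non-trivial coupling |
| `mask_overlap` | TRUE | fragment pairs whose windows share residues (window starts ≤ 3 apart) are trivially correlated and are masked |

Units: coordinates nm (PDB Å are converted on read/write), times ns, masses
Da, information nats, entropy J K⁻¹ mol⁻¹.

## Design choices where the design was open

- **Logarithm base.** Natural logarithms throughout; only ratios of
  information quantities enter the normalised MI, so the base cancels
  downstream.
- **Clamping.** The finite-size correction can push $(I-\varepsilon)/H$
  outside $[0,1]$; values are clamped because nMI is used as a similarity
  weight.
- **Indefinite coupling matrices.** nMI matrices have zero diagonal and are
  not positive semidefinite; the overlap's matrix square roots are taken
  after clipping negative eigenvalues to zero. The clipped magnitude is
  always recorded (`psd_adjustment`); the interactive warning (clipping
  above 1% of the retained trace) is disabled inside batch segmentation and
  clustering, where hollow matrices make it fire unconditionally.
- **Substate representative.** Arithmetic mean of member-block matrices —
  unbiased and exact for a single block. Segmentation is greedy
  left-to-right against the running mean, deterministic given inputs.
- **Difference direction.** Positive log2 fold-change means the coupling
  strengthens in the second (holo) state, matching the volcano-plot
  convention of the source analysis; the Methods-text subtraction order is
  the mirror image and is recovered by swapping arguments.
- **Statistical unit.** One observation per substate representative per
  replica/protomer chain: protomer networks are treated as separate
  samples, as in the reference analysis where each protomer's network is
  presented individually.
- **Edge costs.** $-\ln(\text{nMI})$ turns multiplicative coupling along a
  path into additive cost; the source names only "Dijkstra's algorithm with
  the complete set of correlation values as input", so the contact gating
  (default first frame, 0.75 nm) and the transform are exposed parameters.
  Dijkstra is implemented with a deterministic lexicographic tie-break.
- **Schlitter formula.** The printed source equation omits the determinant
  and the ½ prefactor of Schlitter's bound, a scalar reading that is
  dimensionally untenable for a matrix argument; the canonical determinant
  form is implemented, evaluated through the eigenvalues of the
  mass-weighted covariance.
- **Superposition.** Rigid-body motion is removed (iterated least-squares
  fit to the mean structure) before the entropy covariance by default —
  configurational entropy should not count overall rotation/translation.
  Chains are *not* superposed before alphabet encoding: the letter
  assignment is superposition-invariant per fragment, so none is needed.
- **Fragment library.** The published 25-letter alphabet's coordinates are
  not redistributable here, so the bundled default is a synthetic
  stand-in: a deterministic grid of 25 4-Cα geometries with canonical
  0.38 nm virtual bonds, minimum pairwise Kabsch RMSD 0.031 nm. Any library
  can be plugged in via `load_library()`, or built from observed fragments
  by k-medoid clustering (`build_library_from_fragments()`). All pipeline
  mathematics is independent of the particular alphabet.

## What the synthetic generator emulates — and what it does not

`sim_spec()` / `simulate_alignment()` / `simulate_trajectory()` build a
stated world with analytic ground truth: chains of non-overlapping
4-residue slots whose conformers are discrete latent states; coupled slot
pairs share their state with probability $(1+\rho)/2$ (binary case), giving
the closed-form pair nMI of `analytic_pair_nmi()`; regime schedules switch
the coupling pattern over time windows; geometry is emitted by placing
prototype fragments on an extended 0.38 nm-spaced scaffold with optional
Gaussian noise. Frames are i.i.d. given the regime.

This exercises every pipeline stage — encoding fidelity, MI estimation,
substate segmentation, hub calling, pathway tracing — with known answers.
It deliberately does **not** emulate: temporal autocorrelation within a
regime, three-way or chained couplings beyond the pairwise shared-flip
model, folded tertiary structure or realistic contact topology, solvent or
force-field physics. A green test therefore establishes the correctness of
the estimators and algorithms on the model class they assume, not the
biological accuracy of any particular MD protocol.

## Numerical notes

- Letter assignment ties (two prototypes at identical RMSD) go to the lower
  library index; fragment ranking ties go to the lower fragment index.
- The encoder's inner loop uses a closed-form (trigonometric) eigenvalue
  solution of the 3×3 Kabsch cross-covariance, vectorised over all
  prototypes; it agrees with the SVD route to ~1e-11 nm and is
  property-tested against it.
- $\Omega$ is clamped to $[0,1]$ against round-off; two all-zero matrices
  are defined as identical ($\Omega = 1$). Degenerate reference fragments
  (all points identical) are rejected rather than silently superposed.
- Zero-probability contingency cells contribute 0 ($0 \ln 0 \equiv 0$);
  eps → 0 as $N → ∞$ for fixed support.
- `sim_spec()` requires a seed; the generators restore the caller's RNG
  state, so simulation is reproducible without side effects.

## Known limitations

- The reference analysis's headline numbers (72 hub fragments, 8 + 8
  substates for a 4 × ~58 kDa tetramer over 5 × 400 ns per state) are not
  reproducible at desk scale and the original trajectories are not
  deposited; validation here is property- and oracle-based on synthetic
  worlds.
- Binary MD formats (XTC/DCD) are not parsed; convert to multi-model PDB or
  a coordinate table upstream, or supply frames through the table adapter.
- The substate count is sensitive to `omega_threshold`; no attempt is made
  to infer it from the data (no HMM/changepoint machinery, by design).

## A worked miniature

```{r example, eval = FALSE}
spec_apo <- sim_spec(n_fragments = 3, chains = 5, frames = 200,
                     couplings = tibble::tibble(i = 1, j = 3, rho = 0.15),
                     seed = 1)
spec_holo <- sim_spec(n_fragments = 3, chains = 5, frames = 200,
                      couplings = tibble::tibble(i = 1, j = 3, rho = 0.9),
                      seed = 2)
dir <- tempdir()
write_pdb_multimodel(simulate_trajectory(spec_apo)$trajectory,
                     file.path(dir, "apo.pdb"))
write_pdb_multimodel(simulate_trajectory(spec_holo)$trajectory,
                     file.path(dir, "holo.pdb"))
res <- run_pipeline(pipeline_config(list(
  states = list(apo = file.path(dir, "apo.pdb"),
                holo = file.path(dir, "holo.pdb")),
  n_blocks = 4, omega_threshold = 0.5, min_run = 1,
  lfc_min = 2, p_max = 0.01)))
res$hubs$hubs          # ranked hub fragments
autoplot(res$hubs)     # volcano plot
```

The planted pair (slots at residues 1–4 and 9–12) surfaces as the top-ranked
hub fragments; every number shown by the example is recomputed at run time
by the test suite and the acceptance script.
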