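---
title: "Simulating murine EAE: model, calibration and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating murine EAE: model, calibration and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eaesim)
```

# The biological system and its abstraction

Experimental autoimmune encephalomyelitis (EAE) is a murine model of
multiple sclerosis. Immunization with myelin basic protein (MBP) primes
encephalitogenic CD4+ Th1 cells that infiltrate the central nervous system
(CNS), drive demyelination, and produce an ascending clinical course graded
0-5 (1 flaccid tail; 2 hind limb weakness; 3 hind limb paralysis; 4 whole
body paralysis; 5 death). In strains that recover spontaneously, recovery is
mediated by a regulatory circuit: apoptotic Th1 cells are phagocytosed by
dendritic cells (DCs) which present TCR-derived peptides, priming CD4+
regulatory T cells whose help licenses the DCs for CD8+ regulatory T cell
priming; effector CD8Tregs then recognize Qa-1:TCR-peptide complexes on
recently differentiated Th1 cells and kill them.

`eaesim` captures this system as a discrete-time agent simulation. Eight
cell populations (neurons, microglia, DCs, naive CD4Th, CD4Th1, CD4Th2,
CD4Treg, CD8Treg) occupy five networked two-dimensional lattice
compartments: CNS, cervical lymph node (CLN), circulation, spleen, and a
generic secondary lymphoid organ (SLO). Each compartment carries three
scalar fields — generic type-1 and type-2 cytokines and a soluble
"demyelinating agent" — subject to secretion, diffusion and decay. Cells
are stochastic state machines; receptor-dependent interactions (priming,
licensing, killing, phagocytosis, microglial activation) occur between
cells in the same or adjacent grid-spaces with per-hour hazard rates
converted to per-step probabilities.

# Disease mechanism in the model

1. **Induction.** Immunization DCs (type-1 polarized, MHC-II:MBP-presenting)
   are placed in the SLO at induction and then periodically in linearly
   decreasing numbers; shorter insertion periods are stronger immunizations
   (6 h is the control). The DCs persist for roughly two weeks
   (`dc_lifespan_mean_h = 300`), so priming of naive CD4Th cells is a slow,
   extended process rather than a burst — this is why intervening at day 4
   (onset of encephalitogenic expansion) and day 15 (after the priming wave
   has largely completed) have qualitatively different consequences.
2. **Polarization and expansion.** A primed CD4Th polarizes by the local
   type-1 : type-2 concentration ratio at the priming site (ties favour
   Th1), then undergoes `th_divisions = 4` divisions every
   `division_interval_h = 24` h. Each cell entering the effector state draws
   an activation-induced cell death (AICD) lifespan
   (normal, mean `tcell_aicd_mean_h = 92` h, clamped at zero) and — if Th1 —
   a Qa-1:TCR-peptide expression window (mean 8 h, sd 1 h).
3. **CNS damage.** Effector Th1 enter the CNS from the circulation, bind
   microglia (a TCR:MHC interaction), and activated microglia secrete the
   demyelinating agent. Neurons die with a finite hazard
   (`neuron_kill_per_h`) while their local concentration exceeds
   `neuron_kill_threshold`, and are replaced after a jittered delay. The
   neuronal death-event series is the raw material of clinical scoring.
4. **Antigen recirculation.** Neuron death releases myelin antigen taken up
   by resident CNS DCs, which drain to the CLN and prime further CD4Th.
   This feedback loop has modest gain: under full regulation it is
   clamped quickly; without regulation it sustains disease beyond the
   immunization window and re-ignites after remission, producing relapses.
5. **Regulation.** Apoptotic Th1 are phagocytosed by plain resident DCs
   (committed MBP-presenting DCs do not re-present), predominantly in the
   spleen — the model's dominant Treg priming site. Effector Tregs patrol
   blood and spleen rather than lymph nodes
   (`treg_lymphoid_entry_factor = 0.05`), so newly differentiated Th1 meet
   CD8Tregs a few hours after differentiation, while in transit. This
   geometry is what makes the Qa-1 window duration matter: at a mean window
   of 2 h most Th1 outrun their killers; at 8 h most are caught; beyond 8 h
   the opportunity saturates.

# Clinical scoring and outcome extraction

Neuronal death events are smoothed with a trailing rectangular window
(`score_window_h = 48` h; causal, so no look-ahead) and thresholded:
score(t) is the number of thresholds at or below the smoothed rate. The
first instant score 5 is reached is a death and truncates the course. An
episode is a maximal interval of score >= 1; two episodes separated by less
than 24 h of score 0 merge (in vivo scoring is daily, so sub-day remissions
are not observable); a relapse is any episode after the first. For fatal
runs the final episode extends to the end of observation.

The threshold values and window width shipped as defaults were calibrated
in-package against the two reference behaviours the simulator itself is
built to show — physiological recovery under full regulation, and laboured,
relapsing recovery with regulation abrogated — so that the control group is
monophasic with a median first episode near 10 days and moderate mortality,
and the unregulated group shows doubled mortality, ~20-day episodes and
relapses in just under half of runs. `calibrate_scoring()` exposes the full
grid-search machinery (three normalized squared criteria: score-change
frequency, maximum-score proportions, and cross-experiment threshold
agreement) so the rule can be regenerated or recalibrated against other
targets.

# Parameters that matter most

| parameter | default | unit | role |
|---|---|---|---|
| `regulatory_efficacy` | 1 | probability | kill probability per established CD8Treg:Th1 binding |
| `qa1_duration_mean_h` | 8 | h | mean Qa-1:TCR-peptide expression window (sd 1 h) |
| `tcell_aicd_mean_h` | 92 | h | effector lifespan; sets episode decay tails |
| `imm_dc_period_h` | 6 | h | immunization strength (longer = weaker) |
| `dc_lifespan_mean_h` | 300 | h | width of the priming window |
| `cns_dc_migration_per_h` | 0.16 | 1/h | antigen recirculation gain (relapse propensity) |
| `neuron_kill_threshold` | 1.0 | conc | lethal demyelinating-agent concentration |
| `score_threshold_1/5` | 0.333 / 1.46 | deaths/h | clinical onset / death cutoffs |

All hazards are per-hour rates converted with `1 - exp(-rate * dt)`, so the
step size (`dt_min = 6` simulated minutes) can be refined without
recalibrating interaction strengths. The full registry, with units and legal
ranges, is `config_registry()`.

# Interventions

Interventions are declarative plans applied to a configuration
(`intervention_plan()`, `apply_intervention()`); each touches only its
declared parameters.

* **Regulatory efficacy** scales the kill probability of a bound CD8Treg
  (100% = control; 0% = complete abrogation).
* **Qa-1 duration** moves the mean expression window in [0, 24] h, sd fixed
  at 1 h.
* **Splenectomy** (pre-induction only) replaces the spleen with a
  zero-capacity pass-through: entrants are forwarded back to the
  circulation within the same step, and splenic DCs do not exist. Because
  the spleen is the dominant Treg priming site, splenectomy weakens
  regulation and worsens outcomes.
* **Anti-CD3** multiplies every T-cell TCR binding probability by
  `1 - efficacy` from the administration day onward, persistently, for all
  T cells including Tregs. Multiplicative composition is the only reading
  that keeps probabilities in [0, 1] for all inputs. By default the
  CD8Treg's TCR:Qa-1 recognition of Th1 is also blocked
  (`anti_cd3_blocks_qa1`); it is a TCR binding even though the target is
  Qa-1 rather than classical MHC:peptide, and the treatment is modelled as
  affecting all T cells equally. A config flag exposes the alternative
  interpretation.

# Statistics and robustness analysis

The analysis layer mirrors standard practice for stochastic simulators:
the Vargha-Delaney A-test (`a_test()`, computed from midrank sums, equal to
P(x>y) + 0.5 P(x=y)) measures effect magnitude independently of sample
size, with bands at 0.56/0.64/0.71 (symmetric); the Mann-Whitney U test
(exact by enumeration for small samples, normal approximation with tie
correction otherwise) measures significance, consuming raw per-run episode
counts rather than percentages; Fisher's exact test compares mortality
tables; groups are summarized by medians and inter-quartile ranges.

The robustness analysis is strictly one-at-a-time: a parameter is swept
while all others hold their calibrated defaults, 13 responses are monitored
(peak size and time of the four T-cell populations, CD4Th1 at 40 days,
maximum and 40-day EAE score), and a significant deviation is a large
A-test effect versus control or a change of at least 1.0 in mean EAE score
(for the score responses; the two rules trigger independently). Boundaries
are the first swept value on each side of the default at which deviation
holds (`NaN` if none), indices express boundary distance as a percentage of
the default, the robustness index is the smaller of the two, and the global
table ranks parameters per response (ascending index, NaN last, average
ranks for ties) and orders by summed rank. Zero-default parameters have
undefined percentage indices; absolute distances are reported instead.

# Numerical choices

* Diffusion uses an explicit forward-Euler 4-neighbour Laplacian with
  closed (no-flux) walls for organs and toroidal wrap for the circulation;
  stability requires `D * dt <= 0.25` (enforced at validation). With zero
  decay, mass is conserved exactly under both boundary rules.
* Normal duration draws are clamped at zero (not redrawn), keeping the
  RNG draw count deterministic per stream.
* Within a step, phases run in a fixed order: immunization insertions,
  recruitment, timers/transitions, binding resolution (iteration order
  shuffled from the run's RNG stream), movement, migration, secretion and
  field updates, neuronal death check, recording. Identical configuration
  and seed reproduce a run bit-for-bit; replicate seeds derive from
  `derive_seed(master, label, i)`, so groups sharing a master seed are
  paired replicate-by-replicate for variance-reduced comparisons.
* Movement is an unbiased random walk, one Moore-neighbourhood step per
  motile cell per time step; neurons and microglia are sessile.

# Design decisions taken where the design was genuinely open

* **Compartment scale.** Lattices are compartment-specific (CNS and
  circulation 20x20, spleen 16x16, lymph nodes 12x12) with ~450 neurons.
  This scale resolves the spatial effects that matter here (local
  demyelination, adjacency-limited binding, compartment geography) while
  keeping a 50-day run around a second, so that 100-replicate groups are
  routine. Absolute population sizes are therefore model units, not murine
  cell counts.
* **Neuron death as a hazard.** A deterministic "kill at threshold" rule
  synchronized damage and regrowth into sawtooth oscillations; a finite
  death hazard while the concentration is lethal (with jittered
  replacement) yields the graded, noisy death-rate series that clinical
  scoring presupposes.
* **Demyelinating-agent source.** Activated microglia secrete the agent by
  default (Th1 license them through a TCR:MHC binding);
  `demyel_source_direct = 1` switches to direct Th1 secretion.
* **CD4Th2** is tracked as a polarization-dependent bystander readout; it
  exerts no active suppression.
* **Basal CD4Th1 tone** is represented through the homeostatic naive
  repertoire (globally censused, so recirculating cells are not
  re-recruited) rather than a separate basal effector source.

# What the synthetic generators emulate — and what they do not

`synth_death_events()` produces Poisson death-event traces from piecewise
linear intensity profiles (monophasic, relapsing, fatal) for testing the
scoring and calibration layers in isolation; `synth_two_samples()` makes
tied and continuous two-sample data for the statistics layer. They
reproduce the timing and noise character of simulated traces, not the
mechanism — passing tests on them demonstrates the correctness of the
scoring arithmetic, not the biological fidelity of the simulator, which is
assessed against the emergent group-level behaviours (mortality, relapse
and duration patterns across interventions).

# Known limitations

* The simulation is calibrated at a reduced spatial and population scale;
  quantities with physical units (concentrations, rates) are model units.
* The antigen-recirculation loop's gain is tuned so that unregulated
  disease remits around four weeks with relapses in just under half of
  runs. A consequence is that under intermediate TCR blockade (anti-CD3 at
  60-80%) the loop is subcritical and CD4Th1 populations are essentially
  cleared by day 40; the model therefore does not reproduce a rise in
  40-day CD4Th1 counts at intermediate blockade efficacies, a regime where
  blockade-prolonged effector persistence would require a stronger loop
  than is compatible with ~20-day unregulated episodes at this scale.
* There is no pharmacokinetics: anti-CD3 "efficacy" conflates dose and
  binding strength, is immediate, and persists indefinitely.
* Multiple-testing correction is deliberately not applied in the group
  comparison reports; the A-test bands carry the burden of effect-size
  interpretation.
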