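# clockloops

Which feedback loops make the mammalian circadian clock tick? `clockloops`
implements a data-driven five-gene delay-differential model of the core
circadian oscillator — *Bmal1*, *Rev-erbα* (written `Rev_erba`), *Per2*,
*Cry1*, *Dbp* — and the complete analysis chain for dissecting its rhythm
generators: limit-cycle classification, node and edge clamping with an
exhaustive 2^17 edge-configuration census, bifurcation sweeps with
period-jump and hysteresis detection, and a robustness comparison of the
Goodwin and repressilator prototype oscillators.

## The model

Each mRNA variable follows a delay differential equation

```
x_i'(t) = V_i * prod_{j -> i} F_ji( x_j(t - tau_j) ) - d_i * x_i(t)
F(y)    = (1 + s * u) / (1 + u),   u = (y / ybar)^h
```

with 17 bounded, saturating regulations (7 activating, `s > 1`; 10
inhibiting, `s < 1`), one explicit delay `tau_j` per regulator standing in
for post-transcriptional processing, and 34 kinetic parameters in total.
The network contains multiple interlocked loops, among them the serial
inhibition cycle *Per2* ⊣ *Rev_erba* ⊣ *Cry1* ⊣ *Per2* — a repressilator —
whose central role the analysis chain exposes: clamping machinery holds
genes (nodes) or single regulations (edges) at their limit-cycle mean so
they can no longer transmit rhythms, and the census asks which of the
131,072 ON/OFF configurations of the 17 regulations still oscillate.

Key user-facing functions, all returning tibbles or tidy-able objects:

| area | functions |
| --- | --- |
| model | `default_clock_model()`, `load_model()`, `write_model()`, `clock_params()`, `set_clock_param()` |
| simulation | `simulate_clock()`, `limit_cycle_means()`, `integrate_linear_dde()` |
| oscillation | `classify_oscillation()`, `detect_peaks()`, `phase_of()`, `oscillation_settings()` |
| clamping | `clamp_nodes()`, `clamp_edges()`, `edge_census()`, `edge_importance()`, `subnetwork_viability()`, `enumerate_loops()` |
| sweeps | `sweep_parameter()`, `detect_jumps()`, `hysteresis_scan()` |
| prototypes | `prototype_model()`, `minimal_hill()`, `robustness_compare()` |
| synthetic data & fitting | `generate_profiles()`, `normalize_profiles()`, `fit_clock()`, `de_optimize()` |

## Worked example

```r
library(clockloops)

model <- default_clock_model()
traj  <- simulate_clock(model, t_end = 500)   # method-of-steps RK4, 0.05 h
report <- classify_oscillation(traj)          # transient 300 h discarded
glance(report)
phase_of(report, "Per2", "Rev_erba")
```

```
# A tibble: 1 x 7
  oscillating period          cv torus damped rel_amplitude ref_gene
  <lgl>        <dbl>       <dbl> <lgl> <lgl>          <dbl> <chr>
1 TRUE          24.2 0.000000117 FALSE FALSE          0.472 Per2

[1] 10.15315
```

The default model oscillates with a circadian period; `phase_of()` gives
the peak of *Per2* about 10.2 h after *Rev-erbα*, with *Cry1* a
further 8.9 h later — the serial phase ordering of the repressilator
genes. Clamping everything except the three repressilator inhibitions
keeps the clock running, a little slower:

```r
on <- model$regulations$param %in% c("inh_3_2", "inh_2_4", "inh_4_3")
glance(classify_oscillation(simulate_clock(clamp_edges(model, on = on))))
```

```
# A tibble: 1 x 7
  oscillating period         cv torus damped rel_amplitude ref_gene
  <lgl>        <dbl>      <dbl> <lgl> <lgl>          <dbl> <chr>
1 TRUE          27.0 0.00000261 FALSE FALSE          0.535 Per2
```

A stratified slice of the edge-clamp census shows how dominant that motif
is (the full census is `clockloops census` on the command line;
`inst/cli/clockloops` is a thin Rscript wrapper):

```r
cen <- edge_census(model, config_ids = census_subsample_ids(4096, seed = 1))
mean(cen$oscillating)                          # fraction of rhythmic configs
edge_importance(cen, model) |>
  dplyr::arrange(dplyr::desc(on_frequency)) |>
  head(4)
```

```
[1] 0.1335

# A tibble: 4 x 7
    bit param   source   target   sign       label            on_frequency
  <int> <chr>   <chr>    <chr>    <chr>      <chr>                   <dbl>
1     3 inh_3_2 Per2     Rev_erba inhibition Per2 -| Rev_erba        1
2    11 inh_2_4 Rev_erba Cry1     inhibition Rev_erba -| Cry1        0.996
3     8 inh_4_3 Cry1     Per2     inhibition Cry1 -| Per2            0.984
4    13 inh_4_4 Cry1     Cry1     inhibition Cry1 -| Cry1            0.543
```

Roughly one configuration in eight oscillates, and the three repressilator
edges are ON in essentially all of them while typical edges sit near the
0.5 expected of a non-essential interaction. Prototype analysis explains
why a ring of three inhibitions is such a robust design: the classical
Goodwin chain needs a Hill coefficient of about 8 to oscillate, the
repressilator only about 2:

```r
minimal_hill("goodwin", method = "stability")
minimal_hill("repressilator", h_range = c(1, 6),
             production = c(1000, 1000, 1000))
```

```
[1] 8.017059
[1] 2.019592
```

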