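# niee

Edge-centric, model-free detection of disease tipping points from single
expression samples.

Complex diseases often progress through three stages: a stable normal state,
a critical *pre-disease* state just before an irreversible transition, and
the disease state itself. Near the tipping point, dynamic-network-biomarker
(DNB) theory predicts that a local module of genes shows sharply increased
expression fluctuation and mutual correlation. `niee` quantifies this
signature one sample at a time: it compares a single "perturbed" sample
(a patient at one time point or disease stage) against a reference cohort,
over a protein–protein-interaction background network, and scores every
network edge by how much the appended sample disturbs the local correlation
structure.

The package is for computational biologists analysing time-course or staged
expression data (e.g. infection challenge studies, tumor stages) who want
per-sample early-warning signals and a small interpretable "key local
network" of edges that drive them.

## The score

For an edge connecting genes $g_1$ and $g_2$ with degrees $\alpha$ and
$\beta$ in the background network, the edge entropy over $s$ samples is the
degree-weighted combination of the two node entropies:

$$H_E(s) = \frac{\alpha}{\alpha+\beta} H_{g_1}(s) + \frac{\beta}{\alpha+\beta} H_{g_2}(s),$$

where each node entropy is the normalized Shannon entropy of its
neighbor-weight distribution

$$H_{g}(s) = -\frac{1}{\log M}\sum_{y=1}^{M} p_{y}(s)\,\log p_{y}(s),
\qquad
p_{y}(s) = \frac{|\mathrm{PCC}_{g,y}(s)|}{\sum_{y'} |\mathrm{PCC}_{g,y'}(s)|},$$

over the gene's $M$ first-order neighbors, with Pearson correlations
computed across the samples. The edge standard deviation $SD_E(s)$ is the
same degree-weighted combination of the genes' sample standard deviations.
Appending one perturbed sample to the $s$ reference samples gives
$H_E(s+1)$ and $SD_E(s+1)$, and the differential edge score is

$$\Delta H_E(s+1) = \left|SD_E(s+1) - SD_E(s)\right| \cdot \left|H_E(s+1) - H_E(s)\right| .$$

Averaging $\Delta H_E$ over all edges gives the global score
$\Delta GH$; averaging (or summing) over a screened key local network gives
the key-local score $\Delta LH$. Edges that recur in the top 1% across
perturbed samples form the key local network, and a sharp rise of the score
trajectory relative to its running baseline is flagged as an early-warning
signal.

## Worked example

The built-in generator creates a seeded scenario with a known answer: a
50-gene background network, a 20-sample reference cohort, and a 10-point
perturbed series in which a planted 5-gene module's standard deviation
triples and its internal correlation jumps to 0.9 from time `t6` onward.

```r
library(niee)

bundle <- simulate_scenario(niee_scenario(seed = 7))
bundle$network
#> <background_network> 50 nodes, 165 edges (degree range 2-12)

results <- lapply(colnames(bundle$perturbed), function(tp)
  score_sample(bundle$network, bundle$reference, bundle$perturbed[, tp], tp))

traj <- detect_signals(niee_trajectory(results))
as.data.frame(traj)
#>    label    score  flag
#> 1     t1 0.000394 FALSE
#> 2     t2 0.000159 FALSE
#> 3     t3 0.000174 FALSE
#> 4     t4 0.000241 FALSE
#> 5     t5 0.000311 FALSE
#> 6     t6 0.000396 FALSE
#> 7     t7 0.002690  TRUE
#> 8     t8 0.002129 FALSE
#> 9     t9 0.000288 FALSE
#> 10   t10 0.000282 FALSE
attr(traj, "first_signal")
#> [1] "t7"
```

The global-score trajectory stays flat through the pre-tipping samples
(`t1`–`t5`), surges once the planted module destabilizes, and the
running-baseline detector fires at `t7` — one step after the true tipping
time. Screening each sample's top-1% edges and keeping those that recur
yields the key local network:

```r
tops <- lapply(results, top_fraction_edges, fraction = 0.01)
select_key_network(tops, min_frequency = 2)
#> <key_local_network> 2 edges (min frequency 2 of 10 sample sets)
#> # A tibble: 2 x 3
#>   gene1 gene2 frequency
#> 1 g005  g015          2
#> 2 g010  g049          2
```

Here `g010--g049` is one of the ten planted module-internal edges.
`autoplot(traj)`, `autoplot(results[[7]])` and
`plot_landscape(landscape_matrix(results, key))` visualize the trajectory,
the per-edge score distribution and the edge-by-time landscape. For
file-based pipelines, `run_simulate()`, `run_score()` and `run_keynet()`
(or the `inst/cli/niee.R` wrapper) drive the same steps from a YAML config.

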