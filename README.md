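# channelweb

Energy-channel compartment detection in quantitative food webs.

Many food webs are *compartmentalized*: subgroups of taxa interact strongly
with each other and only weakly with the rest of the web. Generic community
detection (edge betweenness, random walks) finds such subgroups but says
nothing about why they exist. `channelweb` detects compartments from an
ecological mechanism instead — the **energy channel**: the set of carbon
fluxes that originate at one basal resource (a producer or a detritus pool)
and flow up to consumers. The package is written for ecologists working with
quantitative (carbon-flux) flow networks, e.g. exports of ecosystem network
analysis models.

## The method

A web of `S` nodes is an `S×S` flux matrix `F` (g C m⁻² day⁻¹,
`F[i,j]` = flux from `i` to `j`) plus per-node biomass and boundary flows
(imports, exports, respiration). Detection proceeds in four steps:

1. **Basal reliance.** Each node's fractional reliance on every basal
   resource is the diet-weighted average of its resources' reliances,
   `%BR_C = Σ P_C · %BR_R`, where `P_C` is the diet proportion contributed by
   each resource. Basal nodes are absorbing origins (reliance 1 on
   themselves); cycles are resolved by an exact linear solve.
2. **Seed subgroups.** Every node joins the subgroup of its dominant energy
   origin; each basal node seeds one subgroup.
3. **Merge gains.** For every pair of subgroups, compute the change `ΔQ` in
   weighted directed modularity
   `Q = (1/2W) Σᵢⱼ [wᵢⱼ − wᵢᵒᵘᵗ wⱼⁱⁿ / 2W] δ(cᵢ, cⱼ)` that merging them
   would produce.
4. **Greedy merging.** Merge the best pair while any `ΔQ > 0`; stop when no
   merge improves `Q`.

Significance of the final `Q` comes from a Monte Carlo null model that
redraws every predator's prey uniformly while preserving its total intake
and prey count (column sums of `F`). Whether perturbations stay inside
compartments is tested with a bioenergetic ODE model (logistic producers,
multi-prey functional response with Hill exponent `h` and predator
interference `q`, explicit detritus pools) calibrated so the observed flows
are an exact equilibrium; the removal effect of deleting node `k` on node
`i` is `RE_i = log[(B_i⁺+1)/(B_i⁻+1)]/(B_k+1)`.

## Worked example

```r
library(channelweb)

# a synthetic web with 3 planted energy channels, weakly coupled
pw  <- generate_planted_web(channels = 3, per_channel = 5, levels = 3,
                            eps = 0.05, seed = 1)
fit <- detect_compartments(pw$net)
fit
#> <compartment_fit> 3 compartments, Q = 0.6174
#>   seeds: 3 subgroups; 0 merges accepted
#>   sizes: 5, 5, 5

mc <- modularity_significance(pw$net, fit, reps = 1000, seed = 2)
mc
#> <mc_significance> Q = 0.6174, p < 0.001 (1000 reps)
#>   null mean = -0.04893, SEM = 0.003704
```

The three planted channels are recovered exactly (`Q = 0.617`), and none of
the 1000 intake-preserving randomizations reaches the empirical modularity
(`p < 0.001`): the compartment structure is far stronger than chance. A
removal experiment then shows where a perturbation lands:

```r
params <- calibrate_dynamics(pw$net)      # observed flows = equilibrium
out    <- removal_experiment(pw$net, removed = "c1_l1_n1", params = params)
aggregate_re(out, fit)[c("within", "between")]
#> $within
#> [1] 0.01103189
#> $between
#> [1] 0.0005954225
```

The mean effect magnitude on nodes sharing the removed node's compartment
is an order of magnitude larger than on the rest of the web — the
compartments buffer perturbations.

Empirical webs enter through `read_flow_network("nodes.tsv", "edges.tsv")`
or `read_flow_json("network.json")`, usually followed by `balance_flows()`
to enforce steady state. `run_full_analysis()` chains every stage and
writes TSV/JSON reports; a command-line front-end ships at
`inst/cli/channelweb.R`.

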