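# colweb

Coarse-grained self-assembly of collagen-IV-like molecules into 2D networks,
plus a ring-statistics suite for characterising the networks that form —
whether simulated here or digitized from micrographs.

## The problem

Basement membranes such as the ocular lens capsule are built from
two-dimensional collagen IV meshworks. The molecules are ~300 nm worm-like
polymers with sticky terminal domains; *in vitro* they self-assemble into
polygonal networks whose structure depends on solution conditions. Direct
experiments are hard (the networks are fragile, and the interesting
processes span long times), so simplified computational models are used to
connect molecule-level interactions to network-level structure.

`colweb` implements such a model and its analysis stack:

* **Model** — bead–spring worm-like chains (harmonic bonds `½ kl (r−r₀)²`,
  harmonic angles `½ Kθ (θ−θ₀)²`) with patchy-particle head beads that
  attract via a 12-6 Lennard-Jones well (`εHH`, `σHH`) and body beads that
  repel below `σBB` (excluded volume). Head–body terms are zero.
* **Dynamics** — Langevin (implicit-solvent) velocity-Verlet integration in
  a periodic 2D cell (compiled core), a weak-coupling barostat stage that
  lets pressure pick the density, and the melt–cool protocol: equilibrate
  at 30 K, relax the cell at 20 Pa, freeze it, heat to 300 K (which melts
  every head bond, since `εHH = kB·300 K`), then cool over `t_cool` while
  the network self-assembles.
* **Extraction** — head-bead clusters become nodes, molecule strands become
  edges; polygons are assigned by *Delaunay merging*: triangulate the nodes
  on the torus, then remove every triangulation-only edge, merging faces,
  until only network edges remain.
* **Metrics** — polygon edge-count distributions `p(n)` and their
  maximum-entropy reference model (`p(n) ∝ exp(−λ₁n − λ₂/n)`), the shape
  regularity coefficient `SRC = solidity × balanced repartition ×
  convexity` (1 for regular shapes), polygon-size assortativity `r`,
  coordination moments `⟨k⟩`, `μ₂(k)`, edge lengths, areas, dangling-edge
  percentages, and the `(μ₂(k), r)` "network landscape".
* **Builders** — idealised honeycomb and chain-link-fence square nets at
  their energy minimum, pre-tangled molecule templates (permanent
  degree-3 crosslink sites), and periodic Poisson–Voronoi tessellations as
  the random reference (`r ≈ −0.15`).

## Worked example

```r
library(colweb)

# a desk-scale run: 10 x 10 molecules, every stage duration scaled by 0.4
cfg  <- run_config(nx = 10, ny = 10, t_cool = 150, duration_scale = 0.4,
                   seed = 1)
traj <- run_protocol(cfg)      # ~45 s
net  <- build_network(traj$final)
pol  <- delaunay_polygons(net)
network_metrics(net, pol)
#> # A tibble: 1 x 11
#>   Npolygon mean_n mean_k  mu2_k assortativity mean_SRC sd_SRC mean_l_nm
#>      <int>  <dbl>  <dbl>  <dbl>         <dbl>    <dbl>  <dbl>     <dbl>
#> 1       21   6.05   2.63  0.501       -0.0164    0.801  0.133      339.
#> # i 3 more variables: sd_l_nm <dbl>, mean_area_nm2 <dbl>, dangling_pct <dbl>
```

21 polygons formed from 100 molecules; the mean coordination number 2.63
says most head clusters bind three molecule ends (with dangling ends pulling
the mean down), the mean edge ~339 nm is a molecule plus the node offsets,
and `⟨SRC⟩ ≈ 0.80` marks visibly irregular, floppy polygons — far from the
`≈ 0.96` of rigid inorganic networks. Compare against the entropic ideal:

```r
fit <- fit_maxent(pol)
tidy(fit)          # per-n observed / fitted / residual
glance(fit)        # KL divergence, multipliers, convergence
autoplot(pol)      # polygons coloured by edge count
plot_landscape(landscape_point(net, pol))
```

The residuals show the enthalpic signature: fewer triangles (angular strain)
and more squares than maximum entropy predicts. Scans over cooling time,
pressure, well depth or tangle fraction run via `run_scan()`, and the
shipped CLI (`system.file("cli", "colweb", package = "colweb")`) exposes
`simulate / extract / metrics / maxent / scan / landscape / fixtures`
subcommands over config files.

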