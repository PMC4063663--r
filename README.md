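# plasso

Pierced-lasso topologies in proteins: detection, folding simulation, and
native-state dynamics.

A disulphide bridge closes a covalent loop in a polypeptide chain. When part
of the same chain threads through that loop, the protein carries a
**pierced lasso** — a knot-like motif whose topology is switched by redox
chemistry: oxidize the bridge and the chain is threaded, reduce it and the
"knot" falls open. In four-helix-bundle cytokines (leptin is the canonical
case, with its C96–C146 bridge closing a 50-residue lasso) this motif
couples oxidation state to folding mechanism and to the slow native-state
dynamics of the receptor-binding helix.

`plasso` is an R package for studying this class of systems end to end:

* **Topology** — classify covalent loops as zero knot, cinch, empty lasso
  or pierced lasso by counting signed crossings of the chain through a
  triangulated surface spanning the loop; report loop size, lasso terminus
  and the threaded segment (`classify_lasso()`, `scan_candidates()`).
* **Models** — build Calpha structure-based (Gō-type) models with the
  native-centric Hamiltonian

  `V = Σ (k_b/2)(r−r0)² + Σ (k_a/2)(θ−θ0)² + Σ k_d¹[1−cos(φ−φ0)] + k_d²[1−cos3(φ−φ0)]`
  `    + Σ_contacts ε[(1+(σ/r)¹²)(1−G(r)) − 1] + Σ_nonnative (σ/r)¹²`

  with `k_b = 2×10⁴ ε/nm²`, `k_a = 40 ε/rad²`, `k_d¹ = ε`, `k_d² = 0.5ε`,
  `σ = 4 Å`, and a Gaussian well `G` anchoring each native contact at `−ε`.
  The disulphide enters as an unbreakable bond (oxidized), a breakable
  native-like contact (dynamic), or not at all (reduced)
  (`build_contact_map()`, `build_topology()`).
* **Sampling** — BAOAB Langevin dynamics (`dt = 0.005`, thermostat time
  constant 2, reduced units with `k_B = 1`), NVE validation, and umbrella
  sampling along a differentiable fraction of native contacts
  (`run_langevin()`, `run_nve()`, `run_umbrella()`).
* **Analysis** — WHAM specific-heat curves and folding temperatures
  (`wham_cv()`, `wham_fq()`), per-segment folding order (`compute_Q()`,
  `compute_q_segment()`, `mechanism_curves()`), threading-mechanism
  classification of folding transitions into slipknotting, plugging or no
  crossing (`crossing_trace()`, `classify_transition()`,
  `thread_mechanism_ensemble()`), and slow-mode native-state-dynamics
  profiles from the first four principal components (`sample_native()`,
  `pca_fluctuations()`, `nsd_difference()`).
* **Synthetic systems** — an idealized four-helix bundle generator covering
  the full lasso taxonomy with configurable cysteine placement and loop
  size, so the entire pipeline runs and validates with no downloads
  (`make_bundle()`, `make_test_set()`).

Everything user-facing takes and returns tibbles, fitted results have
`tidy()`/`glance()` methods and `autoplot()` figures, and `run_pipeline()`
drives the whole chain from one YAML config.

## A worked example

```r
library(plasso)

# a synthetic leptin-like bundle: C-terminal lasso, thread through it
s <- make_bundle("pierced_C", helix_length = 14, loop_length = 5)
classify_lasso(s)
#> # A tibble: 1 x 11
#>   label         terminus     i     j resid_i resid_j loop_size net_N net_C
#>   <chr>         <chr>    <int> <int>   <int>   <int>     <int> <int> <int>
#> 1 pierced_lasso C           37    73      37      73        36    -1     0
#> # with threaded_from, threaded_to, ambiguous

# oxidized versus reduced folding thermodynamics
cm <- build_contact_map(s)
temps <- c(0.65, 0.75, 0.85, 0.95)
tf <- sapply(c("oxidized", "reduced"), function(st) {
  tp <- build_topology(s, cm, attr(s, "cys_pair"), state = st)
  runs <- lapply(seq_along(temps), function(k)
    run_langevin(tp, cfg = run_config(temperature = temps[k],
                                      n_steps = 6e5, stride = 300,
                                      seed = 100 + k)))
  wham_cv(lapply(runs, function(r) r$e_pot[-(1:200)]), temps)$Tf
})
round(tf, 3)
#> oxidized  reduced
#>    0.803    0.756
```

The classification says the bundle is a pierced lasso: the covalent loop
spans residues 37–73 (36 residues, C-terminal because the second cysteine
is the last residue), and the N-terminal tail crosses the loop surface with
net crossing -1 — one stable pierce (the sign encodes the passage direction
relative to the loop orientation), unambiguous across smoothing levels.
The folding temperatures (the specific-heat maxima from WHAM over the
four-temperature ladder) show the oxidized, threaded protein melting ~6%
above its reduced, unthreaded form: closing the loop buys stability, at the
price of having to thread during folding.

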