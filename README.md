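# cd4logic

Boolean network analysis of CD4+ T helper cell differentiation and
plasticity.

## The scientific problem

Naive CD4+ T cells differentiate into distinct effector and regulatory
types — Th1, Th2, Th17, iTreg, Tfh, Th9 and Foxp3-independent regulatory
cells — depending on the cytokines in their micro-environment, and can
switch type (plasticity) when that environment changes. `cd4logic` treats
this system as a synchronous Boolean regulatory network: nodes are master
transcription factors (T-bet, GATA3, RORγt, Foxp3, Bcl6), intrinsic
cytokine signaling pathways (IFN-γ, IL-2, IL-4, IL-21, IL-9, TGF-β, IL-10)
and extrinsic cytokine inputs (the micro-environment). Each node carries a
logical update rule `x_i(t+1) = f_i(x(t))`; all nodes update simultaneously.
The attractors of this dynamics — states `S*` with `S*(t) = S(t + n)` — are
read as stable cellular expression phenotypes, and the set of initial
states converging to an attractor is its basin of attraction.

The package is aimed at systems immunologists and modelers who want to

* enumerate attractors and basins exhaustively, globally or under clamped
  micro-environments (fixed extrinsic cytokines),
* classify attractors into cell types by marker rules,
* simulate knock-out / over-expression mutants,
* quantify **plasticity**: flip one node of an attractor for a single time
  step, follow the trajectory, and build cell-fate maps of class-to-class
  transitions with per-node, per-direction (activation 0→1 vs inhibition
  1→0) and per-environment statistics,
* measure **functional robustness** to single truth-table bit flips,
* **reduce** networks by exact logical substitution of non-self-regulated
  nodes, and
* cross-check the discrete attractors against a **fuzzy-logic continuous
  ODE approximation** (`dq_i/dt = σ(w_i(q)) − α_i q_i`, with Zadeh
  min/max/complement input functions `w_i`).

Two models are bundled: the 5-node transcription-factor core (TRN) and the
18-node transcriptional–signaling network (TSRN; 5 transcription factors,
7 intrinsic pathways, 6 extrinsic inputs), plus a SOCS-edge-removed TSRN
variant derived programmatically. The rule files are a reconstruction from
the published description of the system; see the methods vignette
(`vignettes/cd4-boolean-model.Rmd`) for the construction criteria and
their consequences.

## Worked example

```r
library(cd4logic)

tsrn <- load_model("TSRN")                    # 18 nodes, 6 inputs
env  <- make_environment(tsrn, "iTreg")       # TGF-βe = 1, IL-2e = 1, rest 0
at   <- attractors_under_environment(tsrn, env)
at
#> attractor_set: 4 attractor(s) over 4096 states
#>   [1] period 1, basin 192,  active: FOXP3+IL2+TGFB+IL10+IL2e+TGFBe
#>   [2] period 1, basin 704,  active: RORGT+BCL6+IL2+IL21+TGFB+IL2e+TGFBe
#>   [3] period 1, basin 1280, active: GATA3+FOXP3+IL2+TGFB+IL10+IL2e+TGFBe
#>   [4] period 1, basin 1920, active: TBET+FOXP3+IL2+TGFB+IL10+IL2e+TGFBe
at$labels
#> [1] "iTreg" "Th17"  "iTreg" "iTreg"

stability_score(tsrn, env)
#> iTreg  Th17
#> 0.926 0.667
```

Under the iTreg-polarizing micro-environment the 4096 intrinsic states fall
into four basins: three Foxp3+ regulatory attractors (including hybrids
with T-bet or GATA3 still on) absorbing 3392/4096 states, and a smaller
Th17 attractor — both lineages need extrinsic TGF-β, and they compete for
it. The stability scores say that 92.6% of single-node transient
perturbations applied to the iTreg attractors return to an iTreg state,
while Th17 is markedly less stable (66.7%), the behavior expected of a
cytokine-dependent subset.

Fate maps and scan statistics:

```r
scan <- perturbation_scan(tsrn)         # all 64 micro-environments
transition_statistics(scan)
#> transition_stats: 3870 perturbations, 634 transitions
#>   overall 16.38% | intrinsic 20.97% | extrinsic 7.21% | macro 16.38%
fm <- build_fate_map(scan)
export_fate_map(fm, "fatemap")          # writes fatemap.graphml, fatemap.dot
```

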