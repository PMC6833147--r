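---
title: "Methods: constraint-based condition analysis with gemkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based condition analysis with gemkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemkit)
```

## The model and its assumptions

gemkit analyses compartmentalised genome-scale metabolic models (GEMs) of
the kind built for yeasts: a stoichiometric matrix $S$ over metabolites and
reactions, flux bounds $l \le v \le u$ in mmol/gDW/h, boolean
gene-protein-reaction (GPR) rules, and a biomass pseudo-reaction whose flux
is the specific growth rate $\mu$ (1/h). Flux balance analysis (FBA) solves

$$\max_v \; v_{\mathrm{biomass}} \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

assuming steady state and that the cell maximises growth. Exchange
reactions move one metabolite across the system boundary; negative flux is
uptake, so a medium is a set of lower-bound overrides on exchanges, and
applying a medium closes the uptake of everything it does not list.

The linear programs are solved by a bounded-variable two-phase primal
simplex implemented in the package (no LP solver library is assumed). A
basic optimal solution directly yields the duals used throughout: shadow
prices per metabolite, and reduced costs per reaction with the convention
that a reduced cost is $\partial(\text{objective})/\partial(\text{bound})$
at the bound where the flux is binding. "Growth limited by substrate X"
therefore reads off as the largest-magnitude reduced cost among uptake
exchanges. The test suite checks every optimum against
`scipy.optimize.linprog` (HiGHS) as an independent oracle and verifies
reduced costs against finite-difference re-solves.

## Condition-specific models from expression evidence

The integration rule is deliberately binary. A gene is *inactive* in a
condition when it has a recorded value in **every** replicate of that
condition and all values are exactly zero; no abundance threshold is
applied, and a gene absent from the table counts as "no evidence", i.e.
active. A condition-specific model deactivates (bounds $[0,0]$) exactly
those reactions whose GPR evaluates to false over the inactive set;
reactions without a GPR (spontaneous) are never deactivated, and all other
constraints are left intact. Because constraints are only ever tightened,
$\mu_{\max}$ of a condition model can never exceed the base model's — a
property-tested invariant.

A biomass component whose maximal production (via a demand reaction) drops
to zero in a condition model is an *auxotrophy*. To compare conditions that
cannot grow at all, auxotrophies are *rescued* under the assumption that
the compound is available in the rich medium: an extracellular counterpart,
an open exchange, and a GPR-free transporter are added (ids prefixed
`EX_rescue_`/`T_rescue_`, so rescues are recognisable downstream and cannot
themselves be expression-deactivated).

## Surplus production capacity

The surplus analysis asks how much of each biomass precursor a condition
could still synthesise while already paying for 90% of its maximal growth:
solve for $\mu_{\max}$, fix the biomass reaction's lower **and** upper
bound to $f\mu_{\max}$ (fixing both matters — with only a lower bound the
LP could trade precursor secretion against extra growth), add a demand for
the component, and maximise it. Components are measured one at a time;
per-component relative values scale the best condition to 100%.

One choice needed care. For a *rescued* component, the rescue uptake would
register as production capacity and mask the broken pathway. The demand is
therefore netted against the component's own rescue influx (objective
$v_{\mathrm{DM}} - v_{T\_rescue}$, clamped at 0): the reported value is
de-novo synthesis capacity, and a condition that can only import the
compound scores exactly 0. Ordinary medium exchanges still count — only
`T_rescue_*` routes are netted out.

## Biomass construction

Macromolecular composition enters as mass fractions (g/gDW, summing to 1
within 0.01) plus per-class monomer mole fractions. Monomer fractions can
be computed from weighted sequence sets (genome for dNTPs, transcriptome
including rRNA/tRNA weights for NTPs, proteome for amino acids). Scaling to
stoichiometric coefficients uses residue masses $M_m$ in g/mmol:

$$\mathrm{coeff}_{c,m} = F_c\, f_m \Big/ \sum_k f_k M_k ,$$

which makes the assembled equation weigh exactly 1 g/gDW (property-tested
to $10^{-6}$). Residue masses are *polymer-incorporated* (free monomer
minus water for protein and nucleic acids): some convention is forced by
the 1 g closure, and this is the standard one in yeast GEMs.
Polymerisation energy is folded into the growth-associated maintenance
(GAM) term of the biomass reaction rather than per-monomer; non-growth
maintenance (NGAM) is a fixed lower bound on an ATP hydrolysis reaction.
Neither GAM/NGAM nor the P/O ratio have package defaults — they are
config inputs, as they must be transferred from a reference model when
organism-specific measurements are lacking. Cell-wall carbohydrates
(glucan, mannan, chitin) are measured; the carbohydrate remainder is split
between trehalose and amylose at a fixed molar ratio.

The biomass equation is treated as growth-rate independent. This is known
to fail above roughly $\mu \approx 0.3$–$0.4\,h^{-1}$, where composition
and GAM shift with growth rate; no growth-rate-dependent rescaling is
attempted, so predictions at high rates should be read with that caveat.

## Gap filling

`fill_gaps()` finds the smallest set of reactions from a universal pool
whose addition makes a target producible (demand flux $\ge \varepsilon$,
default 0.01 mmol/gDW/h, exposed as an argument). It is a MILP — one binary
per pool reaction, big-M linking, minimise the count — solved by
branch-and-bound over the package's own LP. Among equal-cardinality optima
the lexicographically smallest id set is returned, so results are
deterministic; every returned set is post-hoc verified minimal, and the
test suite checks MILP answers against exhaustive subset enumeration on
all fixtures with pools of at most 12 reactions. Per-component filling
processes components in order on an incrementally augmented model, so a
reaction needed by several components is added (and attributed) once; the
union of additions is order-invariant, the attribution need not be.
Candidates carry provenance tags (template model, reference database) for
curator review — the manual literature check that follows gap filling in
practice is out of scope.

## The synthetic world

The generator (`make_toy_model()`, `make_expression()`,
`make_growth_table()`) states the world the tests live in:

* a two- or three-compartment toy GEM with one carbon substrate (uptake
  bound 10 mmol/gDW/h, the usual glucose-uptake order of magnitude), a
  GPR-carrying transporter, $k \ge 3$ single-gene precursor pathways, and a
  riboflavin-like cofactor branch: two linear branches converging on a
  lumazine-like intermediate (the two final branch steps share one gene,
  as with a bifunctional synthase), a linear tail to the
  riboflavin-like compound, and kinase steps to FMN- and FAD-like
  metabolites. Biomass consumes every precursor and a small cofactor
  share, so cutting the branch plants a detectable auxotrophy.
* expression tables with three replicates per condition (the usual
  chemostat design): planted genes get exactly zero everywhere, all other
  genes strictly positive log-normal(meanlog 2, sdlog 1) draws — the
  magnitude is irrelevant since only zero/non-zero is interpreted — and
  one non-planted gene gets a zero in exactly one replicate, so the
  all-replicates rule is exercised against near-misses.
* growth-rate tables with additive Gaussian noise truncated at zero
  (default sd 0.02 1/h, a typical chemostat measurement error).

What a green test establishes is therefore recovery of *planted discrete
truths* (inactive sets, auxotrophies, zero surplus of broken pathways) and
exact agreement of continuous quantities with independent solvers on small
networks. The generator does not emulate read-level noise, isoenzyme
expression correlation, or the degeneracy structure of real GEMs; numbers
reported for a real reconstruction (entity counts, zero-flux counts,
growth-rate correlations) can only be reproduced with that model's own
files and data, which are deliberately not bundled.

## Numerical choices

* LP feasibility/pivot tolerance $10^{-9}$; flux-zero classification
  tolerance $10^{-6}$ mmol/gDW/h; growth call threshold $10^{-4}$ 1/h.
* Zero-flux reactions are defined by flux variability (min = max = 0 at a
  given growth fraction), not by a single FBA solution, because optimal
  solutions of degenerate LPs are not unique. The growth fraction is an
  explicit argument everywhere.
* "Zero expression" means exactly 0 after parsing — no epsilon.
  (Condition ids such as `30D` are protected from numeric coercion when
  reading tables.)
* Default bounds follow the COBRA convention $\pm 1000$ (reversible) and
  $[0, 1000]$ (irreversible); demands are `DM_<met>` with $[0, 1000]$.
* Ties in gap filling break lexicographically; the simplex uses Dantzig
  pricing with an automatic switch to Bland's rule under prolonged
  degeneracy, and single-threaded deterministic arithmetic throughout, so
  every result is bit-stable across runs.
* "Transportable cytosolic metabolite" is operationalised as a cytosolic
  metabolite participating in a reaction that also touches an extracellular
  metabolite; an alternative exchange-based count is exposed
  (`method = "exchange"`) since published counts rarely state their rule.

## Known limitations

No parsimonious FBA, loopless FVA, flux sampling, thermodynamic or enzyme
capacity constraints; expression integration is strictly binary (no
GIMME/iMAT-style continuous weighting); the simplex is dense and sized for
desk-scale models — a genome-scale reconstruction (thousands of reactions)
would want a sparse factorised implementation behind the same interface.
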