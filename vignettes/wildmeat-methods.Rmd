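---
title: "Modelling the consequences of removing wild meat from national food systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the consequences of removing wild meat from national food systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildmeat)
library(dplyr)
```

## The question the package answers

Proposals to prohibit wildlife trade and consumption — prominent since the
COVID-19 pandemic — would remove wild meat ("game meat") from the diets of
dozens of countries. The consequences sit on a spectrum between two worst
cases. If the lost protein is not replaced, per-capita protein supply falls:
a **food-insecurity** worst case. If it is fully replaced by domestic
livestock, pasture and feed cropland must expand: a **land-use-change**
worst case, with species extinctions committed by the converted and occupied
land. `wildmeat` implements this scenario analysis as a tested pipeline:
national consumption estimation, the protein-deficit calculation, the
livestock land-footprint substitution model, and biodiversity loss through
countryside species–area characterization factors, plus the partial-removal /
partial-substitution spectrum between the endpoints.

## The model

**Consumption (annualisation).** National annual wild-meat protein
consumption is

$$W = W_{PPPD} \times \mathrm{population} \times 365.25 / 1000
\quad [\mathrm{kg\ protein/yr}],$$

where $W_{PPPD}$ is the per-capita daily game-meat protein supply
(g/person/day) from a GENuS-style nutrient-supply table. The constant is
exactly 365.25 days. Countries absent from the nutrient-supply source (or
reporting exactly zero there) are filled from FAO-style food balance sheets:
apparent consumption is production plus imports minus exports in live
weight, clamped at zero (re-export artifacts are logged, not errors), and
converted to protein with a protein-content fraction. Countries with zero
consumption under both sources are excluded and listed in the run report —
only non-zero estimates proceed.

**Food insecurity.** The worst-case deficit is
$P_{removal} = P_{current} - W_{PPPD}$ (g/person/day). Two flags summarise
exposure: `below_who`, true when $P_{removal}$ falls strictly below the WHO
recommended minimum intake; and `HIGH_RISK`, true when wild meat supplies
strictly more than 5% of animal protein *and* the country ranks strictly in
the bottom half of a GFSI-style food-security index (larger rank = more
insecure; rank 57 of 113 is bottom-half because $57 > 56.5$). Countries
without a rank are classified `UNRANKED` and reported in a side table,
never dropped.

**Land demand.** Replacement protein is apportioned across the four
livestock sectors (beef, sheep/goat, pork, poultry) by their current shares
of the country's meat-protein consumption — e.g. shares of 20/30/50% for
poultry/beef/pork route the replaced protein in exactly those proportions.
For sector $i$ with pasture and feed-cropland footprints $L^{past}_i$,
$L^{crop}_i$ (m² yr per kg protein):

$$L_{demand} = \sum_i s_i \, W \,(L^{past}_i + L^{crop}_i) / 10^6
\quad [\mathrm{km^2}],$$

with the pasture and cropland components tracked separately. Footprints are
region- and sector-specific; where the country's region lacks a row, the
`GLOBAL` row substitutes and the fallback is logged.

**Biodiversity loss.** Characterization factors give species "destined for
extinction" per km² of one-off habitat transformation ($C_{past}$,
$C_{crop}$) and per km²·yr of continued occupation ($O_{past}$, $O_{crop}$):

$$B_{loss} = L_{pasture}\,(C_{past} + h\,O_{past}) +
             L_{crop}\,(C_{crop} + h\,O_{crop}),$$

with occupation horizon $h = 10$ years by default. Some published statements
of this formula reuse the pasture occupation factor in the cropland term; the
accompanying definitions give each land type its own factor, so the package
uses $O_{crop}$ and offers `eq4_as_printed = TRUE` to reproduce the literal
variant for comparison.

**The scenario spectrum.** A scenario removes a fraction $r \in [0,1]$ of
wild meat and substitutes a fraction $f \in [0,1]$ of what was removed. The
unreplaced protein $(1-f)\,r\,W_{PPPD}$ enters the deficit calculation; the
replaced protein $f\,r\,W$ enters the land and biodiversity stages. Both
responses are linear in $r$ and in $f$; $(r{=}1, f{=}0)$ and
$(r{=}1, f{=}1)$ recover the two worst-case stages exactly, $r = 0$ is
business as usual, and $f = 1$ is the protein-neutral line (post-scenario
supply equals current supply in every country). The linear interpolation is
this package's minimal computable model of the conceptual spectrum; it adds
no behavioural response — compliance, price or trade dynamics are out of
scope, and partial compliance is represented only as $r < 1$.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `who_threshold` | g protein/person/day | 50 | WHO-style safe intake (≈0.83 g/kg/day × 60 kg reference adult). Always explicit in calls and recorded in the run report rather than hard-coded. |
| `game_protein_content` | kg protein / kg live weight | 0.15 | Typical lean-meat protein fraction, used for balance-sheet conversion; configurable because published conversions vary by species mix. |
| `horizon` | years | 10 | Occupation impacts accumulate for a decade; a conservative choice since occupation losses continue for as long as land stays in production. |
| share threshold | fraction of animal protein | 0.05 | "More than 5%" — strict inequality. |
| `genus_zero_is_gap` | logical | `TRUE` | A zero in the nutrient-supply source is treated as a reporting gap and filled from the balance sheet. |

Internal unit conventions are fixed once to avoid silent magnitude errors:
footprints in m²·yr per kg protein (sources quoted per 100 g protein need a
×10 conversion at ingestion), characterization factors in species per km²
and per km²·yr (per-m² sources need ×10⁶), land outputs in km².

## The synthetic-data generator and what tests prove

External sources (GENuS extracts, FAO balance sheets, GFSI rankings,
life-cycle footprints, characterization factors) cannot ship with the
package, so `generate_panel()` draws seeded synthetic country panels with
the structure the analysis assumes: wild-meat protein is a share of animal
protein, which is a share of total protein; sector shares live on the
simplex (flat-Dirichlet draws); a configurable fraction of countries is
reported only through the balance-sheet path; some countries lack an index
rank or a regional footprint. Country codes use a reserved `X..` namespace
so harmonization tests can distinguish synthetic from real ISO3 codes.

Distribution choices are generator policy, not estimates: ranges are
uniform and default to brackets spanning the published extremes (total
protein 40–110 g/person/day; wild-meat share of animal protein 0–0.75,
reaching the most dependent countries on record; populations 5×10⁵–2×10⁸).
Uniform sampling deliberately overweights high-reliance countries relative
to the real, heavily right-skewed cross-country distribution — useful for
exercising every code path, but it means synthetic global totals are *not*
calibrated to real-world magnitudes. Passing tests demonstrate that the
arithmetic, merge rules, flags and aggregation are correct, not that any
real country's value is reproduced; runs on real data in the documented
schemas inherit the former guarantee only.

Ground truth for every panel is computed by `oracle_outputs()`, a
deliberately naive scalar restatement of the model — plain loops, one
country at a time, sharing no code with the pipeline. The headline test
regenerates 50 countries and requires pipeline–oracle agreement within
1e-9 relative tolerance on every output, alongside exact reproduction of
all hand-computable worked examples and the endpoint/bilinearity
identities. Test problem sizes (1–50 countries; a 5×5 scenario grid; a
100-country acceptance run) keep the full suite under a minute while
covering every branch.

## Numerical and degenerate-input policy

- Nutrient-supply ordering violations ($W_{PPPD} > $ animal protein $>$
  total protein) are clamped to the binding bound and logged; the model
  assumes consistent supplies and the sources state no cleaning rule.
- A balance-sheet-derived $W_{PPPD}$ exceeding the nutrient-supply animal
  protein is likewise clamped (with a warning) before the deficit and share
  calculations.
- Negative apparent consumption clamps to zero with a warning.
- A country with no meat-sector protein at all receives equal replacement
  shares (0.25 each) with a warning.
- Strict inequalities at every classification boundary: share exactly 5%,
  rank exactly $n/2$, and $P_{removal}$ exactly at the WHO threshold are
  all *not* flagged.
- No row is silently dropped anywhere: readers quarantine invalid rows with
  row numbers, harmonization quarantines unmappable names, the consumption
  filter lists excluded countries, and the risk landscape sides unranked
  ones.
- Tolerances: sector shares sum to 1 within 1e-12; pipeline–oracle
  agreement within 1e-9 relative; scenario linearity within 1e-12.

## Worked example

```{r example}
cfg <- synthetic_config(n_countries = 10, seed = 7)
synth <- generate_panel(cfg)
panel <- harmonize_countries(synth$inputs)

consumption <- estimate_consumption(panel)
assessment <- assess_food_security(panel, consumption,
                                   who_threshold = 50)
land <- land_demand_all(panel, consumption)
losses <- biodiversity_loss(land$totals, panel$cfs, horizon = 10)

head(national_table(consumption, assessment, land, losses),
     3)[, c("country", "W_kg_protein_yr", "P_removal", "wild_share",
            "risk_category", "L_total_km2", "B_loss")]

endpoint <- run_scenario(panel, scenario_spec(1, 1))
endpoint$totals
```

## Known limitations

- Protein is the sole nutritional indicator; micronutrients, fats and
  calories are out of scope (other meat-borne nutrients scale with mass).
- The WHO comparison uses an absolute g/person/day threshold; body-mass- or
  demography-scaled intakes are not modelled.
- Replacement shares are computed over the four meat sectors only; fish,
  eggs and dairy are excluded from the replacement set.
- Under-reporting of informal wild-meat trade is not corrected; the
  generator exposes an `underreporting_factor` multiplier for sensitivity
  exploration, but no correction is applied by default, so real-data
  estimates are conservative.
- Characterization factors cover terrestrial vertebrates only, so species
  losses understate whole-ecosystem impacts.
- The spectrum is a linear interpolation; no compliance, price, import or
  yield-growth dynamics.
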