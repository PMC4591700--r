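---
title: "Estimating reproductive-health sub-accounts from public ledgers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating reproductive-health sub-accounts from public ledgers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhsa)
library(dplyr)
```

## The problem

National Health Accounts (NHA) track who pays for health care, who delivers
it, and what the money buys. In countries with weak financial information
systems a full NHA is often out of reach, and a *sub-account* is built
instead: an ad-hoc but disciplined estimation of spending on one sector —
here reproductive health (RH), meaning maternal-health services and family
planning — from whatever records exist: budget execution ledgers, routine
service statistics, and unit-cost studies.

`rhsa` implements the three estimation strategies this setting calls for and
the bookkeeping around them. The unit of input is a **ledger entry**: one
public transaction with a year, a financing agent (the public institution
managing the funds), a nominal local-currency amount, and one of three
**earmark classes** that decides which strategy applies. The output is an
**allocation cube**: amounts in constant base-year international dollars
indexed by year × agent × provider tier × health function, from which the
standard report tables are rendered.

## The three strategies

**1. Earmarked pass-through.** Funds explicitly designated for an RH
function (e.g. a national RH programme line) are taken at the full amount
paid out in the year and mapped one-to-one onto a cube cell. No splitting,
no estimation. The entry must carry its function; its provider tier defaults
to primary-care clinics unless stated, since programme spending in this
setting is delivered overwhelmingly through the primary level — this default
is configurable (`default_earmark_tier`) and flagged as an assumption.

**2. Facility funds by distribution factors.** Most public money reaches
facilities without an RH label (salaries, buildings, performance-based
financing subsidies). These are apportioned in two steps, both driven by a
bottom-up reconstruction of facility expenditure from routine statistics:

* Each facility tier's total expenditure is estimated as
  $T_h = \sum_s V_{hs}\, C_s$ — the annual volume of each service delivered
  by tier $h$ times its unit cost. $T_h$ covers all financing sources; only
  its *proportions* are used downstream, so the currency vintage of the
  unit costs cancels.
* The **tier weights** $w_h = T_h / \sum_{h'} T_{h'}$ spread a pooled entry
  across tiers (an entry with a tier hint is pinned to that tier), and each
  tier's **share-matrix row**
  $\pi_{hf} = \big(\sum_{s \in f} V_{hs} C_s\big) / T_h$ splits the tier's
  part across maternal health, family planning and other activities. A cell
  receives $x\, w_h\, \pi_{hf}$. Because both factor vectors sum to one,
  the input amount is conserved exactly.

**3. Administrative apportionment.** National administrative spending
(ministry headquarters, the social-security fund's administration) is
attributed to RH by the **direct-expenditure ratio**
$\phi = D_{RH} / D$, where $D$ is everything allocated by strategies 1–2
(all funds used directly for service provision) and $D_{RH}$ its
maternal-health plus family-planning part. An administrative entry
contributes $x\phi$ to its agent's administration function and
$x(1-\phi)$ to the non-RH residual; administrative cells never enter
$\phi$'s denominator.

**RH totals.** Report tables count the two service functions *plus* the two
administration functions as RH, and exclude only the `OTHER_HEALTH`
residual. That is the convention of published sub-account tables, where
ministry and social-security administration appear as separate rows inside
the RH total.

## Monetary normalization

The pipeline order is fixed: nominal local currency → constant base-year
local currency → international dollars.

* **Deflation.** The inflation rate stored for year $y$ moves money from
  year $y-1$ prices to year $y$ prices; an amount from year $t$ is
  multiplied by $\prod_{y=t+1}^{B}(1+i_y)$ to reach base year $B$. The
  convention is documented rather than configurable: one convention keeps
  results reproducible, and the alternative (rates indexed by the source
  year) is just a relabelling of the input series. Amounts dated after the
  base year are an error — the method only inflates forward.
* **PPP conversion.** Constant amounts are divided by the base-year
  purchasing-power-parity factor (local currency units per international
  dollar).

Both steps are linear, so the adjustment commutes with summation and the
conservation audit can be run at any currency stage; a property test pins
this down.

## Rounding and presentation

The engine keeps full double precision; rounding happens only at the final
rendering step, **half away from zero** (`round_half_away()`), which is the
rounding used in published accounting tables (2.5 → 3, not banker's 2).
Parenthetical percentage shares are rounded to one decimal and a trailing
`.0` is trimmed, so 76.02 prints `76` and 18.74 prints `18.7`; top-level
summary shares use integer precision. This single rule reproduces every
parenthetical share of the bundled published tables, which is itself one of
the package's checks (`verify_printed_tables()`). Table amounts are
reported in thousands of international dollars.

## Arithmetic model

Ledger amounts are carried as R doubles constrained in practice to whole
local-currency units. Integers are exact in doubles up to $2^{53}$ — far
above any national budget in francs — so nominal-stage sums and the
generator's bookkeeping are exact. After monetary adjustment and factor
multiplication values are genuinely fractional; the conservation audit
therefore allows a relative slack of $10^{-9}$, and ground-truth recovery
tests compare at standard double tolerance. Observed discrepancies in the
test battery are at the $10^{-15}$ level (summation-order effects only).

Degenerate inputs are handled loudly rather than silently: a facility tier
with zero bottom-up total has an undefined composition (`NA` share row) and
any attempt to allocate funds to it is an error; an administrative ledger
with no direct expenditures to derive $\phi$ from is an error; a missing
unit cost names the service code; an invalid ledger stops the pipeline
before any allocation, naming rows and fields.

## The synthetic generator

Real sub-account ledgers are rarely public, so the package ships a
generator (`generate_scenario()`) that emulates the study conditions end to
end: three facility tiers plus a national administrative level, six
financing agents, three ledger earmark classes, three years. Defaults are
fixed at the published Burundi magnitudes: a public budget of 100 billion
nominal francs in the first year growing 5 % a year; facility totals split
0.47 / 0.37 / 0.16 across tiers; the published 2012 facility composition as
the target share matrix (25.8 + 2.2 % RH at clinics, 13.2 + 0.2 % at
referral hospitals, 9.8 + 0.2 % at third-tier hospitals); 2 % of the budget
earmarked for RH, 86 % facility funds, 12 % national administration; an
agent mix dominated by the health ministry (0.73) and the civil-service
mutual (0.19); inflation 9.6 % then 18 %; 505 francs per international
dollar.

Volumes are **back-solved**, not sampled: given the target shares, the tier
split and fixed unit costs, the generator computes the spending each
(tier, function) must carry and converts it to integer service counts. This
is what makes an exact ground truth possible — the intended allocation of
every ledger entry is computed by construction, with plain per-entry loops
(`construct_ground_truth()`), independent of the grouped pipeline code it
is used to check. Count rounding leaves a calibration error in the implied
share matrix below $10^{-6}$ at these budget scales. Integer ledger amounts
are produced by largest-part remainder assignment, so class, agent and
category splits sum exactly.

A single seeded pseudo-random stream drives the only stochastic element
(how each agent's facility funds split across spending categories); the
seed is recorded in `config.yaml` and in a `# seed:` header of every CSV a
scenario writes, and a fixed seed reproduces the files byte for byte.
`perturb_scenario()` multiplies volumes by log-normal noise and recomputes
the ground truth, supporting robustness studies of the distribution
factors.

What the generator does **not** emulate: misclassified or overlapping
ledger categories (inputs are required to be pre-resolved to a disjoint
partition; the validator rejects what it can detect, but cannot see
double-counting hidden in category labels), accrual/cash timing differences
beyond the cash-basis rule, donor and household financing (out of scope for
a public sub-account), and sub-national structure. Passing the recovery
tests therefore shows the allocation arithmetic is faithful, not that any
particular country's classification decisions were right.

## The published-table fixture

The published Burundi 2010–2012 sub-account tables ship as a first-class
fixture (`burundi_printed()`), entered from the printed absolutes — the raw
ledgers behind them are not public, so the printed tables are the bridge
between the engine's conventions and a real sub-account.
`verify_printed_tables()` recomputes every number those tables derive from
their own absolutes — all parenthetical shares, the 16 % and 2.6 % growth
rates, the 20 % GDP growth implied by the GDP shares, and the cross-table
sum identities — and checks them at printed precision (the provider table's
columns are allowed a 1-thousand slack, matching the rounding slack visible
in the published table itself; facility-composition rows are allowed
±0.15 percentage points for the same reason).

One published figure is deliberately *not* a check: per-capita RH spending.
From the printed population (9.859 million in 2012), the census fractions
(23.7 % women of childbearing age, deliveries 5 % of population) and the
printed RH totals, the package computes about \$17.6 per woman of
childbearing age and \$83.5 per delivery for 2012, where the source text
reports "close to \$20" and "around \$93"; the denominators behind the
reported figures are not stated and the arithmetic is not recoverable.
`per_capita_indicators()` reports what the printed inputs imply.

```{r}
fx <- burundi_printed()
per_capita_indicators(fx$summary$rh_total[3] * 1e3, 2012, fx$demography) |>
  dplyr::select(per_wcba, per_delivery)
```

## A worked synthetic run

```{r}
scn <- generate_scenario(seed = 1)
alloc <- run_pipeline(scn$ledger, scn$volumes, scn$unit_costs, scn$ctx)
glance(alloc)
build_function_table(alloc) |> head(4)
```

## Design choices that were genuinely open

* **Tier weights for pooled funds.** Whether salaries should be split by
  bottom-up expenditure proportions or by payroll location is not
  decidable from the available records; the package uses the bottom-up
  proportions for every pooled entry and lets a `tier_hint` override them
  per entry, which is how payroll-located records would be expressed.
* **The default tier of earmarked programme funds.** National programme
  spending is assigned to primary-care clinics unless hinted otherwise, as
  the delivery level of the programme packages concerned; configurable.
* **Zero-total tiers error rather than receive zero.** A tier that the
  volume data say spent nothing, receiving funds the ledger says it got,
  signals inconsistent inputs; silence would hide it.
* **Fixed inflation convention** (see above), one pipeline order, one
  rounding rule: reproducibility over configurability wherever the choice
  does not change what can be expressed.
* **Service catalogue.** Published sub-account tables never enumerate the
  services behind their bottom-up estimates; the default catalogue
  (deliveries, antenatal and postnatal visits, family-planning
  consultations and supplies, outpatient visits, inpatient days) is a
  configurable stand-in with costs on a realistic local-currency scale.

## Problem sizes and test design

The bundled test battery runs the full pipeline against the constructed
ground truth on 20 generator seeds, and uses three-year scenarios with
66 ledger entries and 63 volume records — small enough to audit by hand,
large enough to exercise every strategy, agent, tier and function cell.
The Monte-Carlo robustness check uses 5 replicates at two noise levels,
which suffices to order them. These sizes are the package's own choice of
a convincing-but-auditable battery; the generator scales to larger
configurations through `scenario_config()`.

## Limitations

* The engine allocates what the ledger says was paid; it cannot correct
  classification errors upstream, and requires overlapping categories to
  be resolved into disjoint amounts before entry.
* Point estimates only: unit-cost uncertainty is not propagated.
* One country-year is one independent slice; the package does not model
  flows between years (commitments, arrears) beyond the cash-basis rule.
* The published-table fixture validates derived arithmetic, not the
  original study's data collection; the raw ledgers are not available to
  re-run end to end.
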