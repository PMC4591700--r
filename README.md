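# rhsa — reproductive-health sub-account expenditure estimation

`rhsa` builds a **reproductive-health sub-account (RHS)**: an adaptation of
National Health Accounts that isolates public spending on reproductive
health (maternal-health services and family planning) in settings where a
full NHA is not feasible. It is written for health economists and
health-financing analysts who have budget execution ledgers, routine
service statistics and a unit-cost study — and need a defensible,
reproducible allocation of that money across financing agents, provider
tiers and health functions.

## The method

Every public transaction is a ledger entry `(year, agent, amount, earmark
class)`. Three estimation strategies turn a ledger into an allocation cube
(year × agent × provider tier × function, in constant base-year
international dollars):

1. **Earmarked pass-through** — funds explicitly designated for an RH
   function map one-to-one onto a cube cell at the full amount paid out.
2. **Distribution-factor allocation** — non-earmarked facility funds are
   split across provider tiers by weights `w_h = T_h / Σ T_h'` and within
   each tier across functions by the tier's share row
   `π_hf = Σ_{s∈f} V_hs C_s / T_h`, where `T_h = Σ_s V_hs C_s` is the
   bottom-up facility total (service volumes × unit costs). A cell
   receives `x · w_h · π_hf`; both factor vectors sum to one, so money is
   conserved exactly.
3. **Administrative apportionment** — national administrative spending is
   attributed to RH by the direct-expenditure ratio `φ = D_RH / D`
   computed from the strategy-1/2 allocations; `x·φ` lands in the agent's
   administration cell, `x·(1−φ)` in the non-RH residual.

Amounts are deflated to constant base-year prices by chained annual
inflation factors, then converted to international dollars by a PPP
factor. Report tables use the conventional "amount (share)" cells in
thousands of international dollars, rounded half away from zero.

A synthetic-scenario generator back-solves service volumes from a target
share matrix, emits a complete, internally consistent input set with
integer amounts, and computes the implied allocation cube by construction
— the pipeline is tested to recover it exactly. The published Burundi
2010–2012 sub-account tables ship as a fixture (`burundi_printed()`), and
`verify_printed_tables()` re-derives every share, growth rate and sum
identity those tables print.

## Worked example

```r
library(rhsa)

scn   <- generate_scenario(seed = 1)           # Burundi-like synthetic inputs
alloc <- run_pipeline(scn$ledger, scn$volumes, scn$unit_costs, scn$ctx)
alloc
#> <rhs_allocation>
#>   years       : 2010, 2011, 2012
#>   RH totals   : 2010: 54,683,074; 2011: 52,387,988; 2012: 46,616,433 Int$
#>   cube cells  : 156
#>   conservation: ok
```

The `RH totals` line is each year's reproductive-health-attributable
spending in constant 2012 international dollars (service functions plus
national administration, excluding the non-RH residual); `conservation: ok`
means every agent-year's cube cells sum back to its monetary-adjusted
ledger total. The cube renders into the standard report tables:

```r
cat(render_table_text(build_function_table(alloc),
    title = "RH expenditure by health function (thousand Int$)"))
#> RH expenditure by health function (thousand Int$)
#> label                                          2010           2011           2012
#> Social Security Administration (MFP)    2,625 (4.8)    2,515 (4.8)    2,238 (4.8)
#> Public Administration (except MFP)      3,937 (7.2)    3,772 (7.2)    3,356 (7.2)
#> Family Planning                         4,262 (7.8)    4,083 (7.8)    3,633 (7.8)
#> Maternal Health                       43,859 (80.2)  42,018 (80.2)  37,389 (80.2)
```

Each cell is "amount (share of the year's RH total)". Results are also
available tidily — `tidy(alloc)` returns the cube as a tibble,
`glance(alloc)` a one-row audit summary, `autoplot(alloc)` a stacked
year-by-function chart — and `rhs_run("cfg.yaml")` drives the same
pipeline from files to files. A thin CLI lives at `inst/cli/rhsa.R`
(`run`, `simulate`, `verify-tables`, `validate` subcommands).

Per-capita indicators divide RH totals by estimated women of childbearing
age (23.7 % of population) and expected deliveries (5 %):

```r
fx <- burundi_printed()
per_capita_indicators(fx$summary$rh_total[3] * 1e3, 2012, fx$demography)
#>   year population    wcba deliveries per_wcba per_delivery
#>   2012    9859000 2336583     492950     17.6         83.5
```

## Scope

Public financing agents only (no donor or household accounting), national
level only, point estimates only. See the vignette
(`vignettes/reproductive-health-subaccounts.Rmd`) for the model's
assumptions, the generator's defaults, numerical choices and limitations.
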