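# vaxchain

A vial-level discrete-event simulator of national immunization supply
chains, built for **vial-size decisions**: what happens to vaccine
availability, cold-chain utilization, open-vial wastage and cost per
injection when a country swaps its 10-dose measles vial for a 5-, 2- or
1-dose presentation?

It is written for health-systems operations researchers and EPI
(Expanded Programme on Immunization) logisticians. The bundled study
system is a Niger-like four-tier network — one central store, 7 regional
stores served by two cold-truck loops, 42 district stores (7
self-procuring, 1 with no cold storage), 695 clinics — carrying the six
EPI vaccines (BCG, DTP-HepB-Hib, YF, OPV, TT, measles).

## The model in brief

* **Entities.** Vials, held in FIFO batches with arrival and expiry
  times; storage devices and vehicles with finite net volume (stored
  volume never exceeds capacity — excess arrivals are rejected).
* **Ordering.** Reorder point at 25% of an order-up-to level *S*
  (months of expected vial flow per tier), order quantity
  `(S − on-hand) × 1.25`, capped by storage, backlogged past vehicle
  capacity. A trip's *demand-requested* utilization
  (= ordered ÷ vehicle volume) may exceed 100%; actual loading cannot.
* **Sessions (WHO Multi-Dose Vial Policy).** Arriving children draw from
  the open vial, then FIFO sealed vials; stock-outs are missed
  opportunities. Open lyophilized vials are discarded at session end
  (remaining doses = open-vial wastage); open liquid vials persist 28
  days. A 1-dose vial can never be partially used, so its open-vial
  wastage is exactly zero.
* **Metrics.** Availability = patients served ÷ patients arriving, per
  antigen; storage and transport utilization = space consumed ÷ space
  available; all summarized as means over replications and
  median (range) across stores or routes.
* **Costs** (measles): administration
  `doses × (price + injection syringe) + vials × reconstitution
  syringe`, wasted doses `price × doses wasted`, and disposal
  `safety-box cost per dose + per-gram rate × discarded mass`; reported
  as cost per injection.

## Worked example

A miniature network (1 region, 2 districts, 10 clinics; per-clinic
demand matches the full fixture):

```r
library(vaxchain)
params  <- mini_params()
network <- generate_network(params)
demand  <- fixture_demand(network, params)
sim <- run_simulation(network, load_vaccine_catalog(), demand,
                      sim_config(replications = 10, seed = 1))
summary(sim)
```

```
Vaccine availability (percent of arriving patients served):
      antigen availability  sd
          BCG           89 5.4
 DTP-HepB-Hib           86 0.6
           YF           87 4.2
          OPV           86 0.6
           TT           88 2.2
            M           86 4.0

Transport utilization by origin level (per-route means):
    level routes requested_median requested_range actual_median
  central      1              31%          31-31%           28%
 regional      2              46%          44-48%           38%
 district     10              75%         35-227%           50%

Storage utilization by level (refrigerated, time-mean per store):
    level stores median  range
  central      1    66% 66-66%
 regional      1    16% 16-16%
 district      2    57% 56-59%
   clinic     10    28% 20-32%
```

Roughly 86-89% of arriving children are served; the binding constraints
sit at the district-to-clinic tier, where some vaccine carriers are
demand-requested well above 100% of their capacity. Substituting the
1-dose measles presentation:

```r
sim1 <- run_simulation(network,
                       substitute_presentation(load_vaccine_catalog(), "M", 1),
                       demand, sim_config(replications = 10, seed = 1))
subset(sim1$summary$doses, antigen == "M")
#>   antigen arrivals administered open_vial_waste
#>         M   8423.6       6672.6               0
```

Measles open-vial waste drops to exactly zero, but fewer children are
served (6673 vs 7241 per year): the tenfold packaged volume per dose
crowds the same carriers and refrigerators. That trade-off — run on the
full 695-clinic network over the 4 vial-size x 3 target-population
scenario grid — is the package's core experiment (`cmd_suite()`), and
the measles cost per injection rises accordingly (`scenario_costs()`).

A thin command-line wrapper lives at `inst/cli/vaxchain.R`
(`validate`, `run`, `suite` subcommands).

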