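---
title: "Simulating vial-size decisions in a national vaccine cold chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating vial-size decisions in a national vaccine cold chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxchain)
```

## The problem

A national immunization programme moves vaccines from a central store
through regional and district stores to the clinics where children are
vaccinated. Every step is capacity-constrained: cold rooms, refrigerators
and freezers have finite net volume, and the cold trucks, 4x4 trucks and
vaccine carriers that link the tiers have finite cargo space. The
packaging of a vaccine — its *presentation*, chiefly doses per vial —
changes both ends of the trade-off. Fewer doses per vial means less
open-vial wastage under the WHO Multi-Dose Vial Policy (MDVP), but more
packaged volume per dose, more vials, and more injection material moving
through the same cold chain.

`vaxchain` is a vial-level discrete-event simulator of that system,
built to rerun the classic experiment for a Niger-like Expanded Programme
on Immunization (EPI): replace the 10-dose measles vial with 5-, 2- or
1-dose presentations and measure what happens to vaccine availability,
storage and transport utilization, wastage, and cost per injection.

## Model structure

**Entities and state.** Vials are the simulated entities. Same-antigen
vials that arrive together and share an expiry date are held as a FIFO
batch; a location's inventory is its ordered batch list per antigen, and
every removal — for shipment or administration — draws from the oldest
batch first. The daily inventory balance (arrivals plus carry-over minus
removals) can never push a device above its net capacity: arrivals beyond
free space are rejected and ride back to the origin.

**Ordering.** Clinics and stores follow a reorder-point rule: when
on-hand stock of an antigen falls to 25% of its "maximum", the location
orders `(maximum − on-hand) × 1.25` vials. The maximum itself is not a
device property but an order-up-to level derived from expected demand
over the re-supply interval — months of expected vial flow per tier
(default 6 central, 4.5 regional, 3 district, 2.5 clinic, configurable
via `sim_config(order_months = ...)`). Expected vial flow includes the
MDVP waste overhead of multi-dose lyophilized vials
(`E[ceil(N/dpv)] ≈ λ/dpv + (dpv−1)/(2 dpv) · P(N>0)` for Poisson session
demand `N`), so clinics that waste more also order more, as real
clinics do. Orders are capped so post-delivery stock fits the
destination's storage, and unshipped remainders are backlogged to the
next trip.

**Shipping.** Trips run at fixed frequencies (quarterly cold-truck loops
from the central store over the regional tier; monthly 4x4 collection by
districts; monthly vaccine-carrier collection by clinics). A trip's
*demand-requested* utilization is ordered volume over vehicle capacity
and may exceed 100%; actual loading is capped at 100% and the excess
becomes backlog. Each loaded vial is independently destroyed with the
shipping-loss probability at departure; stored vials face a monthly
inventory-loss draw at one twelfth of the annual rate.

**Sessions and the MDVP.** At each immunization session, arriving
children draw doses first from an already-open vial, then from sealed
vials opened FIFO; a child whose antigen is stocked out is a missed
vaccination opportunity and does not re-queue. At session end, open
lyophilized vials (BCG, yellow fever, measles) are discarded and their
remaining doses counted as open-vial wastage; open liquid vials (OPV,
TT, DTP-HepB-Hib) persist for up to 28 days after opening. A
single-dose vial can never be partially used, so its open-vial wastage
is identically zero — the structural fact behind the 1-dose scenario.

**Costs.** Three components, measles only (prices for the other antigens
are not published): administration
(`doses × (price + injection syringe) + vials opened × reconstitution
syringe`, with no syringe for oral OPV and reconstitution only for
lyophilized vaccines), wasted doses (`price × doses wasted`), and
disposal (safety-box cost per dose plus a per-gram rate on the mass of
discarded vials and syringes). The 2-dose measles price is unknown and
is stored as explicitly missing: any cost computation touching it stops
with an error rather than imputing a value. The safety-box cost per dose
has no published value either; it defaults to 0 with a warning and can
be supplied in the cost-input table.

## Allocation under scarcity: two rules, deliberately

When cold *storage* space cannot admit everything, vials are accepted in
rounds of complete vaccine regimens — each round admits the vial mix
covering one child's full schedule, fractionally by doses per vial —
with leftover single vials added in catalog order
(`allocate_limited_space()`). When a *vehicle* is too small for an
order, the load instead keeps each antigen's share of the request
(proportional fill, `load_shipment()`). The distinction is a design
decision worth recording: regimen rounds are weighted by schedule demand
(`doses_per_person / doses_per_vial`), so applying them to vehicle
loading systematically strips out the waste-overhead vials that
large-vial presentations need beyond their demand share, which reverses
the direction of the vial-size experiment. Proportional loading ships
every antigen at the same fill rate, leaving the volume-per-dose effect
— the effect under study — as the driver.

## The synthetic network

The real equipment inventory and route list behind the published
experiment are unpublished, so `generate_network()` builds a synthetic
stand-in that reproduces the published *structure* — 1 central store, 7
regional stores on two cold-truck loops, 42 district stores (7
self-procuring, 1 with no cold storage), 695 clinics — and its
qualitative operating regime, never any real facility's capacity.

Two choices matter most:

* **Clinic heterogeneity.** Clinic demand weights are log-normal
  (sdlog 0.6, normalised). Session-size heterogeneity is what makes
  wastage and congestion effects observable at all: small sessions waste
  most of a 10-dose vial, large clinics overfill their carriers.
* **Capacity calibration.** Device and vehicle capacities are documented
  multiples of expected baseline (10-dose) flow, fixed across scenarios:
  vaccine carriers at 1.4x the mean clinic monthly volume, 4x4 trucks at
  1.8x the mean district monthly volume, cold trucks at 4.5x their
  loop's monthly through-volume; clinic stores at 3.5x mean clinic
  monthly volume, district stores at 1.7x own monthly volume, regional
  stores at 16x, the central store at 7x national monthly volume. These
  constants place the baseline where the published system operates —
  district refrigerators around the 60-70% band, roughly a third of
  clinic carriers above 100% demand-requested utilization, central
  storage near two thirds full, regional storage slack — so that the
  vial-size substitution is exercised against binding constraints, as it
  was in the original study.

Demand uses the published 2010 projection of 586,880 annual births
(the compound projection from the 2005 registry total, 557,381 at 1.04%
per year, gives 586,974; the published figure is carried as-is), a
target-population fraction of 100/80/60%, four sessions per clinic per
month, and per-visit Poisson arrivals (`dynamic`) or a deterministic
split (`static`). TT doses for women are folded into an aggregate stream
proportional to newborn counts (five contacts per newborn-equivalent),
since no separate maternal population is published.

## Numerical and procedural choices

* **Calendar.** A 12 x 30-day year (360 days). Sessions fall at evenly
  spaced days within each month; monthly and quarterly trips are phase-
  staggered so deliveries cascade down the tiers within a month.
  Within a day: expiry sweep → sessions → orders and shipments (same-day
  arrival; the network carries no travel times).
* **Randomness.** One root seed per replication, split into independent
  demand and loss streams, so identical seeds give bit-identical runs
  and demand draws do not shift when loss rates change.
* **Conservation.** Every replication keeps a per-antigen dose ledger:
  initial downstream stock + doses shipped from central − doses returned
  to central (storage-full rejections) = administered + open-vial waste
  + expiry waste + breakage + residual inventory, exactly. The test
  suite asserts exact equality on every replication.
* **Ties and degenerate inputs.** Partial allocation rounds add single
  vials in catalog order; an exhausted temperature class (say, no
  freezer) never blocks antigens of the other class. A store with zero
  capacity is legal, reports storage utilization as missing, and simply
  never holds stock. Availability is reported as missing where nobody
  arrived.
* **Problem sizes.** The acceptance experiments run the full 745-location
  network at 10 replications per scenario (a few minutes per scenario on
  one core); unit tests use a miniature network (1 region, 2 districts,
  10 clinics) whose per-clinic demand matches the full fixture.

## What passing tests do and do not show

The simulator reproduces the published *worked numbers* exactly (the
availability and cost-per-injection arithmetic, the 200% overfilled
carrier), matches an independent brute-force per-dose replay of the MDVP
rules on randomized sessions, conserves doses exactly, and reproduces
the published *directional* result: availability falls monotonically and
open-vial waste falls strictly to zero as the measles vial shrinks from
10 to 1 doses. It does not — and cannot — reproduce the published
table cells or histograms that depend on the real, unpublished
equipment inventory; the synthetic network is calibrated to the same
operating regime, not to the same hardware. Real-world features outside
the model include seasonality and campaign pulses, temperature
excursions, travel times and fuel, emergency orders between scheduled
trips, and intra-day clinic queueing.

## A worked miniature

```{r example, eval = FALSE}
params <- mini_params()
network <- generate_network(params)
demand <- fixture_demand(network, params)

baseline <- run_simulation(network, load_vaccine_catalog(), demand,
                           sim_config(replications = 10, seed = 1))
summary(baseline)

one_dose <- run_simulation(network,
                           substitute_presentation(load_vaccine_catalog(),
                                                   "M", 1),
                           demand, sim_config(replications = 10, seed = 1))
one_dose$summary$doses  # measles open-vial waste: exactly 0
```
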