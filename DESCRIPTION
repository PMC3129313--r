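Package: vaxchain
Title: Discrete-Event Simulation of Multi-Tier Vaccine Cold Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A vial-level discrete-event simulator of national immunization
    supply chains: a four-tier network (central, regional, district, clinic)
    with capacity-constrained cold storage and transport, reorder-point
    ordering with backlogged shipments, first-in-first-out perishable
    inventory, WHO Multi-Dose Vial Policy open-vial wastage accounting, and
    the standard administration/wastage/disposal cost equations. Includes a
    synthetic Niger-like network generator and the vial-size substitution
    experiments (10, 5, 2 and 1 doses per vial) for the measles vaccine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
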