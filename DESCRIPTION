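Package: hospflow
Title: Hybrid Discrete-Event and Agent-Based Simulation of Hospital Patient Flow Under Disruption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid discrete-event / agent-based simulator for clinical
    processes such as an emergency trauma room. Processes are read from a
    BPMN 2.0 subset with sidecar task metadata; hospitals are modelled as
    areas with transit times, resource inventories, minimum stock levels
    and cross-area lending; patients are agents with injury groups,
    priorities and time-to-damage / time-to-reanimation deadlines.
    Time-scheduled modifiers express device outages, efficiency loss and
    area quarantine, so that cyberattack-style disruptions and
    mass-casualty overload can be swept over and their effect on
    per-patient treatment duration and outcomes quantified.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
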