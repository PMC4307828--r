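Package: gamenet
Title: Network Density and Diversity Evaluation for Multi-Role Policy
    Simulation Games
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate the structure of collaboration in Web-based
    multi-role policy simulation games from their interaction logs. Provides
    the two classical structural measures used for this purpose: network
    density (the fraction of possible communication ties actually realized)
    and network diversity (normalized Shannon entropy of the distribution of
    repeated communication exchanges over all possible actor pairs). Includes
    a seeded stochastic simulator of a six-role health-policy game that emits
    interaction logs, scores and environmental events; longitudinal windowed
    snapshots of both measures; role-pair collaboration matrices; the
    focal-organization versus whole-network tie comparison; and file-based
    readers, writers and command-line entry points for a reproducible
    simulate-then-evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
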