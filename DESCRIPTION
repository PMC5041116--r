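Package: essalloc
Title: Evolutionarily Stable Resource Allocation and Mating Systems in
    Hermaphroditic Perennial Plants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves for evolutionarily stable strategies (ESS) of resource
    allocation in hermaphroditic perennial plants that divide a fixed
    resource budget among adult survival, male function (pollen) and female
    function (seeds), with inbreeding depression acting on both juvenile and
    adult survivorship. Provides mutant fitness functions (female, male,
    total), closed-form ESS reproductive and sex allocations under linear
    female and power-law male gain curves, an independent best-response
    numerical solver for arbitrary gain curves, second-order (maximality)
    checks, the selection gradient on the selfing rate with the
    complete-selfing versus complete-outcrossing classification and its
    juvenile inbreeding-depression boundary 1/2 - tau, pairwise-invasibility
    analysis, parameter sweeps, bundled scenarios, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
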