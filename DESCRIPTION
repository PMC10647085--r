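Package: chemkg
Title: Chemical-Species Knowledge Graphs: Curation, Validation and Query Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A toolkit for building and exploiting RDF knowledge graphs of
    chemical species. Provides a typed data model for species (identifiers,
    provenance-tracked properties, classifications, GHS hazard statements,
    uses, NMR/MS spectra), a parser that normalises heterogeneous free-text
    property strings into SI-aligned quantities, a curation stage that selects
    recommended values and flags discrepant entries, an embedded triple store
    with Turtle serialisation, shape validation and a SPARQL query subset,
    an ingestion agent for provider payloads including recursive import of
    classification hierarchies, and analysis agents for NMR-based mixture
    identification, multi-criteria co-solvent selection, homologous-series
    trend fitting and classification auditing. A synthetic-fixture generator
    produces provider payloads with known ground truth so the full pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
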