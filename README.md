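# chemkg

Chemical-species knowledge graphs in R: a typed data model and RDF triple
emitter for species (identifiers, provenance-tracked properties,
classifications, GHS hazard statements, uses, NMR/MS spectra), an ingestion
agent that normalises heterogeneous free-text property strings into
SI-aligned quantities and selects recommended values, and query/analysis
agents for NMR-based mixture identification, multi-criteria co-solvent
selection, homologous-series trend fitting and classification auditing.

## Who this is for

Public chemistry databases aggregate property values from many sources as
free-text strings — `"134.4 °F at 760 mmHg (NTP, 1992)"`, `"1,000,000 mg/L
(at 25 °C)"`, `"Miscible."` — with mixed units, inconsistent syntax and the
occasional typo. `chemkg` is for anyone who wants those records as a typed,
validated, queryable knowledge graph: it parses the strings, converts them
to canonical units (K, kPa, kg/m³, g/mol), keeps every value with its
original string and provenance, selects a single *recommended* value per
property, and emits everything as RDF with lexically meaningful IRIs
(`oskg:BoilingPoint_2_Species_<uuid>`).

## The core procedures

**Curation.** Given the canonicalised values v₁…vₙ of one property, records
are grouped by single-linkage on the relative distance
|vᵢ − vⱼ| / min(vᵢ, vⱼ) ≤ 0.10. The largest group wins (ties: center closest
to the global median); within it, metric-unit originals beat imperial ones,
more decimal places beat fewer, then lowest index. The winner's value is
stored as a new record with `os:isRecommended true` and provenance
`"PubChem agent"`. A record is *discrepant* when
|v − v_rec| / v_rec > 0.20.

**NMR mixture identification.** Candidate species (formula CₓHᵧO_z with
x < 5, z < 10, recommended T_b above 15 °C) contribute their first ¹H-NMR
spectrum, pruned of peaks below 20% of the spectrum maximum. Stage 1 keeps a
species when every retained peak lies within ±0.2 ppm of an observed analyte
peak (reference/solvent peaks excluded); stage 2 additionally requires
matching multiplicities and at most one library peak per observed window.

**Trend fitting.** Boiling points of a homologous series are fitted as
T_b(n) = a·n^(1/3) + b over carbon count n (closed-form least squares), and
missing values extrapolated from the fit.

**Auditing.** Structural rules (alkane CₙH₂ₙ₊₂, alkene CₙH₂ₙ with exactly
one double bond, alkanol CₙH₂ₙ₊₂O) are checked against the graph to find
species missing a classification tag and tags inconsistent with the formula.

## Worked example

The bundled methyl-acetate boiling-point strings, end to end:

```r
library(chemkg)

strings <- methyl_acetate_bp_strings()
recs <- list()
for (i in seq_along(strings)) {
  q <- to_canonical(parse_property_string(strings[i])[[1]], "BoilingPoint")
  recs[[i]] <- build_property_record(q, "BoilingPoint", i,
                                     provenance("src", paste0("urn:src:", i)))
}
format_display(sapply(recs, `[[`, "value"))
#> [1] "330.03888" "329.85"    "808.85"    "330.15"    "330.37222"

rec <- select_recommended(recs)
rec
#> <property_record> BoilingPoint[6] = 329.85 K (recommended)

flagged <- flag_discrepant(recs, rec)
sapply(flagged, `[[`, "value")
#> [1] 808.85
```

Reading: the five raw strings canonicalise to kelvin (the °F entry keeps its
760 mmHg reference pressure as a 101.325 kPa reference state); curation
selects 329.85 K — the metric `"56.7 °C"` entry, more precise than
`"57 °C"` — and flags the 808.85 K entry, whose original string
(`"535.70 °C @ 760.00 mmHg (est)"`) is almost certainly a typo, as the one
value deviating more than 20% from the recommended one.

A quick look at the graph side:

```r
store <- kg_store()
sp <- species(chemkg_uuid(), "C3H6O2", properties = c(recs, list(rec)),
              identifiers = list(identifier_record(
                "InChI", "InChI=1S/C3H6O2/c1-3(4)5-2/h1-2H3",
                provenance("PubChem"))))
kg_add_triples(store, emit_species_triples(sp))
validate_shapes(store)
#> <validation_report> conforms
sparql(store, "SELECT ?v WHERE { ?p a os:BoilingPoint .
                                 ?p os:isRecommended true .
                                 ?p os:value ?v }")
#>        v
#> 1 329.85
```

## Layout

- `R/` — formula handling and IRI minting, the quantity parser and unit
  registry, curation, the embedded triple store (Turtle IO, shape
  validation, SPARQL subset), provider interface and ingestion agent,
  analysis agents, synthetic-fixture generators.
- `inst/extdata/shapes.ttl` — declarative rendering of the validation
  shapes.
- `inst/scripts/chemkg-cli.R` — thin command-line wrapper
  (`validate`, `ingest`, `gen-fixtures`, `identify-nmr`, `audit`).
- `vignettes/chemkg-methods.Rmd` — models, parameters, design choices and
  limitations.
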