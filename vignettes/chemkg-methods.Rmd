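---
title: "chemkg: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemkg: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemkg)
```

`chemkg` turns heterogeneous public chemistry records into a typed,
validated RDF knowledge graph and runs query/analysis agents over it. This
vignette documents the models and procedures it implements, the tunable
parameters and their defaults, the numerical choices, what the synthetic
fixtures do and do not emulate, and the design decisions taken where the
behaviour was genuinely open.

## The data model

A species aggregates, each with provenance: identifiers (InChI, InChIKey,
IUPAC name, SMILES, CAS, molecular-formula text), property records,
chemical classes in a parent-linked hierarchy, GHS hazard statements, uses,
spectra (1D/2D NMR with solvent and frequency, MS with ionization mode) and
an optional heavy-atom structure (atoms with optional coordinates, bonds
with integer orders; a bond is an unordered pair). The species label is
always the Hill rendering of its molecular formula — carbon first, hydrogen
second, the rest alphabetical; without carbon, purely alphabetical (sodium
chloride renders as `ClNa`) — and synonyms are alternative labels.

Instance IRIs are lexically meaningful. Species are
`Species_<uuid>`; instances attached to one species are
`<Class>_<index>_Species_<uuid>` with the index counting instances of that
class from 1; free-standing instances are `<Class>_<uuid>`. Free-standing
nodes created during emission (provenance references, uses) derive their
identifier deterministically from the owning species' UUID plus a counter,
so emitting the same species twice yields byte-identical triples and
`load_species(emit_species_triples(s), iri)` is an exact inverse. UUIDs are
128 random bits drawn from R's RNG, so `set.seed()` makes minting
reproducible.

## Parsing property strings

Provider property strings mix units, syntax and noise. The parser:

1. normalises scientific-notation dialects (`1 × 10 + 6`, `1e6`,
   `1.0E+06`) and strips comma thousands separators;
2. extracts every number followed by a recognisable unit (an extensible
   alias table maps spellings such as `deg F`, `mm Hg`, `torr` onto
   canonical units with their dimension and a metric flag);
3. classifies a quantity preceded by `at`/`@` as a *measurement condition*
   rather than a value — the rule that separates `"100 mg/mL at 73 °F"`
   into one solubility value and one temperature condition. This is a
   declared policy: when both the value and a condition are temperatures
   nothing else in the string disambiguates them;
4. records inequality/approximation qualifiers (`at_least`, `at_most`,
   `approx`). Qualified values participate in curation unchanged — sources
   keep such entries, only non-numeric ones are dropped;
5. returns nothing for strings without a numeric value with a unit
   (`"Miscible."`); bare numbers with no recognisable unit (citation years,
   pH values) are treated as faulty and dropped. Comma-decimal locales are
   not supported; such strings fail unit recognition and are discarded with
   a logged reason.

Canonical units are SI-aligned with field conventions: kelvin for
temperatures, **kilopascal** for pressures (the unit reference pressures
are reported in), kg/m³ for densities and mass concentrations, g/mol for
molar masses. Conversions are exact (`°F`: (v − 32)·5/9 + 273.15; mmHg is
defined as 101.325/760 kPa) and `to_canonical()` is idempotent. A quantity
whose unit has the wrong dimension for its claimed property kind raises a
canonicalisation error and the record is discarded with a logged reason.

One display subtlety: curated tables print kelvin values *truncated* at
five decimals (134.4 °F is shown as 330.03888, though the exact conversion
330.03888̄ rounds to 330.03889). `format_display()` therefore truncates
toward zero; stored values are never rounded.

## Curation: recommended values and discrepancies

With several records of one property, `select_recommended()` applies, in
order:

1. **group** values by single-linkage with relative distance
   |vᵢ − vⱼ| / min(|vᵢ|, |vⱼ|) ≤ `rel_tol`;
2. **winning group**: the largest; ties broken by the group median closest
   to the global median;
3. within the winner, prefer records whose original string used **metric**
   units, then the original numeric token with the most **decimal places**,
   then the **lowest index**;
4. store the winner's value as a new record, `is_recommended = TRUE`,
   provenance label `"PubChem agent"`, no original string and no reference
   state (it summarises a group that may span states).

`rel_tol` defaults to 0.10: wide enough to absorb unit-conversion rounding
scatter (the four concordant methyl-acetate entries span 0.16%), narrow
enough to isolate order-of-magnitude typos. The tie-break ladder
(metric → precision → index) is this package's declared policy: the
upstream behaviour is underdetermined, and this is the minimal
deterministic rule set that reproduces the published methyl-acetate
selection (329.85 K from `"56.7 °C"`). `flag_discrepant()` uses a strict
`> 0.20` relative deviation ("20% higher or lower" read as *exceeding*
20%), never flags the recommended record, and is scale-invariant.

## The embedded store, shapes and SPARQL

Triples live in an in-memory frame with typed literals (string, decimal,
integer, dateTime, boolean); decimals are serialised at full double
precision (`%.17g`) so numeric round-trips are exact. Files use a
line-oriented Turtle profile (one triple per line, absolute IRIs; the
reader additionally accepts `@prefix` and prefixed names for hand-written
fixtures — blank nodes and multi-line literals are outside the profile).

`validate_shapes()` enforces the shipped shape set natively (the
declarative SHACL rendering is in `inst/extdata/shapes.ttl`): exactly one
species label; at least one identifier; identifier nodes carry value and
provenance; property nodes carry value, unit and provenance; recommended
property nodes carry the `"PubChem agent"` provenance label; bond orders
are positive integers; peaks have positions. Problems are report entries,
not errors; ingestion refuses to commit a non-conforming graph.

`sparql()` implements the core of SPARQL 1.1 the toolkit's query patterns
need: `SELECT`/`ASK`, basic graph patterns with joins, `FILTER`
(comparisons, boolean connectives, `BOUND`, `STR`, `STRSTARTS`),
`OPTIONAL`, `DISTINCT`, and transitive property paths `p*`/`p+` on a fixed
predicate — the path form class-hierarchy descent needs. Unsupported syntax
fails with the character position, because a silently empty result is the
worst failure mode of a query interface. Canned queries
(`query_boiling_by_class()`) are implemented directly in R and tested for
equivalence against their SPARQL renderings.

Class-hierarchy semantics: subclass links are asserted between class
individuals with a dedicated parent predicate, and every class-membership
query descends it reflexively and transitively — a species tagged *alkanol*
counts as an *alcohol*.

## Ingestion

`ingest_species()` is keyed on InChI (strings starting `InChI=`) or exact
SMILES match — the duplicate-detection rule is this package's choice. A
known key returns the existing IRI untouched. Otherwise: map payloads,
parse and canonicalise every property string (discards logged with
reasons), stamp acquisition dates from an injectable clock, select one
recommended record per property kind (computed properties included, so the
one-recommended-per-kind invariant holds uniformly), resolve the
classification hierarchy recursively to the root, emit, validate shapes,
and only then commit in a single step. All provider interaction happens
before the commit, so any provider failure (after `max_retries` bounded
retries) or shape violation leaves the store exactly as it was.

Hierarchy import (`import_classification_hierarchy()`) instantiates each
ancestor exactly once, skips ancestors already in the store, terminates on
DAGs and reports cycles by naming them. Spectra get sequence numbers in
provider order, which is what "first ¹H-NMR spectrum" selection keys on.
Synonyms are stored verbatim and deduplicated exactly (no case folding —
provider capitalisation can be meaningful).

## Analysis agents

**NMR identification** (`identify_mixture()`), parameters with defaults:
candidate filter C < 5 and O < 10 over C/H/O-only formulas, recommended
T_b > 288.15 K (15 °C — below a 25 °C experiment so partially liquid
species stay in); intensity pruning at 20% of the spectrum maximum;
matching window ±0.2 ppm. Stage 1 requires **all** retained library peaks
covered by observed analyte windows: a species present in the mixture must
exhibit all its major peaks. (The permissive alternative — at least one
peak covered — floods the candidate list with false positives; this
stringency choice is the main open interpretation in the procedure.)
Reference and solvent peaks are excluded by *role* on the observed
spectrum rather than by hard-coded shift constants, so a different
standard/solvent needs no code change; the bundled catholyte spectrum
marks 2.6 ppm (DMSO) as reference and 4.9 ppm (water) as solvent. Stage 2
rejects multiplicity mismatches (unknown library multiplicities pass) and
candidates with two library peaks inside one observed window — a
singlet/triplet/quartet pattern cannot be explained by coinciding peaks.
Species lacking a recommended boiling point or NMR data are excluded, not
guessed.

**Co-solvent selection**: class members (hierarchy descent) with
|T_b − T_b,ref| ≥ 15 K (inclusive — "15 K lower or higher"), excluding GHS
codes starting H350/H360 (carcinogenicity, reproductive toxicity) and
optionally anything boiling above `tb_max_K`. The Δ-criterion is symmetric
by construction.

**Trend fitting**: T_b(n) = a·n^(1/3) + b, linear in the (n^(1/3), 1)
basis and solved by ordinary least squares (`stats::lm`); the cube-root
basis is the conventional form for boiling-point growth along a homologous
series. Requires two distinct carbon counts.

**Auditing**: the rule registry ships alkane (CₙH₂ₙ₊₂, no double bond),
alkene (CₙH₂ₙ, exactly one order-2 bond) and alkanol (CₙH₂ₙ₊₂O); rules are
extensible via YAML. Formula patterns require the exact element set, so an
oxygen-bearing formula never matches the alkene pattern. Whether alkene
detection should additionally require acyclicity is left as stated — the
rule is formula plus double-bond count; ring perception is out of scope.
`find_missing_class_tags()` returns rule-satisfying species not tagged
(directly or via descendants); `check_class_consistency()` returns tagged
species that fail the rule — the C₂₀H₃₈ "alkene" with two double bonds is
the canonical catch.

## Synthetic fixtures

`gen_species_library()` emulates the statistical shape of provider data,
not real compounds: alkane/alkene/alkanol species with carbon counts 1–12,
boiling points following each class's cube-root trend (anchored on the
light and C10 members of the real series, e.g. a = 291, b = −180 for
alkanes) plus Gaussian scatter of 2 K; 2–5 property strings per species in
mixed K/°C/°F dialects with far-off (×2–3) outliers planted at
`outlier_rate` (default 0.1, a deliberately pessimistic typo rate); GHS
codes on ~30% of species; 1–4 NMR peaks uniform in 0.5–10 ppm.
`gen_mixture_spectrum()` jitters planted peaks within ±0.1 ppm — half the
matching window — so planted species are recoverable by construction.
Every artifact draws from a pseudo-random stream keyed by (seed,
purpose-tag), so adding a generator never shifts existing fixtures.

What passing these tests shows: the pipeline's plumbing — parsing,
canonicalisation, curation, emission, validation, matching — is correct on
data with known ground truth. What it does not show: performance on real
spectra (overlapping peaks, baseline noise, chemically realistic shifts)
or real classification data (deep, diamond-shaped hierarchies); fixtures
are statistically, not chemically, realistic.

## Numerical choices and degenerate inputs

- Group relative distance uses min(|vᵢ|, |vⱼ|) in the denominator;
  zero-valued pairs are distance 0 when equal, unreachable otherwise.
- `fit_cube_root` refuses fewer than two distinct n; two points
  interpolate exactly (RSS 0).
- Empty peak lists cannot be pruned (error), empty record lists cannot be
  curated (error); empty annotation sections are valid and yield empty
  collections.
- Duplicate triples are set-deduplicated; class assertions are idempotent.
- Property indices are re-numbered consecutively from 1 per kind at
  species construction, in input order, so IRIs are stable.

## Problem sizes used in the checks

The shipped test suite exercises round-trips on 200 randomised species,
grouping against a transitive-closure oracle on up to 12 records,
hierarchy import against a reachability oracle on random DAGs of up to 50
nodes, and 100 seeded planted-mixture recovery trials over a 12-species
library — sizes at which the brute-force oracles are feasible and the
behaviour space is well covered.

## Known limitations

- No stereochemistry, aromaticity perception or InChI computation;
  identifiers are stored, not derived.
- No qualitative-solubility parsing ("miscible" carries no number and is
  discarded by design).
- The recommended value is a selected member, never an average; no
  uncertainty weighting.
- The SPARQL subset covers the toolkit's query shapes, not the full 1.1
  recommendation (no aggregates, subqueries, federation or updates beyond
  the provided assertion helpers).
- Live provider access is a thin interface; all shipped workflows run from
  local fixtures.
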