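@prefix sh: <http://www.w3.org/ns/shacl#> .
@prefix os: <http://www.theworldavatar.com/ontology/ontospecies/OntoSpecies.owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix : <http://www.theworldavatar.com/kg/ontospecies/shapes#> .

# Declarative rendering of the shape set enforced by validate_shapes().

:SpeciesLabelShape
    a sh:NodeShape ;
    sh:targetClass os:Species ;
    sh:property [
        sh:path rdfs:label ;
        sh:minCount 1 ;
        sh:maxCount 1 ;
        sh:datatype xsd:string ;
    ] .

:SpeciesIdentifierShape
    a sh:NodeShape ;
    sh:targetClass os:Species ;
    sh:property [
        sh:path os:hasIdentifier ;
        sh:minCount 1 ;
    ] .

:IdentifierValueShape
    a sh:NodeShape ;
    sh:targetObjectsOf os:hasIdentifier ;
    sh:property [ sh:path os:value ; sh:minCount 1 ; ] ;
    sh:property [ sh:path os:hasProvenance ; sh:minCount 1 ; ] .

:PropertyValueShape
    a sh:NodeShape ;
    sh:targetObjectsOf os:hasProperty ;
    sh:property [ sh:path os:value ; sh:minCount 1 ; ] ;
    sh:property [ sh:path os:unit ; sh:minCount 1 ; ] ;
    sh:property [ sh:path os:hasProvenance ; sh:minCount 1 ; ] .

:RecommendedAgentShape
    a sh:NodeShape ;
    sh:targetObjectsOf os:hasProperty ;
    # when os:isRecommended is true, the provenance node must be labelled
    # "PubChem agent"
    sh:sparql [
        sh:message "recommended property must carry provenance label 'PubChem agent'" ;
        sh:select """
            SELECT $this WHERE {
                $this os:isRecommended true .
                FILTER NOT EXISTS {
                    $this os:hasProvenance ?ref .
                    ?ref rdfs:label "PubChem agent" .
                }
            }
        """ ;
    ] .

:BondOrderShape
    a sh:NodeShape ;
    sh:targetClass os:AtomicBond ;
    sh:property [
        sh:path os:hasBondOrder ;
        sh:minCount 1 ;
        sh:datatype xsd:integer ;
        sh:minInclusive 1 ;
    ] .

:PeakPositionShape
    a sh:NodeShape ;
    sh:targetClass os:Peak ;
    sh:property [
        sh:path os:peakPosition ;
        sh:minCount 1 ;
    ] .
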