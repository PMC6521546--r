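# Minimal hand-built source documents used across the test files.

minimal_kgml <- function() {
  '<pathway name="path:hsa00001" title="demo">
     <entry id="1" name="hsa:207" type="gene"><graphics name="AKT1"/></entry>
     <entry id="2" name="cpd:C00008" type="compound"/>
     <relation entry1="1" entry2="2" type="PPrel">
       <subtype name="activation" value="--&gt;"/>
     </relation>
   </pathway>'
}

kgml_with_relation <- function(subtype) {
  sprintf('<pathway name="path:hsa00002" title="one relation">
     <entry id="1" name="hsa:207" type="gene"/>
     <entry id="2" name="hsa:208" type="gene"/>
     <relation entry1="1" entry2="2" type="PPrel">
       <subtype name="%s" value="?"/>
     </relation>
   </pathway>', subtype)
}

minimal_gpml <- function() {
  '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="demo wiki">
     <DataNode GraphId="a1" TextLabel="AKT1" Type="GeneProduct">
       <Xref Database="Entrez Gene" ID="207"/>
     </DataNode>
     <DataNode GraphId="m1" TextLabel="ATP" Type="Metabolite">
       <Xref Database="ChEBI" ID="CHEBI:15422"/>
     </DataNode>
     <Interaction><Graphics>
       <Point GraphRef="a1"/>
       <Point GraphRef="m1" ArrowHead="Arrow"/>
     </Graphics></Interaction>
   </Pathway>'
}

minimal_biopax <- function() {
  '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
            xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">
     <bp:Pathway rdf:ID="P1">
       <bp:displayName>demo reactome</bp:displayName>
       <bp:xref rdf:resource="#PX"/>
     </bp:Pathway>
     <bp:UnificationXref rdf:ID="PX"><bp:db>Reactome</bp:db><bp:id>R-HSA-1</bp:id></bp:UnificationXref>
     <bp:Protein rdf:ID="Prot1">
       <bp:displayName>AKT1</bp:displayName>
       <bp:entityReference rdf:resource="#PR1"/>
     </bp:Protein>
     <bp:ProteinReference rdf:ID="PR1"><bp:xref rdf:resource="#X1"/></bp:ProteinReference>
     <bp:UnificationXref rdf:ID="X1"><bp:db>UniProt</bp:db><bp:id>P31749</bp:id></bp:UnificationXref>
     <bp:SmallMolecule rdf:ID="SM1">
       <bp:displayName>ATP</bp:displayName>
       <bp:entityReference rdf:resource="#SR1"/>
     </bp:SmallMolecule>
     <bp:SmallMoleculeReference rdf:ID="SR1"><bp:xref rdf:resource="#X2"/></bp:SmallMoleculeReference>
     <bp:UnificationXref rdf:ID="X2"><bp:db>ChEBI</bp:db><bp:id>15422</bp:id></bp:UnificationXref>
     <bp:SmallMolecule rdf:ID="SM2">
       <bp:displayName>ADP</bp:displayName>
       <bp:entityReference rdf:resource="#SR2"/>
     </bp:SmallMolecule>
     <bp:SmallMoleculeReference rdf:ID="SR2"><bp:xref rdf:resource="#X3"/></bp:SmallMoleculeReference>
     <bp:UnificationXref rdf:ID="X3"><bp:db>ChEBI</bp:db><bp:id>16761</bp:id></bp:UnificationXref>
     <bp:BiochemicalReaction rdf:ID="RX1">
       <bp:left rdf:resource="#SM1"/>
       <bp:right rdf:resource="#SM2"/>
     </bp:BiochemicalReaction>
     <bp:Catalysis rdf:ID="C1">
       <bp:controller rdf:resource="#Prot1"/>
       <bp:controlled rdf:resource="#RX1"/>
       <bp:controlType>ACTIVATION</bp:controlType>
     </bp:Catalysis>
   </rdf:RDF>'
}

# mapping table used by several normalization/conversion tests
demo_mapping <- function() {
  load_mapping_table(tibble::tibble(
    source_prefix = c("uniprot", "kegg", "ncbigene", "chebi"),
    source_id = c("P31749", "hsa:207", "207", "99999"),
    target_prefix = c("hgnc", "ncbigene", "hgnc", "pubchem.compound"),
    target_id = c("391", "207", "391", "5957")))
}

# two-node one-edge unified graph built directly
tiny_graph <- function() {
  nodes <- tibble::tibble(
    key = c("protein|hgnc:391", "abundance|chebi:15422"),
    class = c("protein", "abundance"), prefix = c("hgnc", "chebi"),
    identifier = c("391", "15422"), label = c("AKT1", "ATP"),
    mods = list(character(), character()),
    members = list(character(), character()))
  edges <- tibble::tibble(
    subject = "protein|hgnc:391", object = "abundance|chebi:15422",
    relation = "increases", database = "kegg", pathway_id = "hsa00001",
    pathway_name = "demo", source_relation = "activation")
  pathway_graph(nodes, edges)
}

edge_multiset <- function(g) {
  e <- g$edges
  sort(paste(e$subject, e$object, e$relation, e$database, e$pathway_id,
             e$source_relation, sep = "\r"))
}
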