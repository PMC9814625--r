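<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_model" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="g6p" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="pyr" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_glc" value="5" constant="true"/>
      <parameter id="lb_rev" value="-1000" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_bio" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_hk1" fbc:label="hk1"/>
      <fbc:geneProduct fbc:id="G_hk2" fbc:label="hk2"/>
      <fbc:geneProduct fbc:id="G_pyk1" fbc:label="pyk1"/>
      <fbc:geneProduct fbc:id="G_pyk2" fbc:label="pyk2"/>
      <fbc:geneProduct fbc:id="G_pyk3" fbc:label="pyk3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_glc" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_glc">
        <listOfProducts>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="HEX1" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="glc" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="g6p" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_hk1"/>
            <fbc:geneProductRef fbc:geneProduct="G_hk2"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="PYK" reversible="true" fast="false" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="g6p" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pyr" stoichiometry="2" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_pyk1"/>
              <fbc:geneProductRef fbc:geneProduct="G_pyk2"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_pyk3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_pyr" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="pyr" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_bio" reversible="false" fast="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="pyr" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
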