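<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="TOY__x002D__BIO" fbc:strict="false">
    <notes>
      <body xmlns="http://www.w3.org/1999/xhtml">
        <p>GAM: 0</p>
        <p>NGAM: 0</p>
      </body>
    </notes>
    <listOfCompartments>
      <compartment id="e" name="extracellular" constant="true"/>
      <compartment id="c" name="cytosol" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_A_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="A_e"/>
      <species id="M_A_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="A_c"/>
      <species id="M_P1_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="P1_c"/>
      <species id="M_P2_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="P2_c"/>
      <species id="M_P3_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="P3_c"/>
      <species id="M_P4_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="P4_c"/>
      <species id="M_P5_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="P5_c"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="FB_1" value="-10" constant="true"/>
      <parameter id="FB_2" value="0" constant="true"/>
      <parameter id="FB_3" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_EX_A" reversible="true" fast="false" fbc:lowerFluxBound="FB_1" fbc:upperFluxBound="FB_3" name="EX_A" sboTerm="SBO:0000627">
        <listOfReactants>
          <speciesReference species="M_A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_T_A" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="T_A">
        <listOfReactants>
          <speciesReference species="M_A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gT"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R1" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="R1">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_P1_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gP1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R2" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="R2">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_P2_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gP2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R3" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="R3">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_P3_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gP3"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R4" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="R4">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_P4_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gP4"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R5" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="R5">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_P5_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gP5"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_BIOMASS" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="BIOMASS">
        <listOfReactants>
          <speciesReference species="M_P1_c" stoichiometry="0.20000000000000001" constant="true"/>
          <speciesReference species="M_P2_c" stoichiometry="0.20000000000000001" constant="true"/>
          <speciesReference species="M_P3_c" stoichiometry="0.20000000000000001" constant="true"/>
          <speciesReference species="M_P4_c" stoichiometry="0.20000000000000001" constant="true"/>
          <speciesReference species="M_P5_c" stoichiometry="0.20000000000000001" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_gP1" fbc:label="gP1"/>
      <fbc:geneProduct fbc:id="G_gP2" fbc:label="gP2"/>
      <fbc:geneProduct fbc:id="G_gP3" fbc:label="gP3"/>
      <fbc:geneProduct fbc:id="G_gP4" fbc:label="gP4"/>
      <fbc:geneProduct fbc:id="G_gP5" fbc:label="gP5"/>
      <fbc:geneProduct fbc:id="G_gT" fbc:label="gT"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>
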