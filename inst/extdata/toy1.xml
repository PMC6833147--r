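<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="TOY1" fbc:strict="false">
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
      <species id="M_A_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="A_e" fbc:charge="0" fbc:chemicalFormula="CH2O"/>
      <species id="M_A_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="A_c" fbc:charge="0" fbc:chemicalFormula="CH2O"/>
      <species id="M_B_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="B_c" fbc:charge="0" fbc:chemicalFormula="CH2O"/>
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
          <fbc:geneProductRef fbc:geneProduct="G_g1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R1" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="R1">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_g2"/>
            <fbc:geneProductRef fbc:geneProduct="G_g3"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_GROWTH" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="GROWTH">
        <listOfReactants>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_GROWTH" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>
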