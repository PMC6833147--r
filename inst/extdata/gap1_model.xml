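<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="GAP__x002D__base" fbc:strict="false">
    <listOfCompartments>
      <compartment id="e" name="extracellular" constant="true"/>
      <compartment id="c" name="cytosol" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_S_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="S_e"/>
      <species id="M_S_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="S_c"/>
      <species id="M_M_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="M_c"/>
      <species id="M_T_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="T_c"/>
      <species id="M_D2_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" name="D2_c"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="FB_1" value="-10" constant="true"/>
      <parameter id="FB_2" value="0" constant="true"/>
      <parameter id="FB_3" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_EX_S" reversible="true" fast="false" fbc:lowerFluxBound="FB_1" fbc:upperFluxBound="FB_3" name="EX_S" sboTerm="SBO:0000627">
        <listOfReactants>
          <speciesReference species="M_S_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_T_S" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="T_S">
        <listOfReactants>
          <speciesReference species="M_S_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_S_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_RA" reversible="false" fast="false" fbc:lowerFluxBound="FB_2" fbc:upperFluxBound="FB_3" name="RA">
        <listOfReactants>
          <speciesReference species="M_S_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_M_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
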