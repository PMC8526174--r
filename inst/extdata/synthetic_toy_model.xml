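<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic four-metabolite toy model used by the test suite to exercise
     the SBML stoichiometry reader. Not derived from any real organism. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="synthetic_toy_model">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_a" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="M_b" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="M_c" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="M_d" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>
      <species id="M_ext" compartment="c" boundaryCondition="true" constant="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="M_a" stoichiometry="1" constant="true"/>
          <speciesReference species="M_b" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="M_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_d" stoichiometry="2" constant="true"/>
          <speciesReference species="M_ext" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R3" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="M_d" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_a" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
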