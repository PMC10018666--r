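<ClinicalProtocol id="HA-WBRT_30Gy_10fx">
  <Prescription totalDoseGy="30" fractions="10" dosePerFractionGy="3" target="PTV_3000"/>
  <Machine id="TB1"/>
  <Fields>
    <Field id="ARC1" technique="arc" gantryStart="180.1" gantryStop="179.9" rotation="CW" collimator="345" couch="0" energy="6X"/>
    <Field id="ARC2" technique="arc" gantryStart="179.9" gantryStop="180.1" rotation="CC" collimator="15" couch="0" energy="6X"/>
    <Field id="ARC3" technique="arc" gantryStart="180.1" gantryStop="179.9" rotation="CW" collimator="90" couch="0" energy="6X"/>
  </Fields>
  <Goals>
    <Goal structure="PTV_3000" metric="D2%" comparator="le" threshold="37.5" units="Gy"/>
    <Goal structure="PTV_3000" metric="D98%" comparator="ge" threshold="25" units="Gy"/>
    <Goal structure="PTV_3000" metric="V30Gy" comparator="ge" threshold="95" units="%"/>
    <Goal structure="Hippocampi" metric="D100%" comparator="le" threshold="9" units="Gy"/>
    <Goal structure="Hippocampi" metric="D0.03cc" comparator="le" threshold="16" units="Gy"/>
    <Goal structure="OpticNerves" metric="D0.03cc" comparator="le" threshold="30" units="Gy"/>
    <Goal structure="OpticChiasm" metric="D0.03cc" comparator="le" threshold="30" units="Gy"/>
  </Goals>
  <ExpectedStructures>
    <Structure id="Body"/>
    <Structure id="PTV_3000"/>
    <Structure id="Hippocampi"/>
    <Structure id="OpticNerve_L"/>
    <Structure id="OpticNerve_R"/>
    <Structure id="OpticChiasm"/>
  </ExpectedStructures>
</ClinicalProtocol>
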