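<StructureDictionary>
  <Structure id="PTV_3000">
    <Synonym id="PTV_WB"/>
    <Synonym id="PTV Brain 3000"/>
  </Structure>
  <Structure id="Hippocampi">
    <Synonym id="Hippocampus_Comb"/>
    <Synonym id="Hippocampus"/>
  </Structure>
  <Structure id="OpticChiasm">
    <Synonym id="Optic Chiasm"/>
    <Synonym id="Chiasm"/>
  </Structure>
  <Structure id="OpticNerve_L">
    <Synonym id="Optic Nerve L"/>
    <Synonym id="OpticNrv_L"/>
  </Structure>
  <Structure id="OpticNerve_R">
    <Synonym id="Optic Nerve R"/>
    <Synonym id="OpticNrv_R"/>
  </Structure>
  <Structure id="Body">
    <Synonym id="External"/>
    <Synonym id="BODY"/>
  </Structure>
</StructureDictionary>
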