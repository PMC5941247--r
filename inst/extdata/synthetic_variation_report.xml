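<?xml version="1.0" encoding="UTF-8"?>
<ClinvarResult-Set>
  <VariationReport VariationID="900001" VariationName="NM_000000.0(SYN1):c.1A&gt;G" VariationType="Simple">
    <Allele AlleleID="1900001">
      <XRefList>
        <XRef DB="dbSNP" ID="900000101" Type="rs"/>
      </XRefList>
      <SequenceLocation Assembly="GRCh38" Chr="1" start="10177" referenceAllele="A" alternateAllele="G"/>
    </Allele>
    <ClinicalSignificance DateLastEvaluated="2018-01-19">
      <ReviewStatus>criteria provided, multiple submitters, no conflicts</ReviewStatus>
      <Description>Pathogenic</Description>
    </ClinicalSignificance>
    <ClinicalAssertionList>
      <ClinicalAssertion ID="1" SubmitterName="Synthetic Genetics Lab">
        <ClinicalSignificance DateLastEvaluated="2016-06-14">
          <ReviewStatus>criteria provided, single submitter</ReviewStatus>
          <Description>Pathogenic</Description>
        </ClinicalSignificance>
        <PhenotypeList>
          <Phenotype Name="Synthetic condition A"/>
        </PhenotypeList>
      </ClinicalAssertion>
      <ClinicalAssertion ID="2" SubmitterName="Synthetic Hospital">
        <ClinicalSignificance DateLastEvaluated="2018-01-19">
          <ReviewStatus>criteria provided, single submitter</ReviewStatus>
          <Description>Pathogenic</Description>
        </ClinicalSignificance>
        <PhenotypeList>
          <Phenotype Name="Synthetic condition A"/>
        </PhenotypeList>
      </ClinicalAssertion>
    </ClinicalAssertionList>
  </VariationReport>
</ClinvarResult-Set>
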