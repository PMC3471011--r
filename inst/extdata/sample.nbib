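PMID- 1001
TA  - Kidney Int
DP  - 2005 Mar
TI  - Treatment of IgA nephropathy with corticosteroids: a randomized
      controlled trial.
AB  - We assessed proteinuria reduction in patients with biopsy-proven
      IgA nephropathy.
MH  - Glomerulonephritis, IGA/*therapy
MH  - Proteinuria/drug therapy
MH  - Humans

PMID- 1002
TA  - Am J Kidney Dis
DP  - 2007
TI  - Anemia management in chronic kidney disease.
AB  - Erythropoietin dosing strategies were compared.
MH  - *Anemia/therapy
MH  - Renal Insufficiency, Chronic/complications
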