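# dialect: ovid_embase
(exp *glomerulopathy/ OR nephrotic.tw OR glomerulonephrit$.tw OR diabetic nephropath$.tw OR *diabetic nephropathy/ OR glomerul$ basement membrane$.mp OR nephrotic syndrome/ OR *immunoglobulin a nephropathy/ OR iga nephropath$.tw OR minimal change.mp OR membranoproliferative.tw OR membranous nephropathy.tw OR anca$.mp OR proliferative glomerulonephritis/ OR antineutrophil.mp OR polyang?itis.mp OR *glomerulus/ OR alport$.mp OR hiv-associated nephropath$.tw OR anti-neutrophil.mp OR *anaphylactoid purpura/ OR *wegener granulomatosis/ OR goodpasture$.tw OR mesangioproliferative.tw OR (balkan adj2 nephr$).tw OR ((lupus.mp OR vasculit$.tw OR granulomatosis.mp OR purpur$.tw OR amyloid$.tw) AND (kidney biopsy/ OR proteinuri$.mp OR nephrit$.mp OR serum creatinine.tw)) OR ((exp *diabetes mellitus/ OR proteinuri$.ti OR *proteinuria/) AND (exp glomerulopathy/ OR nephropath$.tw OR *kidney failure/ OR ((kidney or renal) adj disease$).ti OR *microalbuminuria/)) OR ((exp glomerulopathy/ OR diabetic nephropath$.mp) AND (kidney biopsy/ OR mesangial$.tw OR angiotensin$.tw OR serum creatinine.tw OR albuminuri$.mp OR microalbuminuri$.mp)))
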