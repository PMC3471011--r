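# dialect: ovid_embase
(exp glomerulopathy/ OR ((kidney or renal) adj biopsy).mp OR (diabet$ adj (kidney or renal or nephr$)).mp OR nephrotic.tw OR nephrotic syndrome/ OR glomerulonephrit$.tw OR immunoglobulin a nephropathy/ OR glomerul$ basement membrane$.mp OR iga nephropath$.tw OR minimal change.mp OR membranoproliferative.mp OR (glomerul$ adj (nephr$ or disease$ or scleros$)).tw OR membranous nephr$.tw OR anca$.mp OR proliferative glomerulonephritis/ OR wegener granulomatosis/ OR antineutrophil.mp OR polyang?itis.mp OR *glomerulus/ OR anaphylactoid purpura/ OR alport$.mp OR hiv-associated nephropath$.tw OR anti-neutrophil.mp OR mesangioproliferative.mp OR goodpasture$.mp OR (balkan adj2 nephr$).mp OR heymann nephritis/ OR ((lupus.mp OR vasculit$.mp OR purpur$.mp OR hiv$.tw OR granulomatosis.mp) AND ("Urology and nephrology".ec OR proteinuri$.mp OR nephrit$.mp)) OR ((exp *diabetes mellitus/ OR diabet$.ti) AND (nephropath$.tw OR exp *proteinuria/ OR renin-angiotensin$.mp OR dialys$.tw OR *kidney failure/ OR ((kidney OR renal) adj disease$).ti OR h?emodialys$.tw)) OR (exp *kidney disease/ AND (nephropath$.ti OR exp *proteinuria/ OR renin-angiotensin$.mp OR proteinuri$.ti OR amyloid$.mp)) OR ((exp proteinuria/ OR proteinuri$.mp) AND (nephropath$.tw OR nephrit$.mp OR renin-angiotensin$.tw)))
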