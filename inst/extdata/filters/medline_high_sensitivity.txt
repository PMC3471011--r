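# dialect: ovid_medline
(nephropath$.mp OR glomerulonephrit$.mp OR proteinuri$.mp OR nephrotic.mp OR glomerulosclerosis.mp OR nephrit$.mp OR renal biopsy.tw OR albuminuri$.mp OR minimal change.tw OR glomerulopath$.tw OR membranoproliferative.mp OR antineutrophil.mp OR glomerular disease$.tw OR nephrosis.mp OR microalbuminuri$.tw OR anca$.mp OR (diabetic adj (kidney or renal)).mp OR kidney biopsy.tw OR anti-glomerular.mp OR antiglomerular.mp OR anti-neutrophil.mp OR polyang?itis.mp OR alport$.mp OR mesangioproliferative.tw OR goodpasture$.tw OR nephrosclerosis.tw OR *Kidney Glomerulus/ OR *Lupus Erythematosus, Systemic/ OR *Vasculitis/ OR Purpura, Schoenlein-Henoch/ OR exp Anti-Neutrophil Cytoplasmic Antibody-Associated Vasculitis/ OR ((glomerul$.mp OR kidney.mp OR renal.mp OR nephrolog$.mp) AND (lupus.mp OR purpura.mp OR vasculitis.mp OR granulomatosis.mp)) OR ((chronic adj2 (kidney or renal)).mp AND (*Diabetes Mellitus, Type 2/ OR Kidney Glomerulus/)) OR (exp *Kidney Diseases/ AND (biopsy.mp OR myeloma.tw OR renin-angiotensin.mp OR hiv.tw OR amyloid$.mp)))
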