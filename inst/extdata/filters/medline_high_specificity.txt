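# dialect: ovid_medline
(glomerulonephrit$.mp OR (diabetic adj (nephropath$ or kidney)).mp OR nephrotic.mp OR glomerulosclerosis.mp OR iga nephropath$.tw OR minimal change.tw OR glomerulopath$.tw OR membranous nephropathy.tw OR membranoproliferative.mp OR antineutrophil.mp OR glomerular disease$.tw OR nephrosis.mp OR anca$.mp OR anti-glomerular.mp OR anti-neutrophil.mp OR antiglomerular.mp OR polyang?itis.mp OR alport$.mp OR mesangioproliferative.tw OR goodpasture$.tw OR immunoglobulin a nephropathy.tw OR *AIDS-Associated Nephropathy/ OR *Purpura, Schoenlein-Henoch/ OR *Nephritis, Hereditary/ OR exp *Anti-Neutrophil Cytoplasmic Antibody-Associated Vasculitis/ OR *Balkan Nephropathy/ OR (diabet$ AND nephropath$).ti OR ((glomerul$.mp OR kidney.mp OR renal.mp OR nephrit$.mp OR nephrolog$.mp) AND (lupus.mp OR vasculitis.mp OR purpura.mp)) OR ((nephrit$ OR (chronic adj2 (kidney or renal))).mp. AND (Kidney Glomerulus/ OR *Diabetes Mellitus, Type 2/ OR microalbuminuri$.tw. OR immunoglobulin.tw.)) OR ((proteinuri$.ti OR *Proteinuria/) AND (glomerulo$.mp OR h?ematuria.mp OR albuminuri$.tw OR inflammation.tw OR amyloid$.mp OR myeloma.mp)) OR ((glomerulo$.mp OR nephropath$.tw OR proteinuri$.ti OR microalbuminuri$.ti OR albuminuri$.ti) AND (*Diabetes Mellitus, Type 2/ OR exp *Diabetic Angiopathies/ OR overt.tw)) OR (*Kidney Diseases/ AND (amyloid$.mp OR mesangio$.tw OR sclerosis.tw)))
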