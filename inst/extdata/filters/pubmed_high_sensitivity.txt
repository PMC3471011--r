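# dialect: pubmed
(nephropath*[tw] OR glomerulonephrit*[tw] OR proteinuri*[tw] OR nephrotic[tw] OR glomerulosclerosis[tw] OR nephrit*[tw] OR kidney biopsy[tiab] OR renal biopsy[tiab] OR albuminuri*[tw] OR glomerulopath*[tiab] OR membranoproliferative[tw] OR mesangioproliferative[tiab] OR nephrosis[tw] OR microalbuminuri*[tiab] OR diabetic kidney[tw] OR diabetic renal[tw] OR anti-glomerular[tw] OR nephrosclerosis[tiab] OR alport*[tw] OR goodpasture*[tiab] OR minimal change[tiab] OR glomerular disease*[tiab] OR anca*[tw] OR anti-neutrophil[tw] OR polyangiitis[tw] OR polyangitis[tw] OR antineutrophil[tw] OR antiglomerular[tw] OR "Kidney Glomerulus"[majr:noexp] OR "Lupus Erythematosus, Systemic"[majr:noexp] OR "Vasculitis"[majr:noexp] OR "Purpura, Schoenlein-Henoch"[mh:noexp] OR "Anti-Neutrophil Cytoplasmic Antibody-Associated Vasculitis"[mh] OR ((lupus[tw] OR vasculitis[tw] OR purpura[tw] OR granulomatosis[tw]) AND (glomerul*[tw] OR kidney[tw] OR renal[tw] OR nephrolog*[tw])) OR ((chronic kidney[tiab] OR chronic renal[tiab] OR "Renal Insufficiency, Chronic"[mh]) AND ("Diabetes Mellitus, Type 2"[majr:noexp] OR "Kidney Glomerulus"[mh:noexp])) OR ("Kidney Diseases"[majr] AND (biopsy[tw] OR myeloma[tiab] OR renin-angiotensin[tw] OR hiv[tiab] OR amyloid*[tw])))
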