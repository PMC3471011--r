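# dialect: pubmed
(glomerulonephrit*[tw] OR nephrotic[tw] OR diabetic nephropath*[tw] OR glomerulosclerosis[tw] OR iga nephropath*[tiab] OR minimal change[tiab] OR membranoproliferative[tw] OR glomerulopath*[tiab] OR membranous nephropathy[tiab] OR antineutrophil[tw] OR nephrosis[tw] OR anca*[tw] OR diabetic kidney[tiab] OR anti-glomerular[tw] OR glomerular disease*[tiab] OR anti-neutrophil[tw] OR antiglomerular[tw] OR polyangiitis[tw] OR alport*[tw] OR mesangioproliferative[tiab] OR goodpasture*[tiab] OR immunoglobulin a nephropathy[tiab] OR "AIDS-Associated Nephropathy"[majr:noexp] OR "Purpura, Schoenlein-Henoch"[majr:noexp] OR "Nephritis, Hereditary"[majr:noexp] OR "Anti-Neutrophil Cytoplasmic Antibody-Associated Vasculitis"[majr] OR "Balkan Nephropathy"[majr:noexp] OR (diabet*[ti] AND nephropath*[ti]) OR ((kidney[tw] OR renal[tw] OR nephrit*[tw] OR nephrolog*[tw] OR glomerul*[tw]) AND (purpura[tw] OR lupus[tw] OR vasculitis[tw])) OR ((nephrit*[tw] OR "Renal Insufficiency, Chronic"[mh] OR chronic kidney[tiab] OR chronic renal[tiab]) AND ("Kidney Glomerulus"[mh:noexp] OR "Diabetes Mellitus, Type 2"[majr:noexp] OR microalbuminuri*[tiab] OR immunoglobulin[tiab])) OR ((proteinuri*[ti] OR "Proteinuria"[majr:noexp]) AND (hematuria[tw] OR haematuria[tiab] OR glomerulo*[tw] OR amyloid*[tw] OR albuminuri*[tiab] OR inflammation[tiab] OR myeloma[tw])) OR ((glomerulo*[tw] OR nephropath*[tiab] OR proteinuri*[ti] OR microalbuminuri*[ti] OR albuminuri*[ti]) AND ("Diabetes Mellitus, Type 2"[majr:noexp] OR "Diabetic Angiopathies"[majr] OR overt[tiab])) OR ("Kidney Diseases"[majr:noexp] AND (amyloid*[tw] OR mesangio*[tiab] OR sclerosis[tiab])))
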