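{
  "vocabulary_id": "toy-mesh",
  "descriptors": [
    {"name": "Kidney", "tree_numbers": ["A05.810.453"], "entry_terms": []},
    {"name": "Kidney Glomerulus", "tree_numbers": ["A05.810.453.324"], "entry_terms": ["Renal Glomerulus", "Glomerulus"]},
    {"name": "Urologic Diseases", "tree_numbers": ["C12.777"], "entry_terms": []},
    {"name": "Kidney Diseases", "tree_numbers": ["C12.777.419"], "entry_terms": ["Renal Disease", "Kidney Disease"]},
    {"name": "AIDS-Associated Nephropathy", "tree_numbers": ["C12.777.419.030"], "entry_terms": ["HIV-Associated Nephropathy"]},
    {"name": "Diabetic Nephropathies", "tree_numbers": ["C12.777.419.192", "C14.907.320.382"], "entry_terms": ["Diabetic Kidney Disease", "Diabetic Nephropathy"]},
    {"name": "Glomerulonephritis", "tree_numbers": ["C12.777.419.570"], "entry_terms": ["Bright Disease"]},
    {"name": "Anti-Glomerular Basement Membrane Disease", "tree_numbers": ["C12.777.419.570.075"], "entry_terms": ["Goodpasture Syndrome"]},
    {"name": "Glomerulonephritis, IGA", "tree_numbers": ["C12.777.419.570.363"], "entry_terms": ["IgA Nephropathy", "Berger Disease"]},
    {"name": "Glomerulonephritis, Membranoproliferative", "tree_numbers": ["C12.777.419.570.443"], "entry_terms": ["Mesangiocapillary Glomerulonephritis"]},
    {"name": "Glomerulonephritis, Membranous", "tree_numbers": ["C12.777.419.570.480"], "entry_terms": ["Membranous Nephropathy"]},
    {"name": "Glomerulosclerosis, Focal Segmental", "tree_numbers": ["C12.777.419.570.560"], "entry_terms": ["Focal Segmental Glomerulosclerosis"]},
    {"name": "Lupus Nephritis", "tree_numbers": ["C12.777.419.570.633", "C17.300.480.750"], "entry_terms": ["Lupus Glomerulonephritis"]},
    {"name": "Nephritis", "tree_numbers": ["C12.777.419.780"], "entry_terms": []},
    {"name": "Balkan Nephropathy", "tree_numbers": ["C12.777.419.780.250"], "entry_terms": ["Balkan Endemic Nephropathy"]},
    {"name": "Nephritis, Hereditary", "tree_numbers": ["C12.777.419.780.500"], "entry_terms": ["Alport Syndrome"]},
    {"name": "Renal Insufficiency", "tree_numbers": ["C12.777.419.787"], "entry_terms": ["Kidney Failure"]},
    {"name": "Renal Insufficiency, Chronic", "tree_numbers": ["C12.777.419.787.500"], "entry_terms": ["Chronic Kidney Disease", "Chronic Renal Insufficiency"]},
    {"name": "Nephrotic Syndrome", "tree_numbers": ["C12.777.419.815"], "entry_terms": ["Nephrosis, Lipoid"]},
    {"name": "Urination Disorders", "tree_numbers": ["C12.777.934"], "entry_terms": []},
    {"name": "Proteinuria", "tree_numbers": ["C12.777.934.734"], "entry_terms": []},
    {"name": "Albuminuria", "tree_numbers": ["C12.777.934.734.634"], "entry_terms": ["Microalbuminuria"]},
    {"name": "Vascular Diseases", "tree_numbers": ["C14.907"], "entry_terms": []},
    {"name": "Diabetic Angiopathies", "tree_numbers": ["C14.907.320"], "entry_terms": []},
    {"name": "Vasculitis", "tree_numbers": ["C14.907.940"], "entry_terms": ["Angiitis"]},
    {"name": "Anti-Neutrophil Cytoplasmic Antibody-Associated Vasculitis", "tree_numbers": ["C14.907.940.090"], "entry_terms": ["ANCA-Associated Vasculitis"]},
    {"name": "Granulomatosis with Polyangiitis", "tree_numbers": ["C14.907.940.090.340"], "entry_terms": ["Wegener Granulomatosis"]},
    {"name": "Microscopic Polyangiitis", "tree_numbers": ["C14.907.940.090.530"], "entry_terms": ["Microscopic Polyarteritis"]},
    {"name": "Purpura, Schoenlein-Henoch", "tree_numbers": ["C14.907.940.740"], "entry_terms": ["Anaphylactoid Purpura", "Henoch-Schoenlein Purpura"]},
    {"name": "Connective Tissue Diseases", "tree_numbers": ["C17.300"], "entry_terms": []},
    {"name": "Lupus Erythematosus, Systemic", "tree_numbers": ["C17.300.480"], "entry_terms": ["Systemic Lupus Erythematosus", "SLE"]},
    {"name": "Diabetes Mellitus", "tree_numbers": ["C18.452.394"], "entry_terms": []},
    {"name": "Diabetes Mellitus, Type 2", "tree_numbers": ["C18.452.394.750"], "entry_terms": ["Non-Insulin-Dependent Diabetes Mellitus", "NIDDM"]}
  ]
}
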