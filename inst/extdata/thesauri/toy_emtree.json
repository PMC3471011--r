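{
  "vocabulary_id": "toy-emtree",
  "descriptors": [
    {"name": "kidney", "tree_numbers": ["A01"], "entry_terms": []},
    {"name": "glomerulus", "tree_numbers": ["A01.100"], "entry_terms": ["kidney glomerulus"]},
    {"name": "kidney disease", "tree_numbers": ["C01"], "entry_terms": ["renal disease", "nephropathy"]},
    {"name": "glomerulopathy", "tree_numbers": ["C01.100"], "entry_terms": ["glomerular disease"]},
    {"name": "glomerulonephritis", "tree_numbers": ["C01.100.200"], "entry_terms": []},
    {"name": "proliferative glomerulonephritis", "tree_numbers": ["C01.100.200.100"], "entry_terms": ["mesangioproliferative glomerulonephritis"]},
    {"name": "membranous glomerulonephritis", "tree_numbers": ["C01.100.200.150"], "entry_terms": ["membranous nephropathy"]},
    {"name": "immunoglobulin a nephropathy", "tree_numbers": ["C01.100.200.200"], "entry_terms": ["iga nephropathy", "berger disease"]},
    {"name": "heymann nephritis", "tree_numbers": ["C01.100.200.250"], "entry_terms": []},
    {"name": "lupus erythematosus nephritis", "tree_numbers": ["C01.100.200.300"], "entry_terms": ["lupus nephritis"]},
    {"name": "nephrotic syndrome", "tree_numbers": ["C01.100.300"], "entry_terms": ["nephrosis"]},
    {"name": "diabetic nephropathy", "tree_numbers": ["C01.100.350"], "entry_terms": ["diabetic kidney disease"]},
    {"name": "glomerulosclerosis", "tree_numbers": ["C01.100.400"], "entry_terms": ["focal glomerulosclerosis"]},
    {"name": "kidney failure", "tree_numbers": ["C01.200"], "entry_terms": ["renal failure"]},
    {"name": "chronic kidney failure", "tree_numbers": ["C01.200.100"], "entry_terms": ["chronic renal failure"]},
    {"name": "proteinuria", "tree_numbers": ["C01.300"], "entry_terms": []},
    {"name": "microalbuminuria", "tree_numbers": ["C01.300.100"], "entry_terms": []},
    {"name": "albuminuria", "tree_numbers": ["C01.300.200"], "entry_terms": []},
    {"name": "diabetes mellitus", "tree_numbers": ["C02"], "entry_terms": []},
    {"name": "insulin dependent diabetes mellitus", "tree_numbers": ["C02.100"], "entry_terms": ["type 1 diabetes mellitus"]},
    {"name": "non insulin dependent diabetes mellitus", "tree_numbers": ["C02.200"], "entry_terms": ["type 2 diabetes mellitus"]},
    {"name": "vasculitis", "tree_numbers": ["C03"], "entry_terms": []},
    {"name": "wegener granulomatosis", "tree_numbers": ["C03.100"], "entry_terms": ["granulomatosis with polyangiitis"]},
    {"name": "anaphylactoid purpura", "tree_numbers": ["C03.200"], "entry_terms": ["henoch schoenlein purpura"]},
    {"name": "microscopic polyangiitis", "tree_numbers": ["C03.300"], "entry_terms": []},
    {"name": "kidney biopsy", "tree_numbers": ["P01"], "entry_terms": ["renal biopsy"]}
  ]
}
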