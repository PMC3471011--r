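n_journals: 20
articles_per_journal: 250
prevalence: 0.05
filler_vocab_size: 200
filler_terms_per_record: 8
indexing_dropout: 0.10
seed: 1
profiles:
  - surfaces: [proteinuria]
    p_text_rel: 0.90
    p_text_irr: 0.05
  - surfaces: [glomerulonephritis]
    p_text_rel: 0.60
    p_text_irr: 0.02
    descriptor: Glomerulonephritis
    p_index_rel: 0.60
    p_index_irr: 0.03
    p_major_given_indexed: 0.5
  - surfaces: [polyangiitis, polyangitis]
    weights: [0.7, 0.3]
    p_text_rel: 0.40
    p_text_irr: 0.01
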