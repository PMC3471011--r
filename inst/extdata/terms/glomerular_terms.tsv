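# base	has_descriptor	fields	truncation
proteinuria	false	tw,tiab	true
glomerulonephritis	true	tw	true
polyangiitis	false	tw	false
nephrotic	false	tw,ti	false
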