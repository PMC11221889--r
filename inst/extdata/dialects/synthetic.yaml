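name: synthetic
provenance: synthetic
sep: ","
chain_sep: ";"
mutation_style: colon
col_complex: complex_id
col_ab_chains: ab_chains
col_ag_chains: ag_chains
col_ab_seq: ab_seq
col_ag_seq: ag_seq
col_mutations: mutations
col_ddg: ddg
col_offsets: offsets
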