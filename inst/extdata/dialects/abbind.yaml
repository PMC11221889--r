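# AB-Bind-style tables. The distributed AB-Bind CSV carries complex ids,
# mutation strings and ddG but not chain sequences; sequence columns
# (';'-separated per role, matching the chain-id columns) must be joined
# in before loading. An optional per-chain 'offsets' column maps
# author/PDB numbering onto 1-based sequence positions.
name: abbind
provenance: abbind
sep: ","
chain_sep: ";"
mutation_style: colon
col_complex: "#PDB"
col_ab_chains: ab_chains
col_ag_chains: ag_chains
col_ab_seq: ab_seq
col_ag_seq: ag_seq
col_mutations: Mutation
col_ddg: ddG(kcal/mol)
col_offsets: offsets
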