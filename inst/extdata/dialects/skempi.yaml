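# SKEMPI 2.0-style tables (';'-separated file, 'YA32W' mutation tokens).
# Chain sequence columns must be joined in before loading, as for the
# abbind dialect.
name: skempi
provenance: skempi
sep: ";"
chain_sep: "|"
mutation_style: skempi
col_complex: "#Pdb"
col_ab_chains: ab_chains
col_ag_chains: ag_chains
col_ab_seq: ab_seq
col_ag_seq: ag_seq
col_mutations: Mutation(s)_cleaned
col_ddg: ddG
col_offsets: offsets
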