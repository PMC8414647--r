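input:
  clone_tables:
    EXP01: samples/EXP01.tsv
    EXP02: samples/EXP02.tsv
  dialect: native
germline:
  fasta: germline.fasta
  boundaries: boundaries.yaml
analysis:
  use_c_gene: yes
reference:
  catalog_dir: reference
  criteria:
    health_condition: Healthy
antibody_db: antibody_db.tsv
public_clones:
  sharing_key: cdr3aa
  min_share: 2.0
enrichment:
  cutoff: 0.05
output:
  dir: repscope_out
seed: 1.0
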