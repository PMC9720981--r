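{
  "description": "Canonical gated-subset dictionary: column name, parent population the percentage refers to, lineage, and whether the subset belongs to the exhaustive CD45RA/CCR7 differentiation quartet. All frequencies are percent of the stated parent.",
  "units": "percent_of_parent",
  "subsets": [
    {"name": "tcell_of_lymphs", "parent": "lymphocytes", "lineage": "T", "quartet": false, "definition": "CD3+ of lymphocytes"},
    {"name": "bcell_of_lymphs", "parent": "lymphocytes", "lineage": "B", "quartet": false, "definition": "CD19+ of lymphocytes"},
    {"name": "cd4_of_t", "parent": "tcell_of_lymphs", "lineage": "T", "quartet": false, "definition": "CD4+ of T cells"},
    {"name": "cd8_of_t", "parent": "tcell_of_lymphs", "lineage": "T", "quartet": false, "definition": "CD8+ of T cells"},
    {"name": "cd4_naive", "parent": "cd4_of_t", "lineage": "T", "quartet": true, "definition": "CD45RA+CCR7+ of CD4"},
    {"name": "cd4_cm", "parent": "cd4_of_t", "lineage": "T", "quartet": true, "definition": "CD45RA-CCR7+ of CD4"},
    {"name": "cd4_em", "parent": "cd4_of_t", "lineage": "T", "quartet": true, "definition": "CD45RA-CCR7- of CD4"},
    {"name": "cd4_emra", "parent": "cd4_of_t", "lineage": "T", "quartet": true, "definition": "CD45RA+CCR7- of CD4"},
    {"name": "cd8_naive", "parent": "cd8_of_t", "lineage": "T", "quartet": true, "definition": "CD45RA+CCR7+ of CD8"},
    {"name": "cd8_cm", "parent": "cd8_of_t", "lineage": "T", "quartet": true, "definition": "CD45RA-CCR7+ of CD8"},
    {"name": "cd8_em", "parent": "cd8_of_t", "lineage": "T", "quartet": true, "definition": "CD45RA-CCR7- of CD8"},
    {"name": "cd8_emra", "parent": "cd8_of_t", "lineage": "T", "quartet": true, "definition": "CD45RA+CCR7- of CD8"},
    {"name": "cd4_cd28neg", "parent": "cd4_of_t", "lineage": "T", "quartet": false, "definition": "CD28- of CD4"},
    {"name": "cd4_cd57pos", "parent": "cd4_of_t", "lineage": "T", "quartet": false, "definition": "CD57+ of CD4"},
    {"name": "cd4_senescent", "parent": "cd4_of_t", "lineage": "T", "quartet": false, "definition": "CD28-CD57+ of CD4"},
    {"name": "cd8_cd28neg", "parent": "cd8_of_t", "lineage": "T", "quartet": false, "definition": "CD28- of CD8"},
    {"name": "cd8_cd57pos", "parent": "cd8_of_t", "lineage": "T", "quartet": false, "definition": "CD57+ of CD8"},
    {"name": "cd8_senescent", "parent": "cd8_of_t", "lineage": "T", "quartet": false, "definition": "CD28-CD57+ of CD8"},
    {"name": "rte_of_naive_cd4", "parent": "cd4_naive", "lineage": "T", "quartet": false, "definition": "PTK7+ recent thymic emigrants of naive CD4"},
    {"name": "treg_of_cd4", "parent": "cd4_of_t", "lineage": "T", "quartet": false, "definition": "CD25+Foxp3+ regulatory T cells of CD4"},
    {"name": "b_naive", "parent": "bcell_of_lymphs", "lineage": "B", "quartet": false, "definition": "CD27-IgD+ of B"},
    {"name": "b_switched_mem", "parent": "bcell_of_lymphs", "lineage": "B", "quartet": false, "definition": "CD27+IgD- of B"},
    {"name": "b_unswitched_mem", "parent": "bcell_of_lymphs", "lineage": "B", "quartet": false, "definition": "CD27+IgD+ of B"},
    {"name": "breg_of_b", "parent": "bcell_of_lymphs", "lineage": "B", "quartet": false, "definition": "CD24hiCD38hi regulatory B cells of B"}
  ]
}
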