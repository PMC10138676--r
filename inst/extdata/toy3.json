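{
  "id": "toy3",
  "metabolites": [
    {"id": "a_e", "name": "metabolite A (extracellular)", "compartment": "e", "formula": "C2H4O2", "charge": 0},
    {"id": "a_c", "name": "metabolite A (cytosol)", "compartment": "c", "formula": "C2H4O2", "charge": 0}
  ],
  "reactions": [
    {"id": "EX_a_e", "name": "A exchange", "metabolites": {"a_e": -1}, "lower_bound": -1000, "upper_bound": 1000, "gene_reaction_rule": "", "objective_coefficient": 0},
    {"id": "TRANS_a", "name": "A transport", "metabolites": {"a_e": -1, "a_c": 1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g1", "objective_coefficient": 0},
    {"id": "DM_a_c", "name": "A demand", "metabolites": {"a_c": -1}, "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "", "objective_coefficient": 1}
  ],
  "genes": [
    {"id": "g1", "name": "g1"}
  ],
  "compartments": {"c": "cytosol", "e": "extracellular space"},
  "version": "1"
}
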