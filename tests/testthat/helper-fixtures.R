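# Hand-built miniature models used by several test files.

# linear chain: EX_a -> transport -> demand (growth = uptake)
chain_model <- function() {
  metabolic_model(
    id = "chain",
    metabolites = tibble::tibble(
      id = c("a_e", "a_c", "b_c"),
      formula = c("C2H4O2", "C2H4O2", "C2H4O2"),
      charge = 0L,
      compartment = c("e", "c", "c")),
    reactions = tibble::tibble(
      id = c("EX_a_e", "TRANS_a", "CONV", "DM_b"),
      stoichiometry = list(c(a_e = -1), c(a_e = -1, a_c = 1),
                           c(a_c = -1, b_c = 1), c(b_c = -1)),
      lower_bound = c(-1000, 0, 0, 0),
      upper_bound = 1000,
      gpr = ""),
    objective_id = "DM_b")
}

# closed cycle A -> B -> C -> A (no dead ends, no growth)
cycle_model <- function() {
  metabolic_model(
    id = "cycle",
    metabolites = tibble::tibble(
      id = c("a_c", "b_c", "c_c"), formula = "CH2O", charge = 0L,
      compartment = "c"),
    reactions = tibble::tibble(
      id = c("R1", "R2", "R3"),
      stoichiometry = list(c(a_c = -1, b_c = 1), c(b_c = -1, c_c = 1),
                           c(c_c = -1, a_c = 1)),
      lower_bound = 0, upper_bound = 1000, gpr = ""),
    objective_id = "R1")
}

# default toy + glucose medium shared by many tests
toy_glc_medium <- function(uptake = 10) {
  medium(list(EX_glc_e = c(-uptake, 1000)), name = "toy-glc")
}

pheno_from_growth_matrix <- function(gm) {
  wide <- tidyr::pivot_wider(gm[, c("strain", "carbon_source", "grows")],
                             names_from = "carbon_source",
                             values_from = "grows")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$strain
  m
}
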