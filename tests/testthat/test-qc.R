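test_that("formula parsing handles counts, multi-letter elements and unknowns", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("HO4P"), c(H = 1, O = 4, P = 1))
  expect_equal(parse_formula("C10H15N5O10P2"),
               c(C = 10, H = 15, N = 5, O = 10, P = 2))
  expect_equal(parse_formula("CuSO4"), c(Cu = 1, O = 4, S = 1))
  expect_null(parse_formula(""))
  expect_null(parse_formula(NA))
  expect_null(parse_formula("C6H11O5R"))   # polymeric residue: unknown
  expect_null(parse_formula("X2"))
  expect_null(parse_formula("c6h12"))      # not a valid element casing
})

test_that("transport of identical species is balanced; planted defects are not", {
  mets <- tibble::tibble(
    id = c("glc__D_e", "glc__D_c", "x_c", "y_c", "h2o_c", "p0_c", "p1_c"),
    formula = c("C6H12O6", "C6H12O6", "C3H6O3", "C3H4O2", "H2O",
                "H3O4P", "H3O4P"),
    charge = c(0L, 0L, 0L, 0L, 0L, 0L, -1L),
    compartment = c("e", "c", "c", "c", "c", "c", "c"))
  rxns <- tibble::tibble(
    id = c("GLCt", "DEHYD_OK", "DEHYD_NOW", "CHG"),
    stoichiometry = list(
      c(glc__D_e = -1, glc__D_c = 1),           # transport: balanced
      c(x_c = -1, y_c = 1, h2o_c = 1),          # dehydration with its water
      c(x_c = -1, y_c = 1),                     # same, water forgotten
      c(p0_c = -1, p1_c = 1)),                  # mass ok, charge off by -1
    lower_bound = 0, upper_bound = 1000, gpr = "")
  m <- metabolic_model("bal", mets, rxns)
  rep <- check_mass_charge_balance(m)

  expect_equal(rep$status[rep$reaction_id == "GLCt"], "balanced")
  expect_equal(rep$status[rep$reaction_id == "DEHYD_OK"], "balanced")
  expect_equal(rep$status[rep$reaction_id == "DEHYD_NOW"], "mass_unbalanced")
  imb <- rep$element_imbalance[[which(rep$reaction_id == "DEHYD_NOW")]]
  expect_equal(imb[order(names(imb))], c(H = -2, O = -1))
  expect_equal(rep$status[rep$reaction_id == "CHG"], "charge_unbalanced")
  expect_equal(rep$charge_imbalance[rep$reaction_id == "CHG"], -1)
})

test_that("unknown formulas yield unknown_formula, never a crash or a verdict", {
  mets <- tibble::tibble(id = c("r_c", "s_c"), formula = c("C5H8R", "C5H8O2"),
                         charge = 0L, compartment = "c")
  rxns <- tibble::tibble(id = "RX", stoichiometry = list(c(r_c = -1, s_c = 1)),
                         lower_bound = 0, upper_bound = 10, gpr = "")
  rep <- check_mass_charge_balance(metabolic_model("u", mets, rxns))
  expect_equal(rep$status, "unknown_formula")
})

test_that("balance audit is linear: doubling coefficients keeps balance", {
  toy <- make_toy_gem()
  m <- toy$model
  i <- which(m$reactions$id == "CATAB_glc")
  m$reactions$stoichiometry[[i]] <- 2 * m$reactions$stoichiometry[[i]]
  rep <- check_mass_charge_balance(m)
  expect_equal(rep$status[rep$reaction_id == "CATAB_glc"], "balanced")
})

test_that("biomass and exchange reactions are exempt from the balance audit", {
  toy <- make_toy_gem()
  rep <- check_mass_charge_balance(toy$model)
  expect_false(any(rep$reaction_id %in%
                     c("BIOMASS", exchange_reactions(toy$model))))
  expect_true(all(rep$status == "balanced"))
})

test_that("dead-end analysis: cycles are clean, chains strand their ends", {
  expect_equal(nrow(find_dead_end_metabolites(cycle_model())), 0)

  # linear chain with no exit for the last metabolite
  mets <- tibble::tibble(id = c("a_c", "b_c", "c_c"), formula = "CH2O",
                         charge = 0L, compartment = "c")
  rxns <- tibble::tibble(
    id = c("R1", "R2"),
    stoichiometry = list(c(a_c = -1, b_c = 1), c(b_c = -1, c_c = 1)),
    lower_bound = 0, upper_bound = 1000, gpr = "")
  de <- find_dead_end_metabolites(metabolic_model("chain", mets, rxns))
  expect_equal(de$type[de$metabolite_id == "c_c"], "produced_only")
  expect_equal(de$type[de$metabolite_id == "a_c"], "consumed_only")

  # a reversible step produces and consumes both ends
  rxns2 <- rxns
  rxns2$lower_bound <- -1000
  de2 <- find_dead_end_metabolites(metabolic_model("chain2", mets, rxns2))
  expect_equal(nrow(de2), 0)
})

test_that("planted orphan metabolites are recovered exactly", {
  for (k in c(1, 3)) {
    toy <- make_toy_gem(toy_gem_spec(defects = "orphan_metabolite",
                                     n_orphans = k))
    de <- find_dead_end_metabolites(toy$model)
    expect_equal(de[order(de$metabolite_id), ],
                 toy$answer$dead_ends[order(toy$answer$dead_ends$metabolite_id), ])
  }
})

test_that("dead-end set grows (or stays) when a reaction is removed", {
  toy <- make_toy_gem()
  base <- find_dead_end_metabolites(toy$model)$metabolite_id
  for (rid in setdiff(toy$model$reactions$id, "BIOMASS")) {
    m <- gemkit:::subset_reactions(toy$model,
                                   setdiff(toy$model$reactions$id, rid))
    after <- find_dead_end_metabolites(m)$metabolite_id
    expect_true(all(base %in% after), info = rid)
  }
})

test_that("energy-cycle check: clean model is silent, planted loop flagged, direction fix heals", {
  clean <- make_toy_gem()
  expect_equal(check_energy_generating_cycle(clean$model), 0, tolerance = 1e-9)

  looped <- make_toy_gem(toy_gem_spec(defects = "futile_atp_loop"))
  flux <- check_energy_generating_cycle(looped$model)
  expect_gt(flux, 1e-6)

  # making the planted reaction irreversible (hydrolysis only) kills the cycle
  fixed <- set_bounds(looped$model, looped$answer$futile_reaction, lower = 0)
  expect_equal(check_energy_generating_cycle(fixed), 0, tolerance = 1e-9)

  no_atpm <- clean$model
  no_atpm$atpm_id <- NULL
  expect_error(check_energy_generating_cycle(no_atpm),
               class = "gemkit_config_error")
})

test_that("the QC battery aggregates findings from all checks", {
  toy <- make_toy_gem(toy_gem_spec(defects = c("unbalanced_reaction",
                                               "futile_atp_loop",
                                               "orphan_metabolite")))
  findings <- validate_model_qc(toy$model)
  expect_setequal(unique(findings$check),
                  c("balance", "dead_end", "energy_cycle"))
  expect_true("UNBAL_PLANT" %in% findings$id)
  expect_true("orphan1_c" %in% findings$id)
})
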