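test_that("model construction validates its invariants", {
  mets <- tibble::tibble(id = c("a_c", "a_e"), formula = "CH2O", charge = 0L,
                         compartment = c("c", "e"))
  rxns <- tibble::tibble(id = "R1", stoichiometry = list(c(a_c = -1, a_e = 1)),
                         lower_bound = 0, upper_bound = 10, gpr = "g1")
  m <- metabolic_model("m", mets, rxns, objective_id = "R1")
  expect_s3_class(m, "metabolic_model")
  expect_equal(m$genes, "g1")

  bad_bounds <- rxns; bad_bounds$lower_bound <- 20
  expect_error(metabolic_model("m", mets, bad_bounds),
               class = "gemkit_model_error")
  bad_ref <- rxns; bad_ref$stoichiometry <- list(c(zz_c = -1))
  expect_error(metabolic_model("m", mets, bad_ref),
               class = "gemkit_model_error")
  bad_suffix <- mets; bad_suffix$compartment <- c("e", "c")
  expect_error(metabolic_model("m", bad_suffix, rxns),
               class = "gemkit_model_error")
  expect_error(metabolic_model("m", mets, rxns, objective_id = "nope"),
               class = "gemkit_model_error")
})

test_that("model_summary counts unique ids, genes counted once", {
  empty <- metabolic_model("empty",
    tibble::tibble(id = character(), formula = character(),
                   charge = integer(), compartment = character()),
    tibble::tibble(id = character(), stoichiometry = list(),
                   lower_bound = numeric(), upper_bound = numeric(),
                   gpr = character()))
  expect_equal(unlist(model_summary(empty)), c(reactions = 0, metabolites = 0,
                                               genes = 0))

  # same gene reused in several GPRs is counted once
  toy <- make_toy_gem()
  m <- toy$model
  m$reactions$gpr[m$reactions$id == "WASTEt"] <- "tr_glc"
  m2 <- metabolic_model(m$id, m$metabolites, m$reactions,
                        objective_id = m$objective_id)
  expect_equal(model_summary(m2)$genes, model_summary(toy$model)$genes)
})

test_that("generator sizes are reflected exactly in model_summary", {
  # per source: 3 reactions + 2 metabolites + 4 genes, plus the shared core
  spec <- toy_gem_spec(sources = list(
    s1 = list(n_carbons = 3, yield = 0.2),
    s2 = list(n_carbons = 5, yield = 0.4),
    s3 = list(n_carbons = 6, yield = 0.5)))
  s <- model_summary(make_toy_gem(spec)$model)
  expect_equal(s$reactions, 4 + 3 * 3)
  expect_equal(s$metabolites, 7 + 2 * 3)
  expect_equal(s$genes, 4 * 3)
})

test_that("the bundled 3-reaction JSON fixture loads as specified", {
  path <- system.file("extdata", "toy3.json", package = "gemkit")
  m <- read_model(path)
  expect_equal(model_summary(m),
               tibble::tibble(reactions = 3L, metabolites = 2L, genes = 1L))
  expect_equal(m$objective_id, "DM_a_c")
  expect_setequal(exchange_reactions(m), "EX_a_e")
})

test_that("JSON and SBML round-trips preserve every model field", {
  toy <- make_toy_gem(toy_gem_spec(defects = "futile_atp_loop"))
  model <- toy$model
  for (fmt in c("json", "sbml")) {
    path <- withr::local_tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(model, path, format = fmt)
    back <- read_model(path, format = fmt)
    expect_equal(model_summary(back), model_summary(model))
    expect_equal(back$objective_id, model$objective_id)
    expect_setequal(back$genes, model$genes)
    ord <- match(model$reactions$id, back$reactions$id)
    expect_false(anyNA(ord))
    expect_equal(back$reactions$lower_bound[ord], model$reactions$lower_bound)
    expect_equal(back$reactions$upper_bound[ord], model$reactions$upper_bound)
    for (i in seq_len(nrow(model$reactions))) {
      a <- model$reactions$stoichiometry[[i]]
      b <- back$reactions$stoichiometry[[ord[i]]]
      expect_equal(as.list(sort(b[order(names(b))])),
                   as.list(sort(a[order(names(a))])),
                   info = paste(fmt, model$reactions$id[i]))
      expect_identical(parse_gpr(back$reactions$gpr[ord[i]]),
                       parse_gpr(model$reactions$gpr[i]))
    }
    # second round trip is the identity on the serialised file level
    path2 <- withr::local_tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(back, path2, format = fmt)
    back2 <- read_model(path2, format = fmt)
    expect_equal(back2$reactions[order(back2$reactions$id), ],
                 back$reactions[order(back$reactions$id), ])
  }
})

test_that("read errors are informative", {
  expect_error(read_model("no_such_file.json"), class = "gemkit_io_error")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_model(bad), class = "gemkit_io_error")
  missing_field <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id": "x", "metabolites": []}', missing_field)
  expect_error(read_model(missing_field), "reactions",
               class = "gemkit_io_error")
  odd <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", odd)
  expect_error(read_model(odd), class = "gemkit_usage_error")

  not_sbml <- withr::local_tempfile(fileext = ".xml")
  writeLines("<foo/>", not_sbml)
  expect_error(read_model(not_sbml), "model", class = "gemkit_io_error")
})

test_that("medium TSV round-trips", {
  med <- medium(list(EX_glc_e = c(-10, 1000), EX_o2_e = c(-18, 1000)), "M9")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_medium(med, path)
  back <- read_medium(path, name = "M9")
  expect_equal(as.data.frame(back), as.data.frame(med))
})
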