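# Synthetic fixtures: toy genome-scale models with analytically known optima,
# strain cohorts with planted gene losses, and noisy flux measurements.
#
# A toy model has one linear catabolic pathway per carbon source:
#
#   EX_<s>_e:    <s>_e ->                       (exchange; uptake < 0)
#   TRANS_<s>:   <s>_e -> <s>_c                 (gene tr_<s>)
#   CATAB_<s>:   <s>_c + e adp + e pi ->        (gene rule
#                  a prec + (c-a) waste           (cat_<s>_1 and cat_<s>_2)
#                  + e atp + e h2o                 or iso_<s>)
#   BIOMASS:     prec + m atp + m h2o -> m adp + m pi
#   ATPM:        atp + h2o -> adp + pi
#
# with c the source's carbon count, a its biomass yield per unit uptake and
# e = m * a its ATP stoichiometry. Carbon is conserved exactly (prec and waste
# are CH2O units), all internal reactions are mass- and charge-balanced, and
# at optimum growth = yield * uptake, which is the generator's answer sheet.
# Defects (unbalanced reaction, futile ATP loop, orphan metabolites, missing
# pathway step) are planted on top and recorded in the answer sheet.

TOY_FORMULAS <- c(
  atp_c = "C10H16N5O13P3", adp_c = "C10H15N5O10P2", pi_c = "H3O4P",
  h2o_c = "H2O", prec_c = "CH2O", waste_c = "CH2O", waste_e = "CH2O"
)

#' Specification for a synthetic toy model
#'
#' @param sources named list of carbon sources: each entry a list with
#'   `n_carbons` (integer >= 1) and `yield` (biomass per unit uptake, h^-1;
#'   must not exceed `n_carbons`, the stoichiometric maximum).
#' @param defects character vector among `"unbalanced_reaction"`,
#'   `"futile_atp_loop"`, `"orphan_metabolite"`, `"missing_step"`.
#' @param n_orphans how many orphan metabolites to plant (with
#'   `"orphan_metabolite"`).
#' @param atp_per_biomass ATP cost of one unit of biomass.
#' @param seed seed recorded with the spec (construction is deterministic).
#' @return a `toy_gem_spec` list.
#' @export
toy_gem_spec <- function(sources = list(glc = list(n_carbons = 6, yield = 0.6),
                                        mal = list(n_carbons = 4, yield = 0.3)),
                         defects = character(0), n_orphans = 1,
                         atp_per_biomass = 2, seed = 1L) {
  bad <- setdiff(defects, c("unbalanced_reaction", "futile_atp_loop",
                            "orphan_metabolite", "missing_step"))
  if (length(bad)) {
    abort(paste0("unknown defects: ", paste(bad, collapse = ", ")),
          class = "gemkit_usage_error")
  }
  for (nm in names(sources)) {
    s <- sources[[nm]]
    if (s$yield > s$n_carbons) {
      abort(paste0("source ", nm, ": yield ", s$yield,
                   " exceeds the stoichiometric maximum ", s$n_carbons),
            class = "gemkit_usage_error")
    }
  }
  structure(list(sources = sources, defects = defects, n_orphans = n_orphans,
                 atp_per_biomass = atp_per_biomass, seed = seed),
            class = "toy_gem_spec")
}

#' Generate a toy metabolic model with a known answer sheet
#'
#' @param spec a [toy_gem_spec()].
#' @return list of class `toy_gem` with elements `model`
#'   (a [metabolic_model()]), `base_medium` (carbon-free), and `answer`, the
#'   construction-time answer sheet: per-source expected FBA optima and
#'   required genes, expected dead ends, expected unbalanced reactions, the
#'   planted futile reaction and removed pathway step (if any).
#' @export
make_toy_gem <- function(spec = toy_gem_spec()) {
  stopifnot(inherits(spec, "toy_gem_spec"))
  m <- spec$atp_per_biomass

  mets <- tibble(id = names(TOY_FORMULAS),
                 name = names(TOY_FORMULAS),
                 formula = unname(TOY_FORMULAS),
                 charge = 0L,
                 compartment = ifelse(grepl("_e$", names(TOY_FORMULAS)), "e", "c"))
  rxn <- function(id, st, lb = 0, ub = DEFAULT_BIG, gpr = "") {
    tibble(id = id, name = id, stoichiometry = list(st),
           lower_bound = lb, upper_bound = ub, gpr = gpr)
  }
  rxns <- list(
    rxn("BIOMASS", c(prec_c = -1, atp_c = -m, h2o_c = -m,
                     adp_c = m, pi_c = m)),
    rxn("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1)),
    rxn("WASTEt", c(waste_c = -1, waste_e = 1)),
    rxn("EX_waste_e", c(waste_e = -1), lb = -DEFAULT_BIG)
  )

  src_rows <- list()
  for (nm in names(spec$sources)) {
    s <- spec$sources[[nm]]
    cs <- s$n_carbons
    a <- s$yield
    e <- m * a
    met_e <- paste0(nm, "_e")
    met_c <- paste0(nm, "_c")
    formula <- paste0("C", cs, "H", 2 * cs, "O", cs)
    mets <- bind_rows(mets,
      tibble(id = c(met_e, met_c), name = c(met_e, met_c),
             formula = formula, charge = 0L, compartment = c("e", "c")))
    catab <- c(-1, -e, -e, a, e, e)
    names(catab) <- c(met_c, "adp_c", "pi_c", "prec_c", "atp_c", "h2o_c")
    if (cs - a > 1e-12) catab <- c(catab, waste_c = cs - a)
    genes <- list(transporter = paste0("tr_", nm),
                  complex = paste0("cat_", nm, "_", 1:2),
                  isozyme = paste0("iso_", nm))
    rxns <- c(rxns, list(
      rxn(paste0("EX_", nm, "_e"), stats::setNames(-1, met_e),
          lb = -DEFAULT_BIG),
      rxn(paste0("TRANS_", nm), stats::setNames(c(-1, 1), c(met_e, met_c)),
          gpr = genes$transporter),
      rxn(paste0("CATAB_", nm), catab,
          gpr = paste0("(", genes$complex[1], " and ", genes$complex[2],
                       ") or ", genes$isozyme))
    ))
    src_rows[[nm]] <- tibble(
      source = nm, exchange_id = paste0("EX_", nm, "_e"),
      n_carbons = cs, yield = a,
      expected_growth_uptake10 = a * 10,
      required_genes = list(genes))
  }
  answer <- list(sources = bind_rows(src_rows),
                 dead_ends = tibble(metabolite_id = character(0),
                                    type = character(0)),
                 unbalanced = tibble(reaction_id = character(0)),
                 futile_reaction = NA_character_,
                 removed_reaction_id = NA_character_,
                 removed_source = NA_character_,
                 egc_expected = FALSE)

  if ("unbalanced_reaction" %in% spec$defects) {
    # ATP hydrolysis written without its water: products minus reactants
    # leave {H: +2, O: +1}
    rxns <- c(rxns, list(rxn("UNBAL_PLANT",
                             c(atp_c = -1, adp_c = 1, pi_c = 1))))
    answer$unbalanced <- tibble(reaction_id = "UNBAL_PLANT")
  }
  if ("futile_atp_loop" %in% spec$defects) {
    # a second, reversible hydrolysis: run backwards it regenerates ATP for
    # free, closing a thermodynamically impossible cycle with ATPM
    rxns <- c(rxns, list(rxn("PPASE_REV",
                             c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
                             lb = -DEFAULT_BIG)))
    answer$futile_reaction <- "PPASE_REV"
    answer$egc_expected <- TRUE
  }
  if ("orphan_metabolite" %in% spec$defects) {
    for (i in seq_len(spec$n_orphans)) {
      oid <- paste0("orphan", i, "_c")
      mets <- bind_rows(mets, tibble(id = oid, name = oid, formula = "CH2O",
                                     charge = 0L, compartment = "c"))
      rxns <- c(rxns, list(rxn(paste0("ORPHANSRC", i),
                               stats::setNames(c(-1, 1), c("prec_c", oid)))))
    }
    answer$dead_ends <- tibble(
      metabolite_id = paste0("orphan", seq_len(spec$n_orphans), "_c"),
      type = "produced_only")
  }

  reactions <- bind_rows(rxns)
  if ("missing_step" %in% spec$defects) {
    gap_source <- names(spec$sources)[1]
    removed <- paste0("TRANS_", gap_source)
    reactions <- reactions[reactions$id != removed, ]
    answer$removed_reaction_id <- removed
    answer$removed_source <- gap_source
    # the stranded cytosolic species becomes consumed-only
    answer$dead_ends <- bind_rows(
      answer$dead_ends,
      tibble(metabolite_id = paste0(gap_source, "_c"), type = "consumed_only"))
  }

  model <- metabolic_model(
    id = paste0("toygem_seed", spec$seed),
    metabolites = mets, reactions = reactions,
    objective_id = "BIOMASS", atpm_id = "ATPM")

  structure(list(model = model,
                 base_medium = medium(list(), name = "toy-minimal"),
                 answer = answer, spec = spec),
            class = "toy_gem")
}

#' Specification for a synthetic strain cohort
#'
#' @param n_strains number of strains.
#' @param deletion_rate per-gene, per-strain probability of loss.
#' @param borderline_frac fraction of gene x strain cells whose percent
#'   identity is resampled inside `[35, 65]`, deliberately straddling the
#'   40/70 calling thresholds; 0 keeps every value well away from them.
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_strains = 20, deletion_rate = 0.05,
                        borderline_frac = 0, seed = 7L) {
  stopifnot(n_strains >= 1, deletion_rate >= 0, deletion_rate <= 1,
            borderline_frac >= 0, borderline_frac < 1)
  structure(list(n_strains = n_strains, deletion_rate = deletion_rate,
                 borderline_frac = borderline_frac, seed = seed),
            class = "cohort_spec")
}

#' Generate a strain cohort with planted gene losses
#'
#' Genes are deleted i.i.d. at `deletion_rate` per strain. Percent identity is
#' sampled from Uniform(85, 100) for retained genes and Uniform(0, 30) for
#' lost ones, with an optional borderline fraction resampled in Uniform(35,
#' 65). The truth phenotype (which strain grows on which source) is derived by
#' construction-time bookkeeping from the answer sheet's required-gene sets:
#' a source is usable iff its transporter gene is retained and its catabolic
#' rule (both complex subunits, or the isozyme) is satisfied.
#'
#' @param toy a `toy_gem` from [make_toy_gem()].
#' @param spec a [cohort_spec()].
#' @return list with `homology` (genes x strains pct matrix),
#'   `truth_presence` (logical matrix), `truth_phenotype` (strains x sources
#'   logical matrix) and `spec`.
#' @export
make_strain_cohort <- function(toy, spec = cohort_spec()) {
  stopifnot(inherits(toy, "toy_gem"), inherits(spec, "cohort_spec"))
  genes <- toy$model$genes
  strains <- sprintf("strain%02d", seq_len(spec$n_strains))
  withr::with_seed(spec$seed, {
    present <- matrix(stats::runif(length(genes) * spec$n_strains) >=
                        spec$deletion_rate,
                      nrow = length(genes),
                      dimnames = list(genes, strains))
    pct <- matrix(0, length(genes), spec$n_strains,
                  dimnames = list(genes, strains))
    pct[present] <- stats::runif(sum(present), 85, 100)
    pct[!present] <- stats::runif(sum(!present), 0, 30)
    if (spec$borderline_frac > 0) {
      n_cells <- length(pct)
      n_border <- round(spec$borderline_frac * n_cells)
      cells <- sample.int(n_cells, n_border)
      pct[cells] <- stats::runif(n_border, 35, 65)
    }
  })

  ans <- toy$answer$sources
  phenotype <- matrix(FALSE, spec$n_strains, nrow(ans),
                      dimnames = list(strains, ans$exchange_id))
  for (j in seq_len(nrow(ans))) {
    req <- ans$required_genes[[j]]
    for (i in seq_along(strains)) {
      have <- genes[present[, i]]
      usable <- (req$transporter %in% have) &&
        (all(req$complex %in% have) || req$isozyme %in% have)
      # a source whose pathway step was removed from the model never grows
      if (identical(toy$answer$removed_source, ans$source[j])) usable <- FALSE
      phenotype[i, j] <- usable
    }
  }

  list(homology = pct, truth_presence = present,
       truth_phenotype = phenotype, spec = spec)
}

#' Generate noisy flux measurements from true fluxes
#'
#' @param true_fluxes named numeric vector of true fluxes
#'   (mmol gDW^-1 h^-1).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param outlier_frac fraction of measurements replaced by 10x their
#'   magnitude.
#' @param seed RNG seed.
#' @return tibble with `reaction_id`, `flux`, `orientation` (all +1).
#' @export
make_flux_measurements <- function(true_fluxes, noise_sd = 0,
                                   outlier_frac = 0, seed = 1L) {
  stopifnot(noise_sd >= 0, outlier_frac >= 0, outlier_frac < 1)
  withr::with_seed(seed, {
    measured <- true_fluxes + stats::rnorm(length(true_fluxes), 0, noise_sd)
    n_out <- floor(outlier_frac * length(true_fluxes))
    if (n_out > 0) {
      idx <- sample(seq_along(measured), n_out)
      measured[idx] <- 10 * measured[idx]
    }
  })
  tibble(reaction_id = names(true_fluxes), flux = unname(measured),
         orientation = 1)
}
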