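# Model quality-control diagnostics: mass/charge balance of reactions,
# dead-end metabolites, and energy-generating cycles. These reproduce, as
# automated checks, the defect categories that drive manual curation of a
# genome-scale model; the package reports defects and never repairs them.

#' Audit mass and charge balance of internal reactions
#'
#' For each non-exchange, non-biomass reaction the signed elemental sums
#' `sum(coefficient * atom count)` and `sum(coefficient * charge)` are
#' computed; a balanced reaction has all-zero sums. Reactions touching any
#' metabolite with an unknown or unparseable formula are reported as
#' `unknown_formula` rather than given a fabricated verdict. The biomass
#' reaction is exempt (it is pseudo-stoichiometric by design), as are
#' exchanges (they create/destroy mass by construction).
#'
#' @param model a [metabolic_model()].
#' @return tibble with one row per audited reaction: `reaction_id`, `status`
#'   (`balanced`, `mass_unbalanced`, `charge_unbalanced`, `unknown_formula`),
#'   `element_imbalance` (list column of named vectors, products minus
#'   reactants) and `charge_imbalance`.
#' @export
check_mass_charge_balance <- function(model) {
  ex <- exchange_reactions(model)
  skip <- c(ex, model$objective_id)
  audit <- model$reactions[!model$reactions$id %in% skip, ]
  mets <- model$metabolites
  parsed <- lapply(mets$formula, parse_formula)
  names(parsed) <- mets$id
  charge <- stats::setNames(mets$charge, mets$id)

  rows <- lapply(seq_len(nrow(audit)), function(i) {
    st <- audit$stoichiometry[[i]]
    unknown <- any(vapply(names(st), function(m) is.null(parsed[[m]]),
                          logical(1))) ||
               any(is.na(charge[names(st)]))
    if (unknown) {
      return(tibble(reaction_id = audit$id[i], status = "unknown_formula",
                    element_imbalance = list(stats::setNames(numeric(0), character(0))),
                    charge_imbalance = NA_real_))
    }
    elems <- stats::setNames(numeric(0), character(0))
    for (m in names(st)) {
      elems <- add_elements(elems, parsed[[m]], st[[m]])
    }
    elems <- elems[abs(elems) > 1e-9]
    qimb <- sum(st * charge[names(st)])
    status <- if (length(elems)) {
      "mass_unbalanced"
    } else if (abs(qimb) > 1e-9) {
      "charge_unbalanced"
    } else {
      "balanced"
    }
    tibble(reaction_id = audit$id[i], status = status,
           element_imbalance = list(elems), charge_imbalance = qimb)
  })
  bind_rows(rows)
}

#' Find dead-end metabolites
#'
#' A metabolite is produced-only if no reaction can consume it under the
#' current bounds (and at least one can produce it), and consumed-only in the
#' mirror case. A reversible reaction counts as both producer and consumer of
#' every participant. Dead ends break the steady-state material balance and
#' force zero flux through their reactions.
#'
#' @param model a [metabolic_model()].
#' @return tibble with columns `metabolite_id` and `type`
#'   (`produced_only`, `consumed_only`, or `orphan` when no reaction touches
#'   the metabolite at all).
#' @export
find_dead_end_metabolites <- function(model) {
  can_produce <- stats::setNames(logical(nrow(model$metabolites)),
                                 model$metabolites$id)
  can_consume <- can_produce
  touched <- can_produce
  for (i in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[i]]
    fwd <- model$reactions$upper_bound[i] > 0
    rev <- model$reactions$lower_bound[i] < 0
    for (m in names(st)) {
      touched[m] <- TRUE
      coef <- st[[m]]
      produces <- (coef > 0 && fwd) || (coef < 0 && rev)
      consumes <- (coef < 0 && fwd) || (coef > 0 && rev)
      if (produces) can_produce[m] <- TRUE
      if (consumes) can_consume[m] <- TRUE
    }
  }
  out <- bind_rows(
    tibble(metabolite_id = names(which(touched & can_produce & !can_consume)),
           type = "produced_only"),
    tibble(metabolite_id = names(which(touched & !can_produce & can_consume)),
           type = "consumed_only"),
    tibble(metabolite_id = names(which(!touched)), type = "orphan")
  )
  arrange(out, .data$metabolite_id)
}

#' Check for energy-generating cycles
#'
#' With every exchange reaction clamped to zero, a thermodynamically sound
#' model cannot sustain ATP hydrolysis: maximizing flux through the ATP
#' maintenance reaction must give 0. A positive optimum certifies an
#' energy-generating cycle (e.g. a reversible reaction pair that regenerates
#' ATP for free), a classic curation defect.
#'
#' @param model a [metabolic_model()].
#' @param atpm_id ATP hydrolysis reaction to maximize; defaults to the
#'   model's `atpm_id`.
#' @return maximal ATP-hydrolysis flux with all exchanges closed
#'   (mmol gDW^-1 h^-1); 0 within tolerance means no cycle.
#' @export
check_energy_generating_cycle <- function(model, atpm_id = NULL) {
  atpm_id <- atpm_id %||% model$atpm_id
  if (is.null(atpm_id) || !atpm_id %in% model$reactions$id) {
    abort("no ATP maintenance reaction configured; pass atpm_id",
          class = "gemkit_config_error")
  }
  for (ex in exchange_reactions(model)) {
    model <- set_bounds(model, ex, lower = 0, upper = 0)
  }
  # the ATPM lower bound itself must not force flux during the audit
  model <- set_bounds(model, atpm_id, lower = 0)
  sol <- solve_fba(model, objective_id = atpm_id, sense = "max")
  if (sol$status != "optimal") return(0)
  max(sol$objective_value, 0)
}

#' Run the full QC battery on a model
#'
#' @param model a [metabolic_model()].
#' @param atpm_id optional ATP maintenance reaction id for the
#'   energy-cycle check (skipped when no ATPM reaction is known).
#' @return tibble with one row per finding: `check`, `id`, `status`, `detail`.
#' @export
validate_model_qc <- function(model, atpm_id = NULL) {
  bal <- check_mass_charge_balance(model)
  bal_bad <- filter(bal, .data$status != "balanced")
  dead <- find_dead_end_metabolites(model)
  findings <- bind_rows(
    tibble(check = "balance", id = bal_bad$reaction_id,
           status = bal_bad$status,
           detail = vapply(seq_len(nrow(bal_bad)), function(i) {
             el <- bal_bad$element_imbalance[[i]]
             if (length(el)) {
               paste(names(el), el, sep = ":", collapse = ",")
             } else if (!is.na(bal_bad$charge_imbalance[i])) {
               paste0("charge:", bal_bad$charge_imbalance[i])
             } else {
               ""
             }
           }, character(1))),
    tibble(check = "dead_end", id = dead$metabolite_id, status = dead$type,
           detail = "")
  )
  atpm <- atpm_id %||% model$atpm_id
  if (!is.null(atpm) && atpm %in% model$reactions$id) {
    egc <- check_energy_generating_cycle(model, atpm)
    if (egc > FLUX_TOL) {
      findings <- bind_rows(findings,
        tibble(check = "energy_cycle", id = atpm, status = "cycle_detected",
               detail = paste0("max_atp_flux:", signif(egc, 6))))
    }
  }
  findings
}
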