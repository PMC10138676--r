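# Flux balance analysis and the carbon-source growth screen.
#
# FBA solves max c'v subject to S v = 0 and lb <= v <= ub, with the biomass
# reaction as the canonical objective; the optimal biomass flux is the
# predicted growth rate in h^-1. Media are applied through exchange-reaction
# bounds: uptake is a negative lower bound, secretion a positive upper bound.

#' Define a growth medium
#'
#' @param bounds named list: exchange reaction id -> `c(lower, upper)` flux
#'   bounds (mmol gDW^-1 h^-1), or a data frame with columns `exchange_id`,
#'   `lower_bound`, `upper_bound`.
#' @param name medium name (e.g. `"M9-minimal-aerobic"`).
#' @return a tibble of class `gemkit_medium`.
#' @examples
#' medium(list(EX_glc_e = c(-10, 1000), EX_o2_e = c(-1000, 1000)), "M9-glc")
#' @export
medium <- function(bounds = list(), name = "medium") {
  if (is.data.frame(bounds)) {
    tab <- as_tibble(bounds)
  } else {
    tab <- tibble(
      exchange_id = names(bounds) %||% character(0),
      lower_bound = vapply(bounds, `[`, numeric(1), 1),
      upper_bound = vapply(bounds, `[`, numeric(1), 2)
    )
  }
  if (any(tab$lower_bound > tab$upper_bound)) {
    abort("medium has lower_bound > upper_bound", class = "gemkit_config_error")
  }
  structure(tab, name = name, class = c("gemkit_medium", class(tab)))
}

#' Apply a medium to a model
#'
#' Exchange reactions named in the medium receive its bounds; every other
#' exchange reaction is closed for uptake (lower bound 0) and left open for
#' secretion (upper bound `r DEFAULT_BIG`).
#'
#' @param model a [metabolic_model()].
#' @param med a [medium()].
#' @return the model with exchange bounds set.
#' @export
apply_medium <- function(model, med) {
  ex <- exchange_reactions(model)
  unknown <- setdiff(med$exchange_id, model$reactions$id)
  if (length(unknown)) {
    abort(paste0("medium names exchange reactions absent from the model: ",
                 paste(unknown, collapse = ", ")),
          class = "gemkit_config_error")
  }
  idx <- model$reactions$id %in% ex
  model$reactions$lower_bound[idx] <- 0
  model$reactions$upper_bound[idx] <- DEFAULT_BIG
  for (i in seq_len(nrow(med))) {
    model <- set_bounds(model, med$exchange_id[i],
                        lower = med$lower_bound[i],
                        upper = med$upper_bound[i])
  }
  model
}

#' Solve flux balance analysis
#'
#' @param model a [metabolic_model()].
#' @param objective_id reaction whose flux is optimised; defaults to the
#'   model's objective (biomass) reaction.
#' @param sense `"max"` (default) or `"min"`.
#' @return a `flux_solution`: list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective_value`, `fluxes` (named vector), and the
#'   steady-state residual `max_residual`.
#' @export
solve_fba <- function(model, objective_id = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective_id <- objective_id %||% model$objective_id
  if (is.null(objective_id) || !objective_id %in% model$reactions$id) {
    abort("no objective reaction available", class = "gemkit_config_error")
  }
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  cc <- as.numeric(colnames(S) == objective_id)
  lb <- pmax(model$reactions$lower_bound, -DEFAULT_BIG)
  ub <- pmin(model$reactions$upper_bound, DEFAULT_BIG)
  if (any(lb > ub)) {
    return(new_flux_solution("infeasible", NA_real_, NULL, model))
  }
  res <- lp_solve(cc, S, rep(0, nrow(S)), lb, ub, sense = sense)
  if (res$status != "optimal") {
    return(new_flux_solution(res$status, NA_real_, NULL, model))
  }
  fluxes <- stats::setNames(res$x, colnames(S))
  sol <- new_flux_solution("optimal", res$obj, fluxes, model)
  sol$max_residual <- max(abs(S %*% res$x))
  sol
}

new_flux_solution <- function(status, objective_value, fluxes, model) {
  structure(list(status = status,
                 objective_value = objective_value,
                 fluxes = fluxes,
                 exchange_ids = exchange_reactions(model),
                 model_id = model$id),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective: ", signif(x$objective_value, 6), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Growth rate of a model on a medium
#'
#' Convenience wrapper: apply the medium, solve FBA for biomass. Infeasible
#' problems count as zero growth.
#'
#' @inheritParams apply_medium
#' @return growth rate in h^-1.
#' @export
growth_rate <- function(model, med) {
  sol <- solve_fba(apply_medium(model, med))
  if (sol$status != "optimal") return(0)
  max(sol$objective_value, 0)
}

#' Secreted byproducts of an optimal flux solution
#'
#' @param solution an optimal `flux_solution`.
#' @param tol fluxes above this are reported (mmol gDW^-1 h^-1).
#' @return tibble with `exchange_id` and `flux`, sorted by decreasing flux.
#' @export
predict_secretion <- function(solution, tol = FLUX_TOL) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status != "optimal") {
    abort("secretion is only defined for optimal solutions",
          class = "gemkit_contract_error")
  }
  ex_flux <- solution$fluxes[solution$exchange_ids]
  ex_flux <- ex_flux[!is.na(ex_flux) & ex_flux > tol]
  tibble(exchange_id = names(ex_flux), flux = unname(ex_flux)) |>
    arrange(dplyr::desc(.data$flux))
}

# carbon count of the species behind an exchange reaction
exchange_n_carbons <- function(model, exchange_id) {
  i <- match(exchange_id, model$reactions$id)
  met <- names(model$reactions$stoichiometry[[i]])[1]
  formula_carbons(model$metabolites$formula[match(met, model$metabolites$id)])
}

#' Normalize a growth rate by carbon content
#'
#' Two normalizations are offered. `per_carbon` divides the growth rate by
#' the number of carbon atoms of the source. `carbon_equivalent_uptake`
#' re-solves FBA with the uptake bound set to `60 / n_carbons`
#' (the glucose-equivalent carbon supply: glucose has 6 carbons at uptake 10),
#' so every source feeds the same number of carbon atoms per unit time.
#'
#' @param growth_rate growth rate in h^-1 (`per_carbon` mode).
#' @param n_carbons carbon atoms of the source molecule (>= 1).
#' @param mode `"per_carbon"` or `"carbon_equivalent_uptake"`.
#' @param model,base_medium,exchange_id required for
#'   `carbon_equivalent_uptake`, which re-solves the model.
#' @return normalized growth value.
#' @export
normalize_growth <- function(growth_rate, n_carbons,
                             mode = c("per_carbon", "carbon_equivalent_uptake"),
                             model = NULL, base_medium = NULL,
                             exchange_id = NULL) {
  mode <- match.arg(mode)
  if (is.na(n_carbons) || n_carbons < 1) {
    abort("n_carbons must be >= 1 for carbon-source normalization",
          class = "gemkit_usage_error")
  }
  if (mode == "per_carbon") {
    return(growth_rate / n_carbons)
  }
  if (is.null(model) || is.null(base_medium) || is.null(exchange_id)) {
    abort("carbon_equivalent_uptake needs model, base_medium and exchange_id",
          class = "gemkit_usage_error")
  }
  m <- apply_medium(model, base_medium)
  m <- set_bounds(m, exchange_id, lower = -60 / n_carbons)
  sol <- solve_fba(m)
  if (sol$status != "optimal") return(0)
  max(sol$objective_value, 0)
}

#' Screen candidate carbon sources for growth
#'
#' One FBA solve per candidate exchange reaction, with that exchange's uptake
#' opened to `-uptake` on top of a carbon-free base medium. Candidates whose
#' extracellular species has no parseable formula are dropped with a warning
#' (their carbon count, hence normalization, would be a guess).
#'
#' @param model a [metabolic_model()].
#' @param base_medium a carbon-free [medium()] (salts, O2, ...).
#' @param candidate_exchanges exchange reaction ids to test.
#' @param uptake uptake rate magnitude (default 10 mmol gDW^-1 h^-1).
#' @param normalize_mode `"per_carbon"` (default) or
#'   `"carbon_equivalent_uptake"`.
#' @param anaerobic close oxygen uptake? (default `FALSE`: O2 uptake is left
#'   unconstrained unless the base medium fixes it).
#' @param o2_exchange_id id of the oxygen exchange reaction, if any.
#' @param growth_threshold growth rates above this count as growth.
#' @return tibble, one row per screened source: `carbon_source`, `n_carbons`,
#'   `growth_rate`, `normalized_growth`, `grows`, `secreted` (list column of
#'   named flux vectors).
#' @export
screen_carbon_sources <- function(model, base_medium, candidate_exchanges,
                                  uptake = 10,
                                  normalize_mode = c("per_carbon",
                                                     "carbon_equivalent_uptake"),
                                  anaerobic = FALSE,
                                  o2_exchange_id = "EX_o2_e",
                                  growth_threshold = GROWTH_THRESHOLD) {
  normalize_mode <- match.arg(normalize_mode)
  unknown <- setdiff(candidate_exchanges, model$reactions$id)
  if (length(unknown)) {
    abort(paste0("candidate exchanges absent from the model: ",
                 paste(unknown, collapse = ", ")),
          class = "gemkit_config_error")
  }
  base <- apply_medium(model, base_medium)
  if (o2_exchange_id %in% base$reactions$id &&
      !o2_exchange_id %in% base_medium$exchange_id) {
    base <- set_bounds(base, o2_exchange_id,
                       lower = if (anaerobic) 0 else -DEFAULT_BIG)
  }

  nc <- unname(vapply(candidate_exchanges, exchange_n_carbons, numeric(1),
                      model = model))
  if (any(is.na(nc))) {
    warn(paste0("skipping sources with unknown formula: ",
                paste(candidate_exchanges[is.na(nc)], collapse = ", ")))
    candidate_exchanges <- candidate_exchanges[!is.na(nc)]
    nc <- nc[!is.na(nc)]
  }

  rows <- lapply(seq_along(candidate_exchanges), function(k) {
    ex <- candidate_exchanges[k]
    up <- if (normalize_mode == "carbon_equivalent_uptake" && nc[k] >= 1) {
      60 / nc[k]
    } else {
      uptake
    }
    m <- set_bounds(base, ex, lower = -up)
    sol <- solve_fba(m)
    g <- if (sol$status == "optimal") max(sol$objective_value, 0) else 0
    norm <- if (nc[k] >= 1) {
      if (normalize_mode == "per_carbon") g / nc[k] else g
    } else {
      NA_real_
    }
    secreted <- if (sol$status == "optimal") {
      sec <- predict_secretion(sol)
      stats::setNames(sec$flux, sec$exchange_id)
    } else {
      stats::setNames(numeric(0), character(0))
    }
    tibble(carbon_source = ex, n_carbons = nc[k], growth_rate = g,
           normalized_growth = norm, grows = g > growth_threshold,
           secreted = list(secreted))
  })
  out <- bind_rows(rows)
  attr(out, "normalize_mode") <- normalize_mode
  attr(out, "uptake") <- uptake
  class(out) <- c("carbon_screen", class(out))
  out
}
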