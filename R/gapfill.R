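# Gap filling: add a minimum-cardinality set of donor reactions so that a
# non-growing model reaches the growth threshold on a given medium.
#
# The search is exact: donor reactions that can never carry flux in the
# model+donor union are first discarded (a sound reduction — a reaction
# blocked in the union is blocked in every subset), then subsets are tried in
# order of increasing size, lexicographically by reaction id, and the first
# feasible subset is returned. This finds the same optimum a mixed-integer
# formulation with binary inclusion indicators would, and ties are broken
# deterministically.

#' Gap-fill a model from a donor reaction bag
#'
#' @param model a [metabolic_model()] that fails to grow on `med`.
#' @param donor a [metabolic_model()] serving as reaction donor (typically the
#'   template); only reactions absent from `model` form the bag. Metabolites
#'   the donor reactions need are carried over.
#' @param med a [medium()].
#' @param objective_id objective (biomass) reaction; defaults to the model's.
#' @param growth_threshold growth rate to reach (h^-1).
#' @param max_additions largest subset size searched before giving up.
#' @return a one-row tibble: `model_id`, `status` (`already_growing`,
#'   `filled`, `unfillable`), `growth_before`, `growth_after`, `n_added`,
#'   `added` (list column of reaction ids), `medium`, and `model` (list column
#'   holding the repaired model).
#' @export
gap_fill <- function(model, donor, med, objective_id = NULL,
                     growth_threshold = GROWTH_THRESHOLD,
                     max_additions = 5) {
  objective_id <- objective_id %||% model$objective_id
  g0 <- growth_rate_obj(model, med, objective_id)
  if (g0 > growth_threshold) {
    return(gap_fill_row(model, "already_growing", g0, g0, character(0), med))
  }

  bag <- donor$reactions[!donor$reactions$id %in% model$reactions$id, ]
  bag <- bag[order(bag$id), ]
  union_model <- merge_reactions(model, donor, bag$id)

  g_union <- growth_rate_obj(union_model, med, objective_id)
  if (g_union <= growth_threshold) {
    return(gap_fill_row(model, "unfillable", g0, g_union, character(0), med))
  }

  # precompute the union LP once; candidate subsets only toggle donor bounds
  ctx <- gap_fill_context(union_model, med, objective_id, bag$id)

  # sound reduction: drop donor reactions blocked in the full union
  usable <- bag$id[vapply(bag$id, function(rid) {
    ctx_flux_range(ctx, rid) > FLUX_TOL
  }, logical(1))]

  for (k in seq_len(min(max_additions, length(usable)))) {
    subsets <- utils::combn(usable, k, simplify = FALSE)
    for (subset in subsets) {
      g <- ctx_growth(ctx, subset)
      if (g > growth_threshold) {
        filled <- merge_reactions(model, donor, subset)
        return(gap_fill_row(filled, "filled", g0, g, subset, med))
      }
    }
  }
  gap_fill_row(model, "unfillable", g0, g0, character(0), med)
}

#' Gap-fill a cohort of strain models
#'
#' Only strains failing the growth threshold on *every* medium in
#' `media_list` are gap-filled (against each medium in order, stopping at the
#' first success); growing strains pass through untouched. Per-strain
#' failures are reported, never propagated as errors.
#'
#' @param strain_models named list of [metabolic_model()]s.
#' @param donor donor model (usually the template).
#' @param media_list list of [medium()] objects.
#' @param ... passed to [gap_fill()].
#' @return tibble with one row per strain (columns as in [gap_fill()], plus
#'   `strain`); attribute `summary` counts functional/repaired/non-functional
#'   strains.
#' @export
multi_gap_fill <- function(strain_models, donor, media_list, ...) {
  if (inherits(media_list, "gemkit_medium")) media_list <- list(media_list)
  rows <- imap(strain_models, function(model, strain) {
    res <- tryCatch({
      grows <- any(vapply(media_list, function(med) {
        growth_rate_obj(model, med, model$objective_id) > GROWTH_THRESHOLD
      }, logical(1)))
      if (grows) {
        g <- max(vapply(media_list, function(med) {
          growth_rate_obj(model, med, model$objective_id)
        }, numeric(1)))
        gap_fill_row(model, "growing", g, g, character(0), media_list[[1]])
      } else {
        out <- NULL
        for (med in media_list) {
          out <- gap_fill(model, donor, med, ...)
          if (out$status == "filled") break
        }
        out
      }
    }, error = function(e) {
      gap_fill_row(model, paste0("error: ", conditionMessage(e)),
                   NA_real_, NA_real_, character(0), media_list[[1]])
    })
    res$strain <- strain
    res
  })
  out <- bind_rows(rows)
  out <- select(out, "strain", dplyr::everything())
  attr(out, "summary") <- c(
    functional = sum(out$status %in% c("growing", "already_growing", "filled")),
    repaired = sum(out$status == "filled"),
    non_functional = sum(!out$status %in% c("growing", "already_growing", "filled"))
  )
  out
}

# ---- internals --------------------------------------------------------------

growth_rate_obj <- function(model, med, objective_id) {
  sol <- solve_fba(apply_medium(model, med), objective_id = objective_id)
  if (sol$status != "optimal") return(0)
  max(sol$objective_value, 0)
}

# add the named donor reactions (and any metabolites they need) to a model
merge_reactions <- function(model, donor, reaction_ids) {
  add <- donor$reactions[donor$reactions$id %in% reaction_ids, ]
  needed_mets <- setdiff(unique(unlist(lapply(add$stoichiometry, names))),
                         model$metabolites$id)
  model$metabolites <- bind_rows(
    model$metabolites,
    donor$metabolites[donor$metabolites$id %in% needed_mets, ])
  model$reactions <- bind_rows(model$reactions, add)
  model$genes <- sort(union(model$genes,
                            unlist(lapply(add$gpr, gpr_genes))))
  model
}

gap_fill_row <- function(model, status, g_before, g_after, added, med) {
  tibble(model_id = model$id, status = status,
         growth_before = g_before, growth_after = g_after,
         n_added = length(added), added = list(added),
         medium = attr(med, "name") %||% "medium",
         model = list(model))
}

gap_fill_context <- function(union_model, med, objective_id, donor_ids) {
  m <- apply_medium(union_model, med)
  S <- stoichiometric_matrix(m)
  lb <- pmax(m$reactions$lower_bound, -DEFAULT_BIG)
  ub <- pmin(m$reactions$upper_bound, DEFAULT_BIG)
  donor_idx <- match(donor_ids, m$reactions$id)
  list(S = S, lb = lb, ub = ub,
       donor_idx = stats::setNames(donor_idx, donor_ids),
       obj = as.numeric(m$reactions$id == objective_id))
}

# max biomass with only the given donor subset enabled
ctx_growth <- function(ctx, subset) {
  lb <- ctx$lb
  ub <- ctx$ub
  off <- ctx$donor_idx[setdiff(names(ctx$donor_idx), subset)]
  lb[off] <- 0
  ub[off] <- 0
  res <- lp_solve(ctx$obj, ctx$S, rep(0, nrow(ctx$S)), lb, ub, "max")
  if (res$status != "optimal") return(0)
  max(res$obj, 0)
}

# largest attainable |flux| through one reaction in the full union network
ctx_flux_range <- function(ctx, rid) {
  cc <- numeric(ncol(ctx$S))
  cc[ctx$donor_idx[[rid]]] <- 1
  hi <- lp_solve(cc, ctx$S, rep(0, nrow(ctx$S)), ctx$lb, ctx$ub, "max")
  lo <- lp_solve(cc, ctx$S, rep(0, nrow(ctx$S)), ctx$lb, ctx$ub, "min")
  max(abs(c(if (hi$status == "optimal") hi$obj else 0,
            if (lo$status == "optimal") lo$obj else 0)))
}
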