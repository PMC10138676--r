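# The metabolic model container.
#
# A `metabolic_model` is a light S3 object holding the three tables a
# constraint-based model needs:
#   * metabolites: id, name, formula, charge, compartment
#   * reactions:   id, name, stoichiometry (named numeric list-column, signed
#                  coefficients: negative = consumed), lower_bound,
#                  upper_bound (mmol gDW^-1 h^-1), gpr (rule string)
#   * genes:       character vector
# plus the id of the biomass objective reaction and (optionally) of the
# non-growth ATP maintenance reaction. Ids carry the usual compartment
# suffixes (_c cytosol, _e extracellular); exchange reactions are the
# single-metabolite boundary reactions over extracellular species, with
# negative flux meaning uptake.

#' Construct a metabolic model
#'
#' @param id model identifier.
#' @param metabolites data frame with columns `id`, `name`, `formula`,
#'   `charge`, `compartment` (missing optional columns are filled with `NA`).
#' @param reactions data frame with columns `id`, `name`, `stoichiometry`
#'   (a list column of named numeric vectors, metabolite id -> signed
#'   coefficient), `lower_bound`, `upper_bound`, `gpr`.
#' @param genes character vector of gene ids; defaults to the union of genes
#'   appearing in GPR rules.
#' @param objective_id id of the biomass (objective) reaction.
#' @param atpm_id optional id of the ATP maintenance reaction.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, genes = NULL,
                            objective_id = NULL, atpm_id = NULL) {
  metabolites <- as_tibble(metabolites)
  for (col in c("name", "formula")) {
    if (!col %in% names(metabolites)) metabolites[[col]] <- NA_character_
  }
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  if (!"compartment" %in% names(metabolites)) {
    metabolites$compartment <- ifelse(grepl("_e$", metabolites$id), "e", "c")
  }
  reactions <- as_tibble(reactions)
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""

  gpr_gene_union <- unique(unlist(lapply(reactions$gpr, function(g) {
    tryCatch(gpr_genes(g), error = function(e) character(0))
  })))
  genes <- sort(unique(c(genes %||% character(0), gpr_gene_union)))

  model <- structure(
    list(id = id,
         metabolites = metabolites[, c("id", "name", "formula", "charge",
                                       "compartment")],
         reactions = reactions[, c("id", "name", "stoichiometry",
                                   "lower_bound", "upper_bound", "gpr")],
         genes = genes,
         objective_id = objective_id,
         atpm_id = atpm_id),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate the internal consistency of a model
#'
#' Checks id uniqueness, stoichiometry references, bound ordering, nonzero
#' coefficients, compartment-suffix consistency and the existence of the
#' objective reaction. Unknown compartment codes are flagged with a warning
#' but accepted.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly, or an error describing the first violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    abort("duplicate metabolite ids", class = "gemkit_model_error")
  }
  if (anyDuplicated(rxns$id)) {
    abort("duplicate reaction ids", class = "gemkit_model_error")
  }
  bad_bounds <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad_bounds)) {
    abort(paste0("lower_bound > upper_bound for: ",
                 paste(bad_bounds, collapse = ", ")),
          class = "gemkit_model_error")
  }
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    if (length(st) == 0) {
      abort(paste0("reaction ", rxns$id[i], " has empty stoichiometry"),
            class = "gemkit_model_error")
    }
    if (any(st == 0)) {
      abort(paste0("reaction ", rxns$id[i], " has zero coefficients"),
            class = "gemkit_model_error")
    }
    missing <- setdiff(names(st), mets$id)
    if (length(missing)) {
      abort(paste0("reaction ", rxns$id[i], " references unknown metabolites: ",
                   paste(missing, collapse = ", ")),
            class = "gemkit_model_error")
    }
  }
  suffix <- sub("^.*_([a-z])$", "\\1", mets$id)
  has_suffix <- grepl("_[a-z]$", mets$id)
  mismatch <- has_suffix & suffix != mets$compartment
  if (any(mismatch)) {
    abort(paste0("metabolite id suffix disagrees with compartment: ",
                 paste(mets$id[mismatch], collapse = ", ")),
          class = "gemkit_model_error")
  }
  odd <- setdiff(unique(mets$compartment), c("c", "e"))
  if (length(odd)) {
    warn(paste0("non-standard compartment code(s): ",
                paste(odd, collapse = ", ")))
  }
  if (!is.null(model$objective_id) && !model$objective_id %in% rxns$id) {
    abort(paste0("objective reaction not in model: ", model$objective_id),
          class = "gemkit_model_error")
  }
  gpr_gene_union <- unique(unlist(lapply(rxns$gpr, gpr_genes)))
  orphan_genes <- setdiff(gpr_gene_union, model$genes)
  if (length(orphan_genes)) {
    abort(paste0("GPR genes missing from gene list: ",
                 paste(orphan_genes, collapse = ", ")),
          class = "gemkit_model_error")
  }
  invisible(model)
}

#' Count the unique reactions, metabolites and genes of a model
#'
#' @param model a `metabolic_model`.
#' @return a one-row tibble with columns `reactions`, `metabolites`, `genes`.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  tibble(
    reactions = length(unique(model$reactions$id)),
    metabolites = length(unique(model$metabolites$id)),
    genes = length(unique(model$genes))
  )
}

#' Identify exchange reactions
#'
#' An exchange reaction is a boundary pseudo-reaction over exactly one
#' extracellular metabolite; by convention negative flux is uptake.
#'
#' @param model a `metabolic_model`.
#' @return character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  extracellular <- model$metabolites$id[model$metabolites$compartment == "e"]
  is_ex <- vapply(model$reactions$stoichiometry, function(st) {
    length(st) == 1 && names(st) %in% extracellular
  }, logical(1))
  model$reactions$id[is_ex]
}

# stoichiometric matrix (metabolites x reactions), dense
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Set flux bounds on one reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to modify.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) {
    abort(paste0("unknown reaction: ", reaction_id),
          class = "gemkit_config_error")
  }
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i]) {
    abort(paste0("lower_bound > upper_bound for ", reaction_id),
          class = "gemkit_model_error")
  }
  model
}

# keep only the given reactions (plus metabolites/genes cleanup is the
# caller's concern; genes are re-derived in derive_strain_model)
subset_reactions <- function(model, keep_ids) {
  model$reactions <- model$reactions[model$reactions$id %in% keep_ids, ]
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  s <- model_summary(x)
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  reactions:   ", s$reactions, "\n", sep = "")
  cat("  metabolites: ", s$metabolites, "\n", sep = "")
  cat("  genes:       ", s$genes, "\n", sep = "")
  cat("  objective:   ", x$objective_id %||% "<none>", "\n", sep = "")
  if (!is.null(x$atpm_id)) cat("  atpm:        ", x$atpm_id, "\n", sep = "")
  invisible(x)
}
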