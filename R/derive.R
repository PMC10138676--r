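# Template-based derivation of strain-specific models.
#
# Following the standard multistrain protocol, every reaction of the curated
# template whose GPR evaluates to FALSE under a strain's present-gene set is
# removed; reactions without a GPR (transporters, spontaneous reactions),
# exchanges and the biomass reaction are always retained, because their
# absence of gene evidence is not evidence of absence.

#' Derive a strain-specific model from a template
#'
#' @param template a [metabolic_model()] (the curated reference).
#' @param present_genes either a character vector of genes present in the
#'   strain, or a logical vector named by gene (one column of a
#'   `presence_matrix`).
#' @param strain_id id for the derived model.
#' @return a [metabolic_model()] whose reactions are a subset of the
#'   template's.
#' @export
derive_strain_model <- function(template, present_genes,
                                strain_id = paste0(template$id, "_strain")) {
  if (is.logical(present_genes)) {
    if (is.null(names(present_genes))) {
      abort("logical present_genes must be named by gene",
            class = "gemkit_usage_error")
    }
    present_genes <- names(present_genes)[present_genes]
  }
  keep <- vapply(template$reactions$gpr, function(rule) {
    evaluate_gpr(rule, present_genes)
  }, logical(1))
  # exchanges and biomass always retained (they carry no gene evidence)
  keep[template$reactions$id %in% exchange_reactions(template)] <- TRUE
  keep[template$reactions$id %in% template$objective_id] <- TRUE

  model <- template
  model$id <- strain_id
  model$reactions <- template$reactions[keep, ]
  # prune GPRs down to the present genes (dead OR branches disappear), so the
  # strain model's gene list and rules stay mutually consistent
  model$reactions$gpr <- vapply(model$reactions$gpr, function(rule) {
    pruned <- prune_gpr(parse_gpr(rule), present_genes)
    if (is.logical(pruned)) "" else deparse_gpr(pruned)
  }, character(1), USE.NAMES = FALSE)
  model$genes <- sort(intersect(template$genes, present_genes))
  if (!is.null(model$atpm_id) && !model$atpm_id %in% model$reactions$id) {
    model$atpm_id <- NULL
  }
  model
}

# simplify a GPR AST against a present-gene set: absent leaves become FALSE,
# AND/OR nodes collapse accordingly. Returns an AST, or TRUE/FALSE when the
# rule reduces to a constant.
prune_gpr <- function(ast, present_genes) {
  if (is.null(ast)) return(TRUE)
  if (ast$op == "gene") {
    return(if (ast$id %in% present_genes) ast else FALSE)
  }
  kids <- lapply(ast$args, prune_gpr, present_genes = present_genes)
  if (ast$op == "and") {
    if (any(vapply(kids, isFALSE, logical(1)))) return(FALSE)
    kids <- kids[!vapply(kids, isTRUE, logical(1))]
    if (length(kids) == 0) return(TRUE)
  } else {
    if (any(vapply(kids, isTRUE, logical(1)))) return(TRUE)
    kids <- kids[!vapply(kids, isFALSE, logical(1))]
    if (length(kids) == 0) return(FALSE)
  }
  if (length(kids) == 1) kids[[1]] else list(op = ast$op, args = kids)
}

#' Derive a cohort of strain models from a presence matrix
#'
#' @param template a [metabolic_model()].
#' @param presence a `presence_matrix` from [call_orthologs()] (or any logical
#'   genes x strains matrix).
#' @return named list of strain models, one per column of `presence`.
#' @export
derive_strain_cohort <- function(template, presence) {
  strains <- colnames(presence)
  if (is.null(strains) || length(strains) == 0) {
    abort("presence matrix has no strains", class = "gemkit_usage_error")
  }
  stats::setNames(lapply(strains, function(s) {
    derive_strain_model(template, presence[, s], strain_id = s)
  }), strains)
}
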