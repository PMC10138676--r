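# Model input/output: COBRA-style JSON (schema v1) and SBML Level 3 Version 1
# with the FBC v2 extension. Both writers aim at round-trip fidelity: gene,
# metabolite and reaction sets, numeric bounds (full precision), GPR structure
# and the active objective survive read -> write -> read unchanged.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from file
#'
#' @param path path to the model file.
#' @param format `"json"` (COBRA JSON schema v1), `"sbml"` (Level 3 + FBC v2)
#'   or `"auto"` to infer from the file extension.
#' @param atpm_id optional id of the ATP maintenance reaction; when `NULL`, a
#'   reaction literally named `ATPM` is picked up if present.
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       atpm_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("model file not found: ", path), class = "gemkit_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      json = "json",
      xml = "sbml",
      sbml = "sbml",
      abort(paste0("cannot infer model format from extension '.", ext,
                   "'; pass format explicitly"), class = "gemkit_usage_error")
    )
  }
  model <- switch(format,
    json = read_model_json(path),
    sbml = read_model_sbml(path)
  )
  if (!is.null(atpm_id)) {
    if (!atpm_id %in% model$reactions$id) {
      abort(paste0("ATPM reaction not in model: ", atpm_id),
            class = "gemkit_config_error")
    }
    model$atpm_id <- atpm_id
  } else if (is.null(model$atpm_id) && "ATPM" %in% model$reactions$id) {
    model$atpm_id <- "ATPM"
  }
  model
}

#' Write a metabolic model to file
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @param format `"json"`, `"sbml"` or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", xml = "sbml", sbml = "sbml",
      abort(paste0("cannot infer model format from extension '.", ext, "'"),
            class = "gemkit_usage_error"))
  }
  switch(format,
    json = write_model_json(model, path),
    sbml = write_model_sbml(model, path)
  )
  invisible(path)
}

# ---- COBRA JSON ------------------------------------------------------------

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("malformed JSON model '", path, "': ", conditionMessage(e)),
            class = "gemkit_io_error")
    })
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) {
      abort(paste0("malformed JSON model: missing element '", field, "'"),
            class = "gemkit_io_error")
    }
  }
  mets <- tibble(
    id = map_chr(doc$metabolites, "id"),
    name = map_chr(doc$metabolites, ~ .x$name %||% NA_character_),
    formula = map_chr(doc$metabolites, ~ .x$formula %||% NA_character_),
    charge = map_dbl(doc$metabolites, ~ as.numeric(.x$charge %||% NA)),
    compartment = map_chr(doc$metabolites, ~ .x$compartment %||%
                            sub("^.*_", "", .x$id))
  )
  rxns <- tibble(
    id = map_chr(doc$reactions, "id"),
    name = map_chr(doc$reactions, ~ .x$name %||% NA_character_),
    stoichiometry = map(doc$reactions, function(r) {
      st <- unlist(r$metabolites)
      if (is.null(st)) {
        abort(paste0("malformed JSON model: reaction '", r$id,
                     "' has no metabolites"), class = "gemkit_io_error")
      }
      st
    }),
    lower_bound = map_dbl(doc$reactions, ~ as.numeric(.x$lower_bound %||% -DEFAULT_BIG)),
    upper_bound = map_dbl(doc$reactions, ~ as.numeric(.x$upper_bound %||% DEFAULT_BIG)),
    gpr = map_chr(doc$reactions, ~ .x$gene_reaction_rule %||% "")
  )
  obj_coef <- map_dbl(doc$reactions, ~ as.numeric(.x$objective_coefficient %||% 0))
  objective_id <- if (any(obj_coef != 0)) rxns$id[which(obj_coef != 0)[1]] else NULL
  genes <- map_chr(doc$genes %||% list(), "id")
  metabolic_model(doc$id %||% tools::file_path_sans_ext(basename(path)),
                  mets, rxns, genes = genes, objective_id = objective_id)
}

write_model_json <- function(model, path) {
  mets <- purrr::pmap(model$metabolites, function(id, name, formula, charge,
                                                  compartment) {
    out <- list(id = id, name = name, compartment = compartment)
    if (!is.na(formula)) out$formula <- formula
    if (!is.na(charge)) out$charge <- charge
    out
  })
  rxns <- purrr::pmap(model$reactions, function(id, name, stoichiometry,
                                                lower_bound, upper_bound, gpr) {
    list(id = id, name = name, metabolites = as.list(stoichiometry),
         lower_bound = lower_bound, upper_bound = upper_bound,
         gene_reaction_rule = gpr,
         objective_coefficient =
           if (identical(id, model$objective_id)) 1 else 0)
  })
  doc <- list(
    id = model$id,
    metabolites = mets,
    reactions = rxns,
    genes = lapply(model$genes, function(g) list(id = g, name = g)),
    compartments = list(c = "cytosol", e = "extracellular space"),
    version = "1"
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- SBML L3 + FBC v2 ------------------------------------------------------

# SBML ids cannot start with a digit and conventionally carry M_/R_/G_
# prefixes (BiGG style). Ids are required to stay within [A-Za-z0-9_].
sbml_escape <- function(x) {
  bad <- grepl("[^A-Za-z0-9_]", x)
  if (any(bad)) {
    abort(paste0("ids not representable in SBML (use [A-Za-z0-9_]): ",
                 paste(x[bad], collapse = ", ")),
          class = "gemkit_io_error")
  }
  x
}

fmt_num <- function(x) sprintf("%.17g", x)

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_escape(model$id),
                             "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true")
  }

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    node <- xml2::xml_add_child(sps, "species",
      id = paste0("M_", sbml_escape(m$id)),
      name = if (is.na(m$name)) m$id else m$name,
      compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(m$charge)) {
      xml2::xml_set_attr(node, "fbc:charge", as.character(as.integer(m$charge)))
    }
    if (!is.na(m$formula) && nzchar(m$formula)) {
      xml2::xml_set_attr(node, "fbc:chemicalFormula", m$formula)
    }
  }

  # bounds as shared parameters
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  bound_vals <- sort(unique(c(model$reactions$lower_bound,
                              model$reactions$upper_bound)))
  bound_ids <- paste0("bnd_", seq_along(bound_vals))
  names(bound_ids) <- fmt_num(bound_vals)
  for (k in seq_along(bound_vals)) {
    xml2::xml_add_child(pars, "parameter", id = bound_ids[k],
      value = fmt_num(bound_vals[k]), constant = "true",
      "sboTerm" = "SBO:0000625")
  }

  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    node <- xml2::xml_add_child(rxs, "reaction",
      id = paste0("R_", sbml_escape(r$id)),
      name = if (is.na(r$name)) r$id else r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bound_ids[[fmt_num(r$lower_bound)]],
      "fbc:upperFluxBound" = bound_ids[[fmt_num(r$upper_bound)]])
    st <- r$stoichiometry[[1]]
    reactants <- st[st < 0]
    products <- st[st > 0]
    if (length(reactants)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (mid in names(reactants)) {
        xml2::xml_add_child(lr, "speciesReference",
          species = paste0("M_", sbml_escape(mid)),
          stoichiometry = fmt_num(-reactants[[mid]]), constant = "true")
      }
    }
    if (length(products)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (mid in names(products)) {
        xml2::xml_add_child(lp, "speciesReference",
          species = paste0("M_", sbml_escape(mid)),
          stoichiometry = fmt_num(products[[mid]]), constant = "true")
      }
    }
    ast <- parse_gpr(r$gpr)
    if (!is.null(ast)) {
      gpa <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      add_gpr_node(gpa, ast)
    }
  }

  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  if (!is.null(model$objective_id)) {
    lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
      "fbc:reaction" = paste0("R_", sbml_escape(model$objective_id)),
      "fbc:coefficient" = "1")
  }

  if (length(model$genes)) {
    lgp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(lgp, "fbc:geneProduct",
        "fbc:id" = paste0("G_", sbml_escape(g)), "fbc:label" = g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

add_gpr_node <- function(parent, ast) {
  if (ast$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
      "fbc:geneProduct" = paste0("G_", sbml_escape(ast$id)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
    for (child in ast$args) add_gpr_node(node, child)
  }
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed SBML file '", path, "': ", conditionMessage(e)),
          class = "gemkit_io_error")
  })
  ns <- c(s = SBML_NS, f = FBC_NS)
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    abort("malformed SBML: no <model> element", class = "gemkit_io_error")
  }

  strip <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) == 0) {
    abort("malformed SBML: no <species> elements", class = "gemkit_io_error")
  }
  mets <- tibble(
    id = strip(xml2::xml_attr(sp_nodes, "id"), "M"),
    name = xml2::xml_attr(sp_nodes, "name"),
    formula = xml2::xml_attr(sp_nodes, "f:chemicalFormula", ns = ns),
    charge = as.integer(xml2::xml_attr(sp_nodes, "f:charge", ns = ns)),
    compartment = xml2::xml_attr(sp_nodes, "compartment")
  )

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                              xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0) {
    abort("malformed SBML: no <reaction> elements", class = "gemkit_io_error")
  }
  rxns <- tibble(
    id = strip(xml2::xml_attr(rx_nodes, "id"), "R"),
    name = xml2::xml_attr(rx_nodes, "name"),
    stoichiometry = lapply(rx_nodes, function(node) {
      reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
      prod <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
      st <- c(
        stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                        strip(xml2::xml_attr(reac, "species"), "M")),
        stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                        strip(xml2::xml_attr(prod, "species"), "M")))
      if (length(st) == 0) {
        abort(paste0("malformed SBML: reaction '",
                     xml2::xml_attr(node, "id"), "' has no participants"),
              class = "gemkit_io_error")
      }
      # merge duplicated species (reactant and product of the same reaction)
      tapply(st, names(st), sum)[unique(names(st))]
    }),
    lower_bound = vapply(rx_nodes, function(node) {
      par_vals[[xml2::xml_attr(node, "f:lowerFluxBound", ns = ns)]]
    }, numeric(1)),
    upper_bound = vapply(rx_nodes, function(node) {
      par_vals[[xml2::xml_attr(node, "f:upperFluxBound", ns = ns)]]
    }, numeric(1)),
    gpr = vapply(rx_nodes, function(node) {
      gpa <- xml2::xml_find_first(node, "./f:geneProductAssociation", ns)
      if (inherits(gpa, "xml_missing")) return("")
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0) return("")
      deparse_gpr(read_gpr_node(kids[[1]], ns))
    }, character(1))
  )

  fo <- xml2::xml_find_first(
    mdl, ".//f:listOfObjectives//f:fluxObjective", ns)
  objective_id <- if (!inherits(fo, "xml_missing")) {
    strip(xml2::xml_attr(fo, "f:reaction", ns = ns), "R")
  } else NULL

  gp_nodes <- xml2::xml_find_all(mdl, ".//f:listOfGeneProducts/f:geneProduct", ns)
  genes <- xml2::xml_attr(gp_nodes, "f:label", ns = ns)
  missing_label <- is.na(genes)
  genes[missing_label] <- strip(xml2::xml_attr(gp_nodes, "f:id", ns = ns), "G")[missing_label]

  metabolic_model(strip(xml2::xml_attr(mdl, "id") %||% "model", "M"),
                  mets, rxns, genes = genes, objective_id = objective_id)
}

read_gpr_node <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "f:geneProduct", ns = ns)
    return(list(op = "gene", id = sub("^G_", "", gid)))
  }
  if (!nm %in% c("and", "or")) {
    abort(paste0("malformed SBML GPR node: <", nm, ">"),
          class = "gemkit_io_error")
  }
  list(op = nm, args = lapply(xml2::xml_children(node), read_gpr_node, ns = ns))
}

# ---- medium files ----------------------------------------------------------

#' Read a medium definition from TSV
#'
#' The file has columns `exchange_id`, `lower_bound`, `upper_bound`
#' (mmol gDW^-1 h^-1).
#'
#' @param path TSV path.
#' @param name medium name; defaults to the file stem.
#' @return a `gemkit_medium` tibble.
#' @export
read_medium <- function(path, name = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("exchange_id", "lower_bound", "upper_bound")
  if (!all(required %in% names(tab))) {
    abort(paste0("medium file must have columns: ",
                 paste(required, collapse = ", ")),
          class = "gemkit_io_error")
  }
  medium(stats::setNames(
    lapply(seq_len(nrow(tab)), function(i) c(tab$lower_bound[i], tab$upper_bound[i])),
    tab$exchange_id),
    name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a medium definition to TSV
#'
#' @param med a [medium()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(med, path) {
  readr::write_tsv(med, path)
  invisible(path)
}
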