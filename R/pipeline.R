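# End-to-end orchestration: ortholog calling -> strain derivation ->
# multi-gap-fill -> growth screens -> classification -> clustering -> export.
# Stage artifacts are written to disk (models as JSON, tables as TSV) so any
# stage can be inspected or re-run in isolation, and the fully resolved
# configuration is serialised into the output directory for provenance.

#' Pipeline configuration
#'
#' @param template a [metabolic_model()] or path to a model file.
#' @param homology genes x strains matrix or path to a homology TSV.
#' @param base_medium a [medium()] or path to a medium TSV (carbon-free).
#' @param sources character vector of candidate exchange ids, or path to a
#'   one-column (`exchange_id`) TSV.
#' @param out_dir output directory.
#' @param primary,relaxed,prevalence ortholog-calling thresholds
#'   (see [call_orthologs()]).
#' @param universal,specific classification boundaries
#'   (see [classify_sources()]).
#' @param growth_threshold binary growth call threshold (h^-1).
#' @param uptake screen uptake magnitude (mmol gDW^-1 h^-1).
#' @param normalize_mode `"per_carbon"` or `"carbon_equivalent_uptake"`.
#' @param linkage clustering linkage method.
#' @param seed seed recorded for provenance.
#' @return a `run_config` list.
#' @export
run_config <- function(template, homology, base_medium, sources, out_dir,
                       primary = 70, relaxed = 40, prevalence = 0.75,
                       universal = 0.90, specific = 0.30,
                       growth_threshold = GROWTH_THRESHOLD,
                       uptake = 10, normalize_mode = "per_carbon",
                       linkage = "complete", seed = 1L) {
  stopifnot(primary >= 0, primary <= 100, relaxed >= 0, relaxed <= primary,
            prevalence >= 0, prevalence <= 1,
            universal >= 0, universal <= 1, specific >= 0,
            specific <= universal, uptake > 0)
  structure(list(template = template, homology = homology,
                 base_medium = base_medium, sources = sources,
                 out_dir = out_dir, primary = primary, relaxed = relaxed,
                 prevalence = prevalence, universal = universal,
                 specific = specific, growth_threshold = growth_threshold,
                 uptake = uptake, normalize_mode = normalize_mode,
                 linkage = linkage, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file with the fields of [run_config()]; file
#'   paths in it are resolved relative to the configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p))) {
      file.path(base, p)
    } else {
      p
    }
  }
  for (f in c("template", "homology", "base_medium", "sources")) {
    cfg[[f]] <- rel(cfg[[f]])
  }
  do.call(run_config, cfg)
}

#' Run the multistrain panphenome pipeline
#'
#' Stages: call orthologs from the homology matrix, derive one model per
#' strain from the template, gap-fill the strains that grow on no screened
#' source, screen every functional strain across the carbon sources, classify
#' sources as universal/core/strain-specific, cluster strains into HMV/LMV
#' groups, and export the plotting bundle. All stage outputs land under
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return list with `presence`, `models`, `gapfill`, `growth_matrix`,
#'   `classification`, `clustering`, `n_non_functional` and `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[gemkit] ", ...)

  template <- if (is.character(config$template)) {
    read_model(config$template)
  } else {
    config$template
  }
  homology <- if (is.character(config$homology)) {
    read_homology(config$homology)
  } else {
    config$homology
  }
  base_medium <- if (is.character(config$base_medium)) {
    read_medium(config$base_medium)
  } else {
    config$base_medium
  }
  sources <- if (is.character(config$sources) && length(config$sources) == 1 &&
                 file.exists(config$sources)) {
    readr::read_tsv(config$sources, show_col_types = FALSE)$exchange_id
  } else {
    config$sources
  }
  if (ncol(homology) == 0) {
    abort("no strains in homology matrix", class = "gemkit_usage_error")
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_out <- config
  cfg_out$template <- if (is.character(config$template)) config$template else template$id
  cfg_out$homology <- if (is.character(config$homology)) config$homology else "<in-memory>"
  cfg_out$base_medium <- if (is.character(config$base_medium)) config$base_medium else attr(base_medium, "name")
  jsonlite::write_json(unclass(cfg_out), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  say("calling orthologs for ", ncol(homology), " strains")
  presence <- call_orthologs(homology, primary = config$primary,
                             relaxed = config$relaxed,
                             prevalence = config$prevalence)
  readr::write_tsv(tidy(presence), file.path(config$out_dir, "presence.tsv"))

  say("deriving strain models")
  models <- derive_strain_cohort(template, presence)
  model_dir <- file.path(config$out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  for (s in names(models)) {
    write_model(models[[s]], file.path(model_dir, paste0(s, ".json")))
  }

  say("gap-filling strains without growth on any source")
  media_list <- lapply(sources, function(ex) {
    med <- as_tibble(base_medium)
    med <- bind_rows(med, tibble(exchange_id = ex,
                                 lower_bound = -config$uptake,
                                 upper_bound = DEFAULT_BIG))
    medium(med, name = paste0("base+", ex))
  })
  gf <- multi_gap_fill(models, template, media_list,
                       growth_threshold = config$growth_threshold)
  readr::write_tsv(select(gf, -"added", -"model") |>
                     mutate(added = map_chr(gf$added, paste, collapse = ",")),
                   file.path(config$out_dir, "gapfill.tsv"))
  functional <- gf$strain[gf$status %in% c("growing", "already_growing", "filled")]
  models_fn <- stats::setNames(gf$model[match(functional, gf$strain)], functional)
  n_non_functional <- length(models) - length(functional)
  if (n_non_functional > 0) {
    say(n_non_functional, " strain(s) remain non-functional and are excluded")
  }
  if (length(models_fn) == 0) {
    abort("no functional strain models after gap filling",
          class = "gemkit_pipeline_error")
  }

  say("screening ", length(models_fn), " strains x ", length(sources),
      " carbon sources")
  gm <- build_growth_matrix(models_fn, sources, base_medium,
                            uptake = config$uptake,
                            normalize_mode = config$normalize_mode,
                            growth_threshold = config$growth_threshold)

  say("classifying sources and clustering strains")
  classification <- classify_sources(gm, universal = config$universal,
                                     specific = config$specific)
  clustering <- if (length(models_fn) >= 2) {
    cluster_strains(gm, linkage = config$linkage)
  } else {
    NULL
  }

  strain_annotations <- tibble(
    strain = names(models_fn),
    model_genes = vapply(models_fn, function(m) length(m$genes), integer(1)),
    model_reactions = vapply(models_fn, function(m) nrow(m$reactions), integer(1)))
  if (!is.null(clustering)) {
    export_heatmap_data(gm, classification, clustering,
                        file.path(config$out_dir, "panphenome"),
                        strain_annotations = strain_annotations)
  }

  say("done")
  list(presence = presence, models = models, gapfill = gf,
       growth_matrix = gm, classification = classification,
       clustering = clustering, n_non_functional = n_non_functional,
       out_dir = config$out_dir)
}
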