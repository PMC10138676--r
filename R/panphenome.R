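# Panphenome assembly: the strain x carbon-source growth matrix, the
# universal/core/strain-specific classification of carbon sources, and
# hierarchical clustering of strains into high- and low-metabolic-versatility
# (HMV/LMV) groups.

#' Build the strain-by-carbon-source growth matrix
#'
#' Runs one carbon-source screen per strain model. Strains whose screen fails
#' outright (solver error) are flagged and skipped; the cohort continues.
#'
#' @param strain_models named list of [metabolic_model()]s.
#' @param sources candidate exchange reaction ids.
#' @param base_medium carbon-free [medium()].
#' @param uptake uptake magnitude per source (default 10 mmol gDW^-1 h^-1).
#' @param normalize_mode `"per_carbon"` or `"carbon_equivalent_uptake"`.
#' @param ... further arguments for [screen_carbon_sources()].
#' @return a `growth_matrix`: long tibble with `strain`, `carbon_source`,
#'   `n_carbons`, `growth_rate`, `normalized_growth`, `grows`; failed strains
#'   are listed in attribute `failed_strains`.
#' @export
build_growth_matrix <- function(strain_models, sources, base_medium,
                                uptake = 10,
                                normalize_mode = c("per_carbon",
                                                   "carbon_equivalent_uptake"),
                                ...) {
  normalize_mode <- match.arg(normalize_mode)
  if (length(strain_models) == 0) {
    abort("no strain models supplied", class = "gemkit_usage_error")
  }
  failed <- character(0)
  rows <- imap(strain_models, function(model, strain) {
    scr <- tryCatch(
      screen_carbon_sources(model, base_medium, sources, uptake = uptake,
                            normalize_mode = normalize_mode, ...),
      error = function(e) {
        warn(paste0("screen failed for strain ", strain, ": ",
                    conditionMessage(e)))
        NULL
      })
    if (is.null(scr)) {
      failed <<- c(failed, strain)
      return(NULL)
    }
    mutate(select(scr, -"secreted"), strain = strain, .before = 1)
  })
  out <- bind_rows(rows)
  attr(out, "failed_strains") <- failed
  attr(out, "normalize_mode") <- normalize_mode
  class(out) <- c("growth_matrix", class(out))
  out
}

# wide strains x sources matrix of one layer of the growth matrix
growth_layer <- function(gm, layer = c("normalized", "raw", "binary")) {
  layer <- match.arg(layer)
  col <- switch(layer, normalized = "normalized_growth", raw = "growth_rate",
                binary = "grows")
  wide <- tidyr::pivot_wider(gm[, c("strain", "carbon_source", col)],
                             names_from = "carbon_source",
                             values_from = all_of(col))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$strain
  mode(m) <- "numeric"
  m
}

#' Classify carbon sources by the fraction of strains they support
#'
#' A source is `universal` when strictly more than `universal` (default 90%)
#' of the strains grow on it, `strain_specific` when fewer than `specific`
#' (default 30%) do, and `core` in between (both boundaries inclusive on the
#' core side).
#'
#' @param gm a `growth_matrix` from [build_growth_matrix()].
#' @param universal,specific class boundaries on the growth fraction.
#' @return tibble: `carbon_source`, `growth_fraction`, `class`.
#' @export
classify_sources <- function(gm, universal = 0.90, specific = 0.30) {
  if (nrow(gm) == 0) {
    abort("empty growth matrix", class = "gemkit_usage_error")
  }
  out <- gm |>
    group_by(.data$carbon_source) |>
    summarise(growth_fraction = mean(.data$grows), .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$growth_fraction > universal ~ "universal",
      .data$growth_fraction < specific ~ "strain_specific",
      TRUE ~ "core"
    ))
  structure(out, universal = universal, specific = specific,
            class = c("source_classification", class(out)))
}

#' Cluster strains by their growth profiles
#'
#' Agglomerative clustering on Manhattan distances between strain growth
#' profiles, cut into `k` groups. The group with the larger mean number of
#' growth-supporting sources is labelled HMV (high metabolic versatility),
#' the other LMV. Within HMV, a second two-way cut labels the alpha/beta
#' subgroups. With all-identical profiles a single cluster is reported and
#' labeling is skipped.
#'
#' @param gm a `growth_matrix`.
#' @param layer which layer to cluster on: `"normalized"` (default), `"raw"`
#'   or `"binary"`.
#' @param linkage agglomeration method (default `"complete"`).
#' @param k number of groups for the main cut.
#' @return object of class `strain_clustering`: list with the `hclust` tree,
#'   a `labels` tibble (`strain`, `cluster`, `group`, `subgroup`,
#'   `n_positive`), and the settings used.
#' @export
cluster_strains <- function(gm, layer = c("normalized", "raw", "binary"),
                            linkage = "complete", k = 2) {
  layer <- match.arg(layer)
  prof <- growth_layer(gm, layer)
  if (nrow(prof) < 2) {
    abort("need at least 2 strains to cluster", class = "gemkit_usage_error")
  }
  d <- stats::dist(prof, method = "manhattan")
  npos <- rowSums(growth_layer(gm, "binary") > 0)

  if (max(d) < 1e-12) {
    labels <- tibble(strain = rownames(prof), cluster = 1L,
                     group = NA_character_, subgroup = NA_character_,
                     n_positive = unname(npos[rownames(prof)]))
    return(structure(list(tree = NULL, labels = labels, distance = "manhattan",
                          linkage = linkage, layer = layer, degenerate = TRUE),
                     class = "strain_clustering"))
  }

  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)
  mean_pos <- tapply(npos[names(cl)], cl, mean)
  hmv_cluster <- as.integer(names(which.max(mean_pos)))
  group <- ifelse(cl == hmv_cluster, "HMV", "LMV")

  subgroup <- rep(NA_character_, length(cl))
  names(subgroup) <- names(cl)
  hmv_strains <- names(cl)[group == "HMV"]
  if (length(hmv_strains) >= 2) {
    dh <- stats::dist(prof[hmv_strains, , drop = FALSE], method = "manhattan")
    if (max(dh) > 1e-12) {
      sub_cl <- stats::cutree(stats::hclust(dh, method = linkage), k = 2)
      # alpha = subgroup with more strains (arbitrary but deterministic)
      alpha <- as.integer(names(which.max(table(sub_cl))))
      subgroup[hmv_strains] <- ifelse(sub_cl == alpha, "alpha", "beta")
    }
  }

  labels <- tibble(strain = names(cl), cluster = unname(cl),
                   group = unname(group),
                   subgroup = unname(subgroup[names(cl)]),
                   n_positive = unname(npos[names(cl)]))
  structure(list(tree = tree, labels = labels, distance = "manhattan",
                 linkage = linkage, layer = layer, degenerate = FALSE),
            class = "strain_clustering")
}

#' @export
print.strain_clustering <- function(x, ...) {
  cat("<strain_clustering> ", nrow(x$labels), " strains, ",
      x$distance, " distance, ", x$linkage, " linkage\n", sep = "")
  if (!x$degenerate) {
    print(table(x$labels$group))
  } else {
    cat("  degenerate: all profiles identical\n")
  }
  invisible(x)
}

#' Strain order along the dendrogram leaves
#'
#' @param clustering a `strain_clustering`.
#' @return character vector of strain ids in leaf order.
#' @export
leaf_order <- function(clustering) {
  if (is.null(clustering$tree)) return(clustering$labels$strain)
  clustering$tree$labels[clustering$tree$order]
}

#' Export the panphenome bundle for plotting
#'
#' Writes, under `dir`: `growth_matrix.tsv` (long layout, strains ordered by
#' dendrogram leaves), `sources.tsv` (per-source class annotation),
#' `strains.tsv` (per-strain group labels plus any side annotations),
#' `classification.json`, and `dendrogram.nwk` (Newick).
#'
#' @param gm a `growth_matrix`.
#' @param classification a `source_classification`.
#' @param clustering a `strain_clustering`.
#' @param dir output directory (created if missing).
#' @param strain_annotations optional tibble keyed by `strain` (e.g. total
#'   genome genes and model genes) joined into `strains.tsv`.
#' @return `dir`, invisibly.
#' @export
export_heatmap_data <- function(gm, classification, clustering, dir,
                                strain_annotations = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  order <- leaf_order(clustering)
  gm_out <- as_tibble(gm)
  gm_out$strain <- factor(gm_out$strain, levels = order)
  gm_out <- arrange(gm_out, .data$strain, .data$carbon_source)
  gm_out$strain <- as.character(gm_out$strain)
  readr::write_tsv(gm_out, file.path(dir, "growth_matrix.tsv"))

  readr::write_tsv(as_tibble(classification), file.path(dir, "sources.tsv"))

  strains <- clustering$labels
  strains$strain <- factor(strains$strain, levels = order)
  strains <- arrange(strains, .data$strain)
  strains$strain <- as.character(strains$strain)
  if (!is.null(strain_annotations)) {
    strains <- left_join(strains, strain_annotations, by = "strain")
  }
  readr::write_tsv(strains, file.path(dir, "strains.tsv"))

  jsonlite::write_json(
    stats::setNames(as.list(classification$class),
                    classification$carbon_source),
    file.path(dir, "classification.json"), auto_unbox = TRUE)

  if (!is.null(clustering$tree)) {
    writeLines(hclust_to_newick(clustering$tree),
               file.path(dir, "dendrogram.nwk"))
  }
  invisible(dir)
}

# minimal Newick serialisation of an hclust tree (leaf labels + branch heights)
hclust_to_newick <- function(tree) {
  build <- function(i, parent_height) {
    if (i < 0) {
      lab <- tree$labels[-i]
      return(paste0(lab, ":", fmt_num(parent_height)))
    }
    h <- tree$height[i]
    kids <- vapply(tree$merge[i, ], build, character(1), parent_height = h)
    paste0("(", paste(kids, collapse = ","), "):",
           fmt_num(max(parent_height - h, 0)))
  }
  root <- nrow(tree$merge)
  paste0(build(root, tree$height[root]), ";")
}
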