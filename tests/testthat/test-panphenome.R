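# build a growth_matrix tibble directly from a binary strains x sources matrix
gm_from_binary <- function(bin) {
  out <- tibble::tibble(
    strain = rep(rownames(bin), times = ncol(bin)),
    carbon_source = rep(colnames(bin), each = nrow(bin)),
    n_carbons = 6,
    growth_rate = as.numeric(bin) * 0.5,
    normalized_growth = as.numeric(bin) * 0.5 / 6,
    grows = as.logical(bin))
  class(out) <- c("growth_matrix", class(out))
  out
}

test_that("the growth matrix equals per-strain independent screens", {
  toy <- make_toy_gem()
  coh <- make_strain_cohort(toy, cohort_spec(n_strains = 6,
                                             deletion_rate = 0.15, seed = 2))
  models <- derive_strain_cohort(toy$model, call_orthologs(coh$homology))
  sources <- toy$answer$sources$exchange_id
  gm <- build_growth_matrix(models, sources, toy$base_medium)
  for (s in names(models)) {
    scr <- screen_carbon_sources(models[[s]], toy$base_medium, sources)
    sub <- gm[gm$strain == s, ]
    expect_equal(sub$growth_rate, scr$growth_rate, info = s)
    expect_equal(sub$grows, scr$grows, info = s)
  }
})

test_that("an identical cohort produces identical rows", {
  toy <- make_toy_gem()
  models <- list(a = toy$model, b = toy$model, c = toy$model)
  gm <- build_growth_matrix(models, toy$answer$sources$exchange_id,
                            toy$base_medium)
  wide <- pheno_from_growth_matrix(gm)
  expect_true(all(apply(wide, 2, function(col) length(unique(col)) == 1)))
})

test_that("classification recovers planted growth fractions exactly", {
  set.seed(21)
  n <- 100
  fractions <- c(src_a = 0.95, src_b = 0.5, src_c = 0.1)
  bin <- sapply(fractions, function(f) {
    v <- rep(FALSE, n); v[sample(n, round(f * n))] <- TRUE; v
  })
  rownames(bin) <- sprintf("s%03d", 1:n)
  cls <- classify_sources(gm_from_binary(bin))
  expect_equal(stats::setNames(cls$growth_fraction, cls$carbon_source),
               fractions[cls$carbon_source])
  expect_equal(stats::setNames(cls$class, cls$carbon_source),
               c(src_a = "universal", src_b = "core", src_c = "strain_specific"))
})

test_that("class boundaries are inclusive on the core side", {
  n <- 10
  bin <- cbind(at90 = rep(c(TRUE, FALSE), c(9, 1)),
               at30 = rep(c(TRUE, FALSE), c(3, 7)),
               all = rep(TRUE, n),
               none = rep(FALSE, n))
  rownames(bin) <- paste0("s", 1:n)
  cls <- classify_sources(gm_from_binary(bin))
  got <- stats::setNames(cls$class, cls$carbon_source)
  expect_equal(got[["at90"]], "core")          # exactly 0.90 is core
  expect_equal(got[["at30"]], "core")          # exactly 0.30 is core
  expect_equal(got[["all"]], "universal")
  expect_equal(got[["none"]], "strain_specific")
})

test_that("classification is invariant under strain permutation", {
  set.seed(4)
  bin <- matrix(runif(60) < 0.5, 12, 5,
                dimnames = list(paste0("s", 1:12), paste0("src", 1:5)))
  gm <- gm_from_binary(bin)
  gm_perm <- gm[sample(nrow(gm)), ]
  class(gm_perm) <- class(gm)
  expect_equal(dplyr::arrange(as.data.frame(classify_sources(gm)), carbon_source),
               dplyr::arrange(as.data.frame(classify_sources(gm_perm)), carbon_source))
})

test_that("removing one strain moves any growth fraction by at most 1/(n-1)", {
  set.seed(5)
  bin <- matrix(runif(80) < 0.6, 16, 5,
                dimnames = list(paste0("s", 1:16), paste0("src", 1:5)))
  gm <- gm_from_binary(bin)
  f_all <- classify_sources(gm)$growth_fraction
  for (drop in rownames(bin)[1:4]) {
    sub <- gm[gm$strain != drop, ]
    class(sub) <- class(gm)
    f_sub <- classify_sources(sub)$growth_fraction
    expect_true(all(abs(f_sub - f_all) <= 1 / (nrow(bin) - 1) + 1e-12))
  }
})

test_that("planted phenotype blocks are recovered as HMV and LMV", {
  # 6 versatile strains (grow on 5 sources), 4 reduced strains (1 source)
  bin <- rbind(matrix(TRUE, 6, 5), cbind(TRUE, matrix(FALSE, 4, 4)))
  dimnames(bin) <- list(paste0("s", 1:10), paste0("src", 1:5))
  # jitter the growth rates so profiles inside a block aren't identical
  gm <- gm_from_binary(bin)
  set.seed(8)
  gm$normalized_growth <- gm$normalized_growth +
    ifelse(gm$grows, runif(nrow(gm), 0, 0.01), 0)
  cl <- cluster_strains(gm)
  labels <- stats::setNames(cl$labels$group, cl$labels$strain)
  expect_true(all(labels[paste0("s", 1:6)] == "HMV"))
  expect_true(all(labels[paste0("s", 7:10)] == "LMV"))
  # HMV has the larger mean positive-source count by construction
  expect_gt(mean(cl$labels$n_positive[cl$labels$group == "HMV"]),
            mean(cl$labels$n_positive[cl$labels$group == "LMV"]))
})

test_that("duplicate strains land in the same cluster at zero distance", {
  bin <- rbind(a = c(TRUE, TRUE, FALSE), b = c(TRUE, TRUE, FALSE),
               c = c(FALSE, FALSE, TRUE))
  colnames(bin) <- paste0("src", 1:3)
  cl <- cluster_strains(gm_from_binary(bin))
  lab <- cl$labels
  expect_equal(lab$cluster[lab$strain == "a"], lab$cluster[lab$strain == "b"])
  expect_equal(unname(as.matrix(stats::dist(
    gemkit:::growth_layer(gm_from_binary(bin), "normalized"),
    method = "manhattan"))["a", "b"]), 0)
})

test_that("all-identical profiles degrade to a single unlabeled cluster", {
  bin <- matrix(TRUE, 4, 3, dimnames = list(paste0("s", 1:4),
                                            paste0("src", 1:3)))
  cl <- cluster_strains(gm_from_binary(bin))
  expect_true(cl$degenerate)
  expect_true(all(is.na(cl$labels$group)))
  expect_equal(leaf_order(cl), paste0("s", 1:4))
})

test_that("clustering is equivariant under strain relabeling", {
  set.seed(13)
  bin <- matrix(runif(50) < 0.5, 10, 5,
                dimnames = list(paste0("s", 1:10), paste0("src", 1:5)))
  gm <- gm_from_binary(bin)
  cl <- cluster_strains(gm)
  # relabel strains by a fixed permutation of their names
  perm <- stats::setNames(paste0("t", sample(10)), paste0("s", 1:10))
  gm2 <- gm
  gm2$strain <- unname(perm[gm2$strain])
  class(gm2) <- class(gm)
  cl2 <- cluster_strains(gm2)
  m1 <- stats::setNames(cl$labels$group, perm[cl$labels$strain])
  m2 <- stats::setNames(cl2$labels$group, cl2$labels$strain)
  expect_equal(m2[names(m1)], m1)
})

test_that("the exported bundle round-trips and stays consistent", {
  toy <- make_toy_gem()
  coh <- make_strain_cohort(toy, cohort_spec(n_strains = 6,
                                             deletion_rate = 0.2, seed = 11))
  models <- derive_strain_cohort(toy$model, call_orthologs(coh$homology))
  gm <- build_growth_matrix(models, toy$answer$sources$exchange_id,
                            toy$base_medium)
  cls <- classify_sources(gm)
  cl <- cluster_strains(gm)
  dir <- withr::local_tempdir()
  export_heatmap_data(gm, cls, cl, dir)

  back <- readr::read_tsv(file.path(dir, "growth_matrix.tsv"),
                          show_col_types = FALSE)
  expect_equal(dplyr::arrange(back, strain, carbon_source),
               dplyr::arrange(as.data.frame(gm), strain, carbon_source),
               ignore_attr = TRUE)
  # strain order in the export equals the dendrogram leaf order
  expect_equal(unique(back$strain), leaf_order(cl))

  src <- readr::read_tsv(file.path(dir, "sources.tsv"), show_col_types = FALSE)
  expect_equal(table(src$class), table(cls$class))
  cls_json <- jsonlite::fromJSON(file.path(dir, "classification.json"))
  expect_equal(unlist(cls_json[cls$carbon_source]),
               stats::setNames(cls$class, cls$carbon_source))

  # leaf order is stable across repeated runs
  dir2 <- withr::local_tempdir()
  export_heatmap_data(gm, cls, cluster_strains(gm), dir2)
  expect_identical(readLines(file.path(dir, "growth_matrix.tsv")),
                   readLines(file.path(dir2, "growth_matrix.tsv")))
  expect_identical(readLines(file.path(dir, "dendrogram.nwk")),
                   readLines(file.path(dir2, "dendrogram.nwk")))
})

test_that("the Newick export parses and carries all strains", {
  bin <- rbind(a = c(TRUE, TRUE, FALSE), b = c(TRUE, FALSE, FALSE),
               c = c(FALSE, FALSE, TRUE), d = c(TRUE, TRUE, TRUE))
  colnames(bin) <- paste0("src", 1:3)
  cl <- cluster_strains(gm_from_binary(bin))
  nwk <- gemkit:::hclust_to_newick(cl$tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(bin))
})
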