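# Robust comparison of predicted versus measured fluxes.
#
# The biweight midcorrelation (bicor) replaces mean and standard deviation by
# median and median absolute deviation and down-weights points far from the
# median with Tukey's biweight, so a single aberrant flux measurement cannot
# dominate the correlation the way it does with Pearson's r.

#' Biweight midcorrelation
#'
#' For each vector, `u_i = (x_i - med(x)) / (9 * mad(x))` with the *unscaled*
#' median absolute deviation, weights `w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]`,
#' and `x~_i = (x_i - med(x)) * w_i`; then
#' `bicor = sum(x~ y~) / sqrt(sum(x~^2) * sum(y~^2))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) {
    abort("bicor: x and y must have equal length", class = "gemkit_stat_error")
  }
  if (length(x) < 3) {
    abort("bicor: need at least 3 observations", class = "gemkit_stat_error")
  }
  xt <- bicor_transform(x)
  yt <- bicor_transform(y)
  denom <- sqrt(sum(xt^2) * sum(yt^2))
  if (denom == 0) {
    abort("bicor: degenerate input (all weighted deviations zero)",
          class = "gemkit_stat_error")
  }
  sum(xt * yt) / denom
}

bicor_transform <- function(x) {
  med <- stats::median(x)
  madx <- stats::median(abs(x - med))  # unscaled MAD
  if (madx == 0) {
    abort("bicor: zero median absolute deviation", class = "gemkit_stat_error")
  }
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Permutation test for the biweight midcorrelation
#'
#' Two-sided p-value from random permutations of `y`, with the add-one
#' correction `(1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`.
#'
#' @inheritParams bicor
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list with `estimate` and `p_value`.
#' @export
bicor_test <- function(x, y, n_perm = 10000, seed = 1L) {
  obs <- bicor(x, y)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      r <- tryCatch(bicor(x, sample(y)), error = function(e) NA_real_)
      r
    }, numeric(1))
  })
  perm <- perm[!is.na(perm)]
  list(estimate = obs,
       p_value = (1 + sum(abs(perm) >= abs(obs))) / (length(perm) + 1))
}

#' Compare predicted and measured flux sets per pathway
#'
#' Pairs the two flux vectors on reaction id, applies the measured table's
#' orientation column (`-1` when the measurement refers to the reverse of the
#' model reaction), and computes the biweight midcorrelation per pathway and
#' overall. Pathways with fewer than 3 pairs are reported with `NA` and a
#' notice.
#'
#' @param predicted a `flux_solution` from [solve_fba()] or a named flux
#'   vector.
#' @param measured data frame with columns `reaction_id`, `flux` and
#'   optionally `orientation` (+1/-1, default +1).
#' @param pathway_map data frame with columns `reaction_id`, `pathway`
#'   (e.g. glycolysis, PPP, TCA).
#' @param n_perm,seed permutation-test settings (see [bicor_test()]).
#' @return a `flux_comparison` tibble: `pathway`, `n`, `bicor`, `p_value`,
#'   plus a `pairs` list column with the paired table; unmatched measured
#'   reactions are kept in attribute `unmatched`.
#' @export
compare_flux_sets <- function(predicted, measured, pathway_map,
                              n_perm = 10000, seed = 1L) {
  fluxes <- if (inherits(predicted, "flux_solution")) {
    if (predicted$status != "optimal") {
      abort("predicted solution is not optimal", class = "gemkit_contract_error")
    }
    predicted$fluxes
  } else {
    predicted
  }
  measured <- as_tibble(measured)
  if (!"orientation" %in% names(measured)) measured$orientation <- 1
  measured$orientation[is.na(measured$orientation)] <- 1

  paired <- measured |>
    mutate(measured_flux = .data$flux * .data$orientation) |>
    filter(.data$reaction_id %in% names(fluxes)) |>
    mutate(predicted_flux = unname(fluxes[.data$reaction_id])) |>
    left_join(as_tibble(pathway_map), by = "reaction_id") |>
    select("reaction_id", "pathway", "predicted_flux", "measured_flux")
  unmatched <- setdiff(measured$reaction_id, paired$reaction_id)

  groups <- c(stats::setNames(
    lapply(unique(paired$pathway[!is.na(paired$pathway)]),
           function(p) paired[!is.na(paired$pathway) & paired$pathway == p, ]),
    unique(paired$pathway[!is.na(paired$pathway)])),
    list(all = paired))

  rows <- imap(groups, function(tab, label) {
    if (nrow(tab) < 3) {
      rlang::inform(paste0("pathway '", label, "': fewer than 3 paired ",
                           "reactions, comparison skipped"))
      return(tibble(pathway = label, n = nrow(tab), bicor = NA_real_,
                    p_value = NA_real_, pairs = list(tab)))
    }
    bt <- tryCatch(
      bicor_test(tab$predicted_flux, tab$measured_flux,
                 n_perm = n_perm, seed = seed),
      error = function(e) list(estimate = NA_real_, p_value = NA_real_))
    tibble(pathway = label, n = nrow(tab), bicor = bt$estimate,
           p_value = bt$p_value, pairs = list(tab))
  })
  out <- bind_rows(rows)
  attr(out, "unmatched") <- unmatched
  class(out) <- c("flux_comparison", class(out))
  out
}

#' Read a measured-flux table from TSV
#'
#' Columns: `reaction_id`, `flux` (mmol gDW^-1 h^-1) and optional
#' `orientation` (+1/-1).
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_measured_fluxes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("reaction_id", "flux") %in% names(tab))) {
    abort("measured flux TSV needs columns reaction_id, flux",
          class = "gemkit_io_error")
  }
  tab
}
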