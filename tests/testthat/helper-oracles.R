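# Independent oracles used across the suite. Each re-derives the expected
# result by a different route than the implementation: exhaustive enumeration,
# a direct transcription of a defining formula, or plain nested loops.

# Exhaustive vertex enumeration for max c'v s.t. S v = 0, lb <= v <= ub.
# Every basic solution (n - rank(S) variables pinned to a bound) is solved and
# filtered for feasibility; the best objective over the finitely many vertices
# is the LP optimum.
oracle_lp_vertex <- function(cc, S, lb, ub) {
  n <- length(cc)
  r <- qr(S)$rank
  nb_count <- max(n - r, 0)
  combs <- if (nb_count == 0) list(integer(0)) else
    utils::combn(n, nb_count, simplify = FALSE)
  best <- -Inf
  for (nb in combs) {
    bvars <- setdiff(seq_len(n), nb)
    grid <- if (length(nb)) expand.grid(rep(list(1:2), length(nb))) else
      data.frame(row.names = 1)
    for (gi in seq_len(nrow(grid))) {
      v <- numeric(n)
      if (length(nb)) v[nb] <- ifelse(unlist(grid[gi, ]) == 1, lb[nb], ub[nb])
      SB <- S[, bvars, drop = FALSE]
      rhs <- -as.vector(S[, nb, drop = FALSE] %*% v[nb])
      sol <- tryCatch(qr.solve(SB, rhs, tol = 1e-12), error = function(e) NULL)
      if (is.null(sol) || max(abs(SB %*% sol - rhs)) > 1e-8) next
      v[bvars] <- sol
      if (all(v >= lb - 1e-9 & v <= ub + 1e-9)) best <- max(best, sum(cc * v))
    }
  }
  best
}

# oracle FBA optimum for a model + medium via vertex enumeration
oracle_fba_optimum <- function(model, med) {
  m <- apply_medium(model, med)
  S <- gemkit:::stoichiometric_matrix(m)
  cc <- as.numeric(colnames(S) == m$objective_id)
  oracle_lp_vertex(cc, S, pmax(m$reactions$lower_bound, -1000),
                   pmin(m$reactions$upper_bound, 1000))
}

# Brute-force two-pass ortholog caller: first pass computes, per gene, the
# fraction of strains above the relaxed threshold with explicit loops; second
# pass applies the per-gene effective threshold cell by cell.
oracle_call_orthologs <- function(pct, primary = 70, relaxed = 40,
                                  prevalence = 0.75) {
  out <- matrix(FALSE, nrow(pct), ncol(pct), dimnames = dimnames(pct))
  for (g in seq_len(nrow(pct))) {
    n_over <- 0
    for (s in seq_len(ncol(pct))) {
      if (pct[g, s] > relaxed) n_over <- n_over + 1
    }
    thr <- if (n_over / ncol(pct) > prevalence) relaxed else primary
    for (s in seq_len(ncol(pct))) {
      out[g, s] <- pct[g, s] >= thr
    }
  }
  out
}

# Direct transcription of the biweight midcorrelation definition, written as
# scalar loops to stay independent of the vectorised implementation.
oracle_bicor <- function(x, y) {
  n <- length(x)
  med_x <- median(x); med_y <- median(y)
  mad_x <- median(abs(x - med_x)); mad_y <- median(abs(y - med_y))
  xt <- numeric(n); yt <- numeric(n)
  for (i in seq_len(n)) {
    ui <- (x[i] - med_x) / (9 * mad_x)
    vi <- (y[i] - med_y) / (9 * mad_y)
    wx <- if (abs(ui) < 1) (1 - ui^2)^2 else 0
    wy <- if (abs(vi) < 1) (1 - vi^2)^2 else 0
    xt[i] <- (x[i] - med_x) * wx
    yt[i] <- (y[i] - med_y) * wy
  }
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + xt[i] * yt[i]
    dx <- dx + xt[i]^2
    dy <- dy + yt[i]^2
  }
  num / sqrt(dx * dy)
}

# Exhaustive minimum-cardinality gap fill: tries every subset of the donor bag
# up to max_k, in increasing size, and returns the smallest subset restoring
# growth (NULL when none does).
oracle_gapfill <- function(model, donor, med, max_k = 3,
                           threshold = 1e-6) {
  bag <- sort(setdiff(donor$reactions$id, model$reactions$id))
  for (k in 0:min(max_k, length(bag))) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(bag, k, simplify = FALSE)
    for (subset in subsets) {
      filled <- gemkit:::merge_reactions(model, donor, subset)
      if (growth_rate(filled, med) > threshold) return(subset)
    }
  }
  NULL
}

# GPR truth evaluation through R's own parser: and/or are rewritten to &&/||
# and genes substituted by their membership value.
oracle_gpr_eval <- function(rule, genes_present, all_genes) {
  expr <- rule
  expr <- gsub("\\band\\b", "&&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  env <- new.env()
  for (g in all_genes) assign(g, g %in% genes_present, envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

# random GPR over the given genes: recursive, bounded depth
random_gpr <- function(genes, depth = 3) {
  if (depth == 0 || runif(1) < 0.35) return(sample(genes, 1))
  op <- sample(c(" and ", " or "), 1)
  n_args <- sample(2:3, 1)
  args <- vapply(seq_len(n_args), function(i) random_gpr(genes, depth - 1),
                 character(1))
  paste0("(", paste(args, collapse = op), ")")
}
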