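# Ortholog presence calling from a gene x strain homology-percentage matrix.
#
# The calling rule has a primary threshold and a prevalence-triggered
# relaxation: a gene is an ortholog in a strain when its percent identity is
# at least 70; but when, for a given gene, the fraction of strains with
# identity strictly over 40 exceeds 0.75, that gene's threshold is relaxed to
# 40 for all strains. The effective threshold is recorded per gene.

#' Read a homology matrix from TSV
#'
#' Expected layout: first column `gene`, remaining columns one per strain,
#' values percent identity in `[0, 100]`; missing values are treated as 0.
#'
#' @param path TSV path.
#' @return numeric matrix, genes x strains.
#' @export
read_homology <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1] != "gene") {
    abort("homology TSV must have a leading 'gene' column",
          class = "gemkit_io_error")
  }
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$gene
  m[is.na(m)] <- 0
  validate_homology(m)
  m
}

#' Write a homology matrix to TSV
#'
#' @param homology genes x strains numeric matrix.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_homology <- function(homology, path) {
  tab <- bind_cols(tibble(gene = rownames(homology)),
                   as_tibble(homology))
  readr::write_tsv(tab, path)
  invisible(path)
}

validate_homology <- function(homology) {
  if (!is.matrix(homology) || is.null(rownames(homology)) ||
      is.null(colnames(homology))) {
    abort("homology must be a matrix with gene rownames and strain colnames",
          class = "gemkit_usage_error")
  }
  if (ncol(homology) == 0) {
    abort("homology matrix has no strains", class = "gemkit_usage_error")
  }
  if (any(homology < 0 | homology > 100)) {
    abort("homology values must lie in [0, 100]", class = "gemkit_usage_error")
  }
  invisible(homology)
}

#' Call ortholog presence from percent-identity values
#'
#' @param homology genes x strains matrix of percent identity in `[0, 100]`
#'   (missing data coded as 0).
#' @param primary primary identity threshold (default 70); presence requires
#'   `pct >= primary`.
#' @param relaxed relaxed threshold (default 40) applied to a gene when its
#'   prevalence criterion fires.
#' @param prevalence a gene's threshold drops to `relaxed` when the fraction
#'   of strains with `pct > relaxed` is strictly greater than this value
#'   (default 0.75).
#' @return object of class `presence_matrix`: a logical genes x strains
#'   matrix with attribute `effective_threshold` (named numeric, per gene).
#' @export
call_orthologs <- function(homology, primary = 70, relaxed = 40,
                           prevalence = 0.75) {
  validate_homology(homology)
  over_relaxed_frac <- rowMeans(homology > relaxed)
  eff <- ifelse(over_relaxed_frac > prevalence, relaxed, primary)
  names(eff) <- rownames(homology)
  presence <- sweep(homology, 1, eff, FUN = ">=")
  structure(presence,
            effective_threshold = eff,
            primary = primary, relaxed = relaxed, prevalence = prevalence,
            class = c("presence_matrix", "matrix", "array"))
}

#' Tidy a presence matrix
#'
#' @param x a `presence_matrix` from [call_orthologs()].
#' @param ... unused.
#' @return long tibble: `gene`, `strain`, `present`, `effective_threshold`.
#' @export
tidy.presence_matrix <- function(x, ...) {
  eff <- attr(x, "effective_threshold")
  tibble(
    gene = rep(rownames(x), times = ncol(x)),
    strain = rep(colnames(x), each = nrow(x)),
    present = as.logical(x),
    effective_threshold = rep(unname(eff), times = ncol(x))
  )
}
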