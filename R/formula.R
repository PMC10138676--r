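# Chemical formula handling.
#
# Formulas follow the usual Hill-style grammar: element symbols (one capital
# letter plus optional lower-case letters) each followed by an optional
# integer count, e.g. "C6H12O6", "HO4P". Polymeric or generic group symbols
# ("R", "X", "*") make the composition unknowable, so parsing returns NA and
# downstream balance checks report `unknown_formula` instead of guessing.

#' Parse a chemical formula into element counts
#'
#' @param formula a single formula string such as `"C6H12O6"`. `NA` or `""`
#'   means the composition is unknown.
#' @return a named numeric vector of element counts, or `NULL` when the
#'   formula is missing or cannot be interpreted.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("HO4P")
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || length(formula) != 1 || is.na(formula) ||
      !nzchar(formula)) {
    return(NULL)
  }
  # generic/polymeric groups: composition undefined
  if (grepl("(^|[^A-Za-z])[RX*](?![a-z])", formula, perl = TRUE)) {
    return(NULL)
  }
  tokens <- gregexpr("([A-Z][a-z]*)([0-9]*)", formula, perl = TRUE)[[1]]
  matched <- regmatches(formula, gregexpr("([A-Z][a-z]*)([0-9]*)", formula))[[1]]
  if (length(matched) == 0 ||
      sum(nchar(matched)) != nchar(gsub("\\s", "", formula))) {
    return(NULL)  # unparseable residue
  }
  el <- sub("[0-9]*$", "", matched)
  cnt <- sub("^[A-Za-z]+", "", matched)
  cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
  out <- tapply(cnt, el, sum)
  stats::setNames(as.numeric(out), names(out))
}

# add scaled element counts into an accumulator (named numeric vectors)
add_elements <- function(acc, counts, coef) {
  if (is.null(counts)) return(acc)
  for (el in names(counts)) {
    acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) + coef * counts[[el]]
  }
  acc
}

# number of carbon atoms in a formula, NA when unknown
formula_carbons <- function(formula) {
  counts <- parse_formula(formula)
  if (is.null(counts)) return(NA_real_)
  if ("C" %in% names(counts)) counts[["C"]] else 0
}
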