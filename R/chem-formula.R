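#' Parse a Hill-notation elemental formula
#'
#' Converts a formula string such as `"C16H48O8Si8"` into a named integer
#' vector of element counts (class `elemental_formula`). Element symbols must
#' be present in the packaged isotope abundance table (see [isotope_table()]).
#'
#' @param text Formula string: element symbols each followed by an optional
#'   positive integer count, e.g. `"C2H6O"`.
#' @return An `elemental_formula`: named integer vector of counts, in
#'   canonical Hill order (C, H, then other elements alphabetically).
#' @examples
#' parse_formula("C2H6O")
#' parse_formula("C17H18ClN3O")  # Tinuvin 326
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string", call. = FALSE)
  if (grepl("[^A-Za-z0-9]", text))
    stop("formula contains characters outside the element-count grammar: ",
         sQuote(text), call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("formula does not match the element-count grammar: ", sQuote(text),
         call. = FALSE)
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  known <- unique(isotope_table()$element)
  bad <- setdiff(elems, known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  ef <- as.integer(counts)
  names(ef) <- names(counts)
  new_elemental_formula(ef)
}

new_elemental_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (length(counts) == 0L || all(counts <= 0L))
    stop("formula must contain at least one element with count >= 1",
         call. = FALSE)
  if (any(counts < 0L))
    stop("negative element count in formula: ",
         paste(names(counts)[counts < 0L], collapse = ", "), call. = FALSE)
  counts <- counts[hill_order(names(counts))]
  structure(counts, class = "elemental_formula")
}

#' Coerce to an elemental formula
#'
#' @param x A formula string, a named numeric vector of element counts, or an
#'   `elemental_formula`.
#' @return An `elemental_formula`.
#' @export
as_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    stopifnot(all(x == round(x)))
    v <- as.integer(x); names(v) <- names(x)
    return(new_elemental_formula(v))
  }
  stop("cannot interpret object as an elemental formula", call. = FALSE)
}

hill_order <- function(elems) {
  if ("C" %in% elems) {
    rest <- setdiff(elems, c("C", "H"))
    match(c("C", intersect("H", elems), sort(rest)), elems)
  } else {
    order(elems)
  }
}

#' @export
format.elemental_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format(x), "\n")
  invisible(x)
}

# signed element-count addition; `b` may carry negative counts (adduct deltas)
formula_add <- function(a, b) {
  elems <- union(names(a), names(b))
  v <- integer(length(elems)); names(v) <- elems
  v[names(a)] <- v[names(a)] + as.integer(a)
  v[names(b)] <- v[names(b)] + as.integer(b)
  if (any(v < 0L))
    stop("adduct would remove more atoms than present: ",
         paste(names(v)[v < 0L], collapse = ", "), call. = FALSE)
  new_elemental_formula(v)
}

formula_multiply <- function(a, n) {
  stopifnot(n >= 1L)
  v <- as.integer(a) * as.integer(n); names(v) <- names(a)
  new_elemental_formula(v)
}

#' Total atom count of a formula
#' @param f An `elemental_formula` (or anything [as_formula()] accepts).
#' @return Integer atom count.
#' @export
atom_count <- function(f) sum(as.integer(as_formula(f)))
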