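#' Packaged isotope abundance table
#'
#' Natural isotopic compositions (IUPAC/CIAAW 2021 representative values) for
#' the elements commonly encountered in extractables screening and in
#' electrospray adducts. Shipped as a plain-text file under
#' `inst/extdata/isotope_abundances_iupac2021.tsv`.
#'
#' @return A data frame with columns `element`, `mass_number`, `exact_mass`
#'   (Da), `abundance` (fraction), and `shift` (nominal mass offset from the
#'   element's lightest isotope).
#' @export
isotope_table <- function() {
  tab <- get0(".isotope_table_cache", envir = .rrfkit_cache)
  if (!is.null(tab)) return(tab)
  path <- system.file("extdata", "isotope_abundances_iupac2021.tsv",
                      package = "rrfkit", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$shift <- tab$mass_number -
    stats::ave(tab$mass_number, tab$element, FUN = min)
  bad <- tapply(tab$abundance, tab$element, function(a) abs(sum(a) - 1) > 1e-9)
  if (any(bad))
    stop("isotope abundances do not sum to 1 for: ",
         paste(names(bad)[bad], collapse = ", "))
  assign(".isotope_table_cache", tab, envir = .rrfkit_cache)
  tab
}

.rrfkit_cache <- new.env(parent = emptyenv())

# physical constants (CODATA), Da
ELECTRON_MASS <- 0.000548579909
PROTON_MASS <- 1.007276466621

# distribution of integer mass shifts for a single atom of `element`
single_atom_dist <- function(element) {
  tab <- isotope_table()
  rows <- tab[tab$element == element, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("element absent from the isotope table: ", element, call. = FALSE)
  d <- numeric(max(rows$shift) + 1L)
  d[rows$shift + 1L] <- rows$abundance
  d
}

# direct open convolution; envelopes are short, so O(n*m) beats FFT round-off
conv_open <- function(a, b) {
  if (length(b) > length(a)) { tmp <- a; a <- b; b <- tmp }
  out <- numeric(length(a) + length(b) - 1L)
  for (j in seq_along(b)) {
    idx <- j:(j + length(a) - 1L)
    out[idx] <- out[idx] + b[j] * a
  }
  out
}

# n-fold self-convolution by binary exponentiation
convolve_power <- function(d, n) {
  out <- 1
  base <- d
  while (n > 0L) {
    if (n %% 2L == 1L) out <- conv_open(out, base)
    base <- conv_open(base, base)
    n <- n %/% 2L
  }
  out
}

#' Isotopologue distribution of a formula
#'
#' Computes the isotope-envelope abundances of a neutral or ionic formula,
#' aggregated by integer mass shift from the monoisotopic peak (nominal-mass
#' isotopologues, not exact-mass fine structure). The distribution is the
#' convolution of each element's single-atom isotope distribution, taken to
#' the power of its atom count.
#'
#' @param f Formula (string, named counts, or `elemental_formula`).
#' @param prune_threshold Peaks with abundance below this fraction are dropped
#'   from the returned envelope (after the full convolution; the retained
#'   abundances are not renormalized). Must lie in `[0, 1e-3]`.
#' @return An `isotopologue_distribution`: data frame with columns `shift`
#'   (integer Da from monoisotopic) and `abundance`, ordered by shift, plus a
#'   `prune_threshold` attribute. The first row is the monoisotopic peak.
#' @examples
#' isotopologue_distribution("Cl2")          # chlorine doublet pattern
#' isotopologue_distribution("C16H48O8Si8")  # D8 siloxane: monoisotopic < 0.5
#' @export
isotopologue_distribution <- function(f, prune_threshold = 1e-10) {
  if (!is.numeric(prune_threshold) || length(prune_threshold) != 1L ||
      prune_threshold < 0 || prune_threshold > 1e-3)
    stop("prune_threshold must be a single value in [0, 1e-3]", call. = FALSE)
  f <- as_formula(f)
  d <- 1
  for (i in seq_along(f)) {
    ed <- convolve_power(single_atom_dist(names(f)[i]), as.integer(f[i]))
    d <- conv_open(d, ed)
  }
  keep <- d >= prune_threshold & d > 0  # unreachable shifts carry no peak
  keep[1L] <- TRUE  # monoisotopic peak always retained
  out <- data.frame(shift = which(keep) - 1L, abundance = d[keep])
  structure(out, class = c("isotopologue_distribution", "data.frame"),
            prune_threshold = prune_threshold)
}

#' Monoisotopic fraction of a formula
#'
#' Fraction of a compound's total ion envelope carried by its monoisotopic
#' peak (all atoms as the lightest isotope). This is the share of response an
#' extracted ion chromatogram drawn on the monoisotopic ion captures, relative
#' to the full extracted compound chromatogram; it shrinks with carbon count
#' and sharply with Si, Cl, or Br content.
#'
#' @inheritParams isotopologue_distribution
#' @return Fraction in (0, 1].
#' @examples
#' monoisotopic_fraction("C16H48O8Si8") # < 0.5: a monoisotopic EIC loses half
#' @export
monoisotopic_fraction <- function(f) {
  f <- as_formula(f)
  tab <- isotope_table()
  mono <- tab[tab$shift == 0L, ]
  ab <- mono$abundance[match(names(f), mono$element)]
  prod(ab ^ as.numeric(f))
}

#' Monoisotopic mass of a formula
#'
#' @inheritParams isotopologue_distribution
#' @return Mass in Da (sum of lightest-isotope exact masses).
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  tab <- isotope_table()
  mono <- tab[tab$shift == 0L, ]
  m <- mono$exact_mass[match(names(f), mono$element)]
  if (anyNA(m))
    stop("element absent from the isotope table: ",
         paste(names(f)[is.na(m)], collapse = ", "), call. = FALSE)
  sum(m * as.numeric(f))
}
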