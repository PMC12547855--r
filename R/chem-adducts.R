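# named neutral species that appear in ESI adduct labels
ADDUCT_COMPONENTS <- list(
  H    = c(H = 1L),
  NH4  = c(N = 1L, H = 4L),
  Na   = c(Na = 1L),
  K    = c(K = 1L),
  ACN  = c(C = 2L, H = 3L, N = 1L),         # acetonitrile
  Cl   = c(Cl = 1L),
  HCOO = c(C = 1L, H = 1L, O = 2L),         # formate
  CH3  = c(C = 1L, H = 3L),
  H2O  = c(H = 2L, O = 1L),
  NH3  = c(N = 1L, H = 3L)
)

#' Parse an ESI adduct label
#'
#' Understands the usual bracket notation: `[M+H]+`, `[M+NH4]+`, `[2M+Na]+`,
#' `[M-H]-`, `[M+Cl]-`, `[M+ACN+NH4]+`, `[M+2H]2+`, `[3M+K]+`, ... A label is
#' a multimer count on `M`, signed component terms (each an optional count
#' followed by a known species name), and a trailing charge.
#'
#' @param label Adduct label string.
#' @return An `adduct_spec`: list with `label`, `delta` (signed element
#'   counts), `charge` (nonzero integer), `multimer` (positive integer).
#' @examples
#' parse_adduct("[2M+Na]+")
#' parse_adduct("[M+ACN+NH4]+")
#' @export
parse_adduct <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  lab <- gsub("−", "-", label)  # minus sign -> hyphen
  m <- regmatches(lab, regexec("^\\[([0-9]*)M((?:[+-][0-9]*[A-Za-z0-9]+)*)\\]([0-9]*)([+-])$", lab))[[1]]
  if (length(m) == 0L)
    stop("cannot parse adduct label: ", sQuote(label), call. = FALSE)
  multimer <- if (nzchar(m[2])) as.integer(m[2]) else 1L
  zmag <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  charge <- if (m[5] == "+") zmag else -zmag
  delta <- integer(0)
  terms <- m[3]
  if (nzchar(terms)) {
    tm <- gregexpr("[+-][0-9]*[A-Za-z0-9]+", terms)[[1]]
    for (tok in regmatches(terms, list(tm))[[1]]) {
      sgn <- if (substr(tok, 1, 1) == "+") 1L else -1L
      body <- substring(tok, 2)
      cnt <- 1L
      cm <- regmatches(body, regexec("^([0-9]+)(.*)$", body))[[1]]
      if (length(cm)) { cnt <- as.integer(cm[2]); body <- cm[3] }
      comp <- ADDUCT_COMPONENTS[[body]]
      if (is.null(comp))
        stop("unknown adduct component ", sQuote(body), " in ", sQuote(label),
             call. = FALSE)
      add <- comp * (sgn * cnt)
      elems <- union(names(delta), names(add))
      v <- integer(length(elems)); names(v) <- elems
      v[names(delta)] <- v[names(delta)] + delta
      v[names(add)] <- v[names(add)] + add
      delta <- v
    }
  }
  structure(list(label = label, delta = delta, charge = charge,
                 multimer = multimer),
            class = "adduct_spec")
}

#' @export
format.adduct_spec <- function(x, ...) x$label

#' @export
print.adduct_spec <- function(x, ...) {
  cat("<adduct>", x$label, " charge", x$charge, " multimer", x$multimer, "\n")
  invisible(x)
}

#' Apply an adduct to a neutral formula
#'
#' Builds the ion species for a neutral molecule under a given adduct:
#' multimerizes the formula, applies the signed element delta, and records the
#' charge.
#'
#' @param f Neutral formula (string, named counts, or `elemental_formula`).
#' @param adduct An `adduct_spec` or adduct label string.
#' @return An `ion_species`: list with `formula` (`elemental_formula` of the
#'   ion), `charge`, and `adduct`.
#' @examples
#' apply_adduct("C2H6O", "[M+H]+")
#' apply_adduct("C2H6O", "[2M+Na]+")
#' @export
apply_adduct <- function(f, adduct) {
  f <- as_formula(f)
  if (is.character(adduct)) adduct <- parse_adduct(adduct)
  stopifnot(inherits(adduct, "adduct_spec"))
  ion <- formula_multiply(f, adduct$multimer)
  if (length(adduct$delta)) ion <- formula_add(ion, adduct$delta)
  structure(list(formula = ion, charge = adduct$charge, adduct = adduct),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat("<ion>", format(x$formula), " charge", x$charge,
      " m/z", format(ion_mz(x), digits = 9), "\n")
  invisible(x)
}

#' m/z of an ion species
#'
#' Monoisotopic m/z including the electron mass correction:
#' `(M_mono - z * m_e) / |z|`.
#'
#' @param ion An `ion_species` from [apply_adduct()].
#' @param isotope_shift Integer nominal mass shift from the monoisotopic peak
#'   (adds `shift * 1.00336` Da, the carbon-13 spacing, as a nominal
#'   placement; envelope abundances come from [isotopologue_distribution()]).
#' @return m/z in Th.
#' @export
ion_mz <- function(ion, isotope_shift = 0L) {
  stopifnot(inherits(ion, "ion_species"))
  m <- monoisotopic_mass(ion$formula) + 1.00335483507 * isotope_shift
  (m - ion$charge * ELECTRON_MASS) / abs(ion$charge)
}
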