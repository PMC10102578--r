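#' Monoisotopic element masses used throughout the package
#'
#' IUPAC monoisotopic masses (u) for the elements supported by the formula
#' parser, plus the electron mass. The proton mass is defined as H minus an
#' electron so that charge bookkeeping is exact.
#'
#' @return Named numeric vector of masses in u. Names are element symbols,
#'   `"C13"` is the heavy carbon isotope, `"e"` the electron and `"proton"`
#'   the H+ ion.
#' @export
element_masses <- function() {
  m <- c(
    H   = 1.0078250319,
    C   = 12,
    C13 = 13.0033548,
    N   = 14.0030740,
    O   = 15.9949146,
    S   = 31.9720707,
    Na  = 22.9897693,
    e   = 0.0005485799
  )
  c(m, proton = unname(m["H"] - m["e"]))
}

# mass deltas (u) for common neutral gains/losses and the 13C spacing
.mass_deltas <- function() {
  m <- element_masses()
  c(
    C13   = unname(m["C13"] - m["C"]),     # 1.0033548
    H2O   = unname(2 * m["H"] + m["O"]),   # 18.010565
    NH3   = unname(m["N"] + 3 * m["H"]),   # 17.026549
    CO    = unname(m["C"] + m["O"]),       # 27.994915
    CO2   = unname(m["C"] + 2 * m["O"]),   # 43.989830
    HCOOH = unname(2 * m["H"] + m["C"] + 2 * m["O"])  # 46.005480
  )
}

#' Parse a molecular formula into element counts
#'
#' Supports the elements C, H, N, O, S, Na plus a single heavy-carbon marker
#' written either as a `(13C)` group (as printed in annotation tables, e.g.
#' `"C5(13C)H10O4"`) or as `"[13C]"`.
#'
#' @param formula Character scalar, e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts (names as in
#'   [element_masses()], heavy carbon as `"C13"`).
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  f <- formula
  counts <- c(H = 0L, C = 0L, C13 = 0L, N = 0L, O = 0L, S = 0L, Na = 0L)
  # heavy-carbon markers
  for (pat in c("\\((13)C(\\d*)\\)", "\\[13C(\\d*)\\]")) {
    mt <- regmatches(f, regexec(pat, f))[[1]]
    if (length(mt)) {
      k <- mt[length(mt)]
      counts["C13"] <- counts["C13"] + if (nzchar(k)) as.integer(k) else 1L
      f <- sub(pat, "", f)
    }
  }
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)(\\d*)", f))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != f)
    stop("cannot parse formula: ", formula)
  for (tk in toks) {
    el <- sub("\\d+$", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(counts)) stop("unknown element '", el, "' in ", formula)
    counts[el] <- counts[el] + n
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' @inheritParams parse_formula
#' @return Neutral monoisotopic mass in u.
#' @examples
#' monoisotopic_mass("C5H8O4")  # glutaric acid, 132.042259
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  m <- element_masses()
  sum(counts * m[names(counts)])
}

#' Adduct and in-source loss rules for singly charged breath ions
#'
#' Each rule maps a neutral molecule M to an observed ion via a fixed mass
#' delta that includes the proton gained or lost (and therefore the electron).
#' The set covers the ionisation forms observed for breath metabolites in
#' positive and negative SESI mode.
#'
#' @return data.frame with columns `name`, `polarity` (`"pos"`/`"neg"`) and
#'   `mass_delta` (u, signed, applied to the neutral monoisotopic mass).
#' @export
adduct_rules <- function() {
  m <- element_masses()
  d <- .mass_deltas()
  pr <- unname(m["proton"])
  rules <- list(
    list("[M+H]+",        "pos",  pr),
    list("[M+H2O+H]+",    "pos",  d[["H2O"]] + pr),
    list("[M-H2O+H]+",    "pos", -d[["H2O"]] + pr),
    list("[M+NH4]+",      "pos",  d[["NH3"]] + pr),
    list("[M-CO+H]+",     "pos", -d[["CO"]] + pr),
    list("[M-CO2+H]+",    "pos", -d[["CO2"]] + pr),
    list("[M-NH3+H]+",    "pos", -d[["NH3"]] + pr),
    list("[M-HCOOH+H]+",  "pos", -d[["HCOOH"]] + pr),
    list("[M-H]-",        "neg", -pr),
    list("[M-H2O-H]-",    "neg", -d[["H2O"]] - pr),
    list("[M+HCOO]-",     "neg",  d[["HCOOH"]] - pr),
    list("[M(C13)-H]-",   "neg",  d[["C13"]] - pr)
  )
  data.frame(
    name = vapply(rules, `[[`, "", 1L),
    polarity = vapply(rules, `[[`, "", 2L),
    mass_delta = vapply(rules, `[[`, 0, 3L),
    stringsAsFactors = FALSE
  )
}

# normalise the spacing variants used in printed tables: "[M + H2O + H]+"
.canon_adduct <- function(name) gsub("[[:space:]]", "", name)

.adduct_delta <- function(adduct) {
  rules <- adduct_rules()
  i <- match(.canon_adduct(adduct), rules$name)
  if (is.na(i)) stop("unknown adduct rule: ", adduct)
  rules$mass_delta[i]
}

#' Theoretical m/z of a formula under an adduct rule
#'
#' Neutral monoisotopic mass plus the rule's signed delta (which carries the
#' proton/electron bookkeeping); charge magnitude is 1 for all rules.
#'
#' @param formula Molecular formula of the neutral molecule.
#' @param adduct Adduct rule name, e.g. `"[M-H]-"` (spaces tolerated).
#' @return Theoretical m/z in Th.
#' @export
theoretical_mz <- function(formula, adduct) {
  monoisotopic_mass(formula) + .adduct_delta(adduct)
}

#' Mass error of a measured m/z in parts per million
#'
#' `(measured - theoretical) / theoretical * 1e6`, the convention used for
#' the annotation tables' printed mass errors.
#'
#' @param measured_mz Measured m/z (Th).
#' @inheritParams theoretical_mz
#' @return Signed ppm error.
#' @examples
#' ppm_error(131.035, "C5H8O4", "[M-H]-")  # ~0.1 ppm
#' @export
ppm_error <- function(measured_mz, formula, adduct) {
  theo <- theoretical_mz(formula, adduct)
  (measured_mz - theo) / theo * 1e6
}
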