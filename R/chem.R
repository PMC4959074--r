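# Elemental masses and ion chemistry shared by the simulator and the annotator.

# Monoisotopic atomic masses (Da).  "[37Cl]" is the heavy chlorine isotope
# used by the [M+37Cl]- adduct.
.ATOMIC_MASS <- c(
  C    = 12,
  H    = 1.0078250319,
  N    = 14.0030740052,
  O    = 15.9949146221,
  P    = 30.97376151,
  S    = 31.97207069,
  Na   = 22.98976928,
  K    = 38.9637069,
  Cl   = 34.96885271,
  "[37Cl]" = 36.96590260
)

.ELECTRON_MASS <- 0.00054857990
# Mass difference between 13C and 12C; isotopologue spacing is this / |charge|.
.C13_MASS_SHIFT <- 1.0033548378
# Natural abundance of 13C.
.C13_ABUNDANCE <- 0.0107

#' Parse an elemental formula string
#'
#' Supported element tokens: C, H, N, O, P, S, Na, K, Cl and `[37Cl]` (the
#' heavy chlorine isotope).  Counts default to 1.
#'
#' @param formula Character vector of formula strings, e.g. `"C42H82NO8P"`.
#' @return For a single string, a named integer vector of element counts;
#'   for longer input, a list of such vectors.
#' @examples
#' parse_formula("C16H32O2")
#' @export
parse_formula <- function(formula) {
  one <- function(f) {
    stopifnot(is.character(f), length(f) == 1L, !is.na(f))
    if (!nzchar(f)) {
      return(stats::setNames(integer(0), character(0)))
    }
    m <- gregexpr("(\\[37Cl\\]|Cl|Na|C|H|N|O|P|S|K)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f)) {
      stop("cannot parse formula: ", f)
    }
    el <- sub("[0-9]*$", "", tokens)
    n <- as.integer(sub("^.*?([0-9]*)$", "\\1", tokens))
    n[is.na(n)] <- 1L
    counts <- tapply(n, el, sum)
    stats::setNames(as.integer(counts), names(counts))
  }
  if (length(formula) == 1L) one(formula) else lapply(formula, one)
}

#' Format element counts as a formula string
#'
#' Hill order (C, H, then alphabetical); zero counts are dropped.
#'
#' @param counts Named integer vector of element counts.
#' @return A formula string.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  els <- names(counts)
  ord <- c(
    intersect(c("C", "H"), els),
    sort(setdiff(els, c("C", "H")))
  )
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula Formula string(s) or a named count vector.
#' @return Monoisotopic mass(es) in Daltons.
#' @examples
#' formula_mass("C16H32O2") # palmitic acid, 256.2402
#' @export
formula_mass <- function(formula) {
  if (is.character(formula)) {
    vapply(formula, function(f) {
      cnt <- parse_formula(f)
      sum(.ATOMIC_MASS[names(cnt)] * cnt)
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    sum(.ATOMIC_MASS[names(formula)] * formula)
  }
}

#' Negative-ion adduct definitions
#'
#' Each adduct is an elemental gain/loss applied to the neutral species plus a
#' charge; the m/z shift is computed from monoisotopic atomic masses and
#' includes the electron mass for the charge carried.
#'
#' @param names Optional character vector selecting a subset by name.
#' @return A data frame with columns `name`, `gain`, `loss`, `charge`,
#'   `shift` (Da; applied to the neutral mass before dividing by |charge|).
#' @examples
#' default_adducts(c("[M-H]-", "[M+OAc]-"))
#' @export
default_adducts <- function(names = NULL) {
  adducts <- data.frame(
    name   = c("[M-H]-", "[M+OAc]-", "[M+Cl]-", "[M+37Cl]-",
               "[M+K-2H]-", "[M+NO3]-", "[M-2H]2-"),
    gain   = c("", "C2H3O2", "Cl", "[37Cl]", "K", "NO3", ""),
    loss   = c("H", "", "", "", "H2", "", "H2"),
    charge = c(-1L, -1L, -1L, -1L, -1L, -1L, -2L),
    stringsAsFactors = FALSE
  )
  mass0 <- function(f) if (nzchar(f)) formula_mass(f) else 0
  adducts$shift <- vapply(seq_len(nrow(adducts)), function(i) {
    mass0(adducts$gain[i]) - mass0(adducts$loss[i]) +
      abs(adducts$charge[i]) * .ELECTRON_MASS
  }, numeric(1))
  if (!is.null(names)) {
    missing <- setdiff(names, adducts$name)
    if (length(missing)) stop("unknown adduct(s): ", paste(missing, collapse = ", "))
    adducts <- adducts[match(names, adducts$name), , drop = FALSE]
    rownames(adducts) <- NULL
  }
  adducts
}

#' Theoretical m/z of an ionized lipid
#'
#' `m/z = (monoisotopic mass + adduct shift) / |charge|`, with the adduct
#' shift including the electron mass.
#'
#' @param mono_mass Neutral monoisotopic mass(es) in Da.
#' @param adduct A single row of [default_adducts()] or an adduct name.
#' @return Theoretical m/z value(s).
#' @examples
#' theoretical_mz(formula_mass("C16H32O2"), "[M-H]-") # 255.2330
#' @export
theoretical_mz <- function(mono_mass, adduct) {
  if (is.character(adduct)) adduct <- default_adducts(adduct)
  stopifnot(nrow(adduct) == 1L)
  (mono_mass + adduct$shift) / abs(adduct$charge)
}

#' Sum-composition shorthand name
#'
#' Lipids are named by class plus total acyl carbons:double bonds, with the
#' ion form appended, e.g. `"Cer 36:1 [M+OAc]-"`.
#'
#' @param class_name Lipid class label.
#' @param carbons Total acyl/alkyl carbons.
#' @param double_bonds Total double bonds.
#' @param adduct_name Optional adduct name to append.
#' @return Character vector of names.
#' @export
shorthand <- function(class_name, carbons, double_bonds, adduct_name = NULL) {
  base <- paste0(class_name, " ", carbons, ":", double_bonds)
  if (is.null(adduct_name)) base else paste(base, adduct_name)
}

# parts-per-million difference of observed vs theoretical m/z
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
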