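# Ground-truth multiplicative effects applied by the synthetic study
# generator: per-class factors per infected group, with species overrides.

#' Default ground-truth class effects
#'
#' Multiplicative abundance factors (`1 + percent change / 100`) applied to
#' each lipid class in the two Wolbachia-infected groups relative to the
#' uninfected control (whose factor is exactly 1): ceramides 0.38/0.80
#' (wMel/wMelPop), HexCer 0.68/1.05, SM 0.65/1.28, PC 0.62/0.96,
#' PE 1.02/1.02, PI 1.94/1.27, PG 1.50/1.17, DG 0.68/1.17.  Species-level
#' overrides: DG 34:1 0.35/1.42, LacCer 40:1 0.19/0.49, LacCer 34:1 and
#' 36:1 raised 1.52/1.90-fold in wMel.  PE-Cer (0.60/0.85) and the LacCer
#' class default (0.80/0.90) are stand-ins: those classes decrease without a
#' published class mean.  Classes not listed (PS, LPC, LPE, background) are
#' unchanged.
#'
#' @return An object of class `effect_config`: a list with elements
#'   `class_factors` (data frame `class_name`, `wMel`, `wMelPop`) and
#'   `overrides` (data frame `class_name`, `carbons`, `double_bonds`,
#'   `wMel`, `wMelPop`).
#' @examples
#' eff <- default_effects()
#' subset(eff$class_factors, class_name == "Cer")
#' @export
default_effects <- function() {
  class_factors <- data.frame(
    class_name = c("Cer", "HexCer", "SM", "PC", "PE", "PI", "PG", "DG",
                   "PE-Cer", "LacCer"),
    wMel    = c(0.38, 0.68, 0.65, 0.62, 1.02, 1.94, 1.50, 0.68, 0.60, 0.80),
    wMelPop = c(0.80, 1.05, 1.28, 0.96, 1.02, 1.27, 1.17, 1.17, 0.85, 0.90),
    stringsAsFactors = FALSE
  )
  overrides <- data.frame(
    class_name   = c("DG", "LacCer", "LacCer", "LacCer"),
    carbons      = c(34L, 40L, 34L, 36L),
    double_bonds = c(1L, 1L, 1L, 1L),
    wMel    = c(0.35, 0.19, 1.52, 1.90),
    wMelPop = c(1.42, 0.49, 1.00, 1.00),
    stringsAsFactors = FALSE
  )
  effect_config(class_factors, overrides)
}

#' Construct an effect configuration
#'
#' @param class_factors Data frame with `class_name` and one column of
#'   positive multiplicative factors per non-control group.
#' @param overrides Optional data frame of species-level factors keyed by
#'   (`class_name`, `carbons`, `double_bonds`).
#' @return An `effect_config` object.
#' @export
effect_config <- function(class_factors, overrides = NULL) {
  groups <- setdiff(names(class_factors), "class_name")
  stopifnot(length(groups) >= 1)
  for (g in groups) {
    if (any(class_factors[[g]] <= 0)) stop("effect factors must be > 0")
  }
  if (!is.null(overrides) && nrow(overrides)) {
    for (g in intersect(groups, names(overrides))) {
      if (any(overrides[[g]] <= 0)) stop("effect factors must be > 0")
    }
  }
  structure(list(class_factors = class_factors, overrides = overrides,
                 groups = groups),
            class = "effect_config")
}

#' Null effects (no group differences)
#'
#' @param groups Names of the non-control groups.
#' @return An `effect_config` with every factor equal to 1.
#' @export
null_effects <- function(groups = c("wMel", "wMelPop")) {
  cf <- data.frame(class_name = character(0), stringsAsFactors = FALSE)
  for (g in groups) cf[[g]] <- numeric(0)
  effect_config(cf)
}

#' Look up effect factors for species
#'
#' Vectorized over species; the control group always returns 1, unlisted
#' classes return 1, and species overrides take precedence over class
#' factors.
#'
#' @param effects An `effect_config`.
#' @param class_name,carbons,double_bonds Species descriptors (vectors).
#' @param group Single group name (e.g. `"control"`, `"wMel"`).
#' @return Numeric vector of multiplicative factors.
#' @export
effect_factor <- function(effects, class_name, carbons, double_bonds, group) {
  stopifnot(inherits(effects, "effect_config"), length(group) == 1L)
  n <- length(class_name)
  if (group == "control" || !(group %in% effects$groups)) return(rep(1, n))
  f <- rep(1, n)
  cf <- effects$class_factors
  idx <- match(class_name, cf$class_name)
  hit <- !is.na(idx)
  f[hit] <- cf[[group]][idx[hit]]
  ov <- effects$overrides
  if (!is.null(ov) && nrow(ov)) {
    key <- paste(class_name, carbons, double_bonds)
    okey <- paste(ov$class_name, ov$carbons, ov$double_bonds)
    oidx <- match(key, okey)
    ohit <- !is.na(oidx)
    f[ohit] <- ov[[group]][oidx[ohit]]
  }
  f
}
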