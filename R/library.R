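# The bundled lipid library: sum-composition species used both to simulate
# synthetic studies and as the annotation reference.

# Elemental composition of a sum-composition species.  `carbons` counts the
# acyl/alkyl (and sphingoid) carbons only; headgroup atoms are added per class.
.CLASS_FORMULA <- list(
  "FA-background" = function(c, d) c(C = c,      H = 2 * c - 2 * d,      O = 2),
  DG       = function(c, d) c(C = c + 3L,  H = 2 * c + 4 - 2 * d,  O = 5),
  PC       = function(c, d) c(C = c + 8L,  H = 2 * c + 16 - 2 * d, N = 1, O = 8,  P = 1),
  LPC      = function(c, d) c(C = c + 8L,  H = 2 * c + 18 - 2 * d, N = 1, O = 7,  P = 1),
  PE       = function(c, d) c(C = c + 5L,  H = 2 * c + 10 - 2 * d, N = 1, O = 8,  P = 1),
  LPE      = function(c, d) c(C = c + 5L,  H = 2 * c + 12 - 2 * d, N = 1, O = 7,  P = 1),
  PS       = function(c, d) c(C = c + 6L,  H = 2 * c + 10 - 2 * d, N = 1, O = 10, P = 1),
  PG       = function(c, d) c(C = c + 6L,  H = 2 * c + 11 - 2 * d, O = 10, P = 1),
  PI       = function(c, d) c(C = c + 9L,  H = 2 * c + 15 - 2 * d, O = 13, P = 1),
  Cer      = function(c, d) c(C = c,       H = 2 * c + 1 - 2 * d,  N = 1, O = 3),
  HexCer   = function(c, d) c(C = c + 6L,  H = 2 * c + 11 - 2 * d, N = 1, O = 8),
  LacCer   = function(c, d) c(C = c + 12L, H = 2 * c + 21 - 2 * d, N = 1, O = 13),
  SM       = function(c, d) c(C = c + 5L,  H = 2 * c + 13 - 2 * d, N = 2, O = 6,  P = 1),
  "PE-Cer" = function(c, d) c(C = c + 2L,  H = 2 * c + 7 - 2 * d,  N = 2, O = 6,  P = 1)
)

# Primary (quantifier) ion per class, following negative-mode practice:
# acetate adducts for choline-containing and neutral classes, deprotonation
# otherwise.
.CLASS_PRIMARY_ADDUCT <- c(
  Cer = "[M+OAc]-", SM = "[M+OAc]-", DG = "[M+OAc]-", PC = "[M+OAc]-",
  LPC = "[M+OAc]-", HexCer = "[M-H]-", LacCer = "[M-H]-", "PE-Cer" = "[M-H]-",
  PE = "[M-H]-", LPE = "[M-H]-", PS = "[M-H]-", PG = "[M-H]-", PI = "[M-H]-",
  "FA-background" = "[M-H]-"
)

# Typical base intensities (arbitrary units).  PE carries the most intense
# ions and PG the second most; background sits low.
.CLASS_BASE_ABUNDANCE <- c(
  PE = 6e6, PG = 4e6, Cer = 2.5e6, PC = 2.5e6, PI = 2e6, HexCer = 1.5e6,
  "PE-Cer" = 1.5e6, DG = 1.5e6, SM = 1.2e6, LacCer = 1e6, PS = 1e6,
  LPC = 8e5, LPE = 8e5, "FA-background" = 6e5
)

.lipid_formula <- function(class_name, carbons, double_bonds) {
  fun <- .CLASS_FORMULA[[class_name]]
  if (is.null(fun)) stop("unknown lipid class: ", class_name)
  counts <- fun(as.integer(carbons), as.integer(double_bonds))
  counts[counts != 0]
}

# first n species of an ordered (carbons, double_bonds) grid
.species_grid <- function(class_name, n, carbons, double_bonds) {
  g <- expand.grid(double_bonds = double_bonds, carbons = carbons)
  g <- g[order(g$carbons, g$double_bonds), c("carbons", "double_bonds")]
  if (nrow(g) < n) stop("grid too small for class ", class_name)
  g <- g[seq_len(n), , drop = FALSE]
  data.frame(class_name = class_name, g, row.names = NULL,
             stringsAsFactors = FALSE)
}

# cache for the default library (built once per session)
.lipidpipe_cache <- new.env(parent = emptyenv())

# run code with a private, deterministic RNG stream, restoring the caller's
.with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bundled lipid library
#'
#' Builds the sum-composition species library used for simulation and
#' annotation: 13 annotated lipid classes with species counts matching an
#' FT-ICR negative-mode cell-line lipidome (Cer 57, HexCer 29, LacCer 14,
#' SM 12, PE-Cer 16, PC 53, LPC 11, PE 81, LPE 9, PS 12, PI 59, PG 40,
#' DG 29), plus a large panel of unchanged background species
#' (saturated free fatty acids and synthetic unknown-formula compounds)
#' that anchors probabilistic quotient normalization.  The library is
#' deterministic: repeated calls return identical tables.
#'
#' @param n_background Number of synthetic unknown background species in
#'   addition to the saturated free fatty acids (default 3000).
#' @return A data frame with one row per species: `species_id`, `class_name`,
#'   `carbons`, `double_bonds`, `formula`, `mono_mass`, `base_abundance`,
#'   `primary_adduct`, `blank_level` (relative intensity in solvent blanks).
#' @examples
#' lib <- default_library(n_background = 50)
#' subset(lib, class_name == "Cer" & carbons == 36 & double_bonds == 1)
#' @export
default_library <- function(n_background = 3000) {
  key <- paste0("library_", n_background)
  if (!is.null(.lipidpipe_cache[[key]])) return(.lipidpipe_cache[[key]])

  grids <- rbind(
    .species_grid("Cer",     57, 32:44, 0:4),
    .species_grid("HexCer",  29, 32:41, 0:2),
    .species_grid("LacCer",  14, 32:45, 1),
    .species_grid("SM",      12, 33:38, 0:1),
    .species_grid("PE-Cer",  16, 34:41, 0:1),
    .species_grid("PC",      53, 30:43, 0:3),
    .species_grid("LPC",     11, 14:19, 0:1),
    .species_grid("PE",      81, 30:43, 0:5),
    .species_grid("LPE",      9, 16:20, 0:1),
    .species_grid("PS",      12, 32:37, 3:4),
    .species_grid("PI",      59, 32:41, 0:5),
    .species_grid("PG",      40, 30:39, 0:3),
    .species_grid("DG",      29, 28:37, 0:2),
    .species_grid("FA-background", 25, 12:36, 0) # saturated solvent FFAs
  )
  # relative intensity in solvent blanks: saturated FFAs are solvent-borne
  # (high enough to fail the 2x blank rule); lipids are absent from blanks
  grids$blank_level <- ifelse(grids$class_name == "FA-background", 0.6, 0)

  lib <- .with_private_seed(1205L, {
    forms <- character(nrow(grids))
    mass <- numeric(nrow(grids))
    for (i in seq_len(nrow(grids))) {
      cnt <- .lipid_formula(grids$class_name[i], grids$carbons[i],
                            grids$double_bonds[i])
      forms[i] <- format_formula(cnt)
      mass[i] <- formula_mass(cnt)
    }
    grids$formula <- forms
    grids$mono_mass <- mass

    # Synthetic unknown background compounds: plausible CHNOP formulae whose
    # [M-H]- ion and its 13C isotopologue stay >= 5 ppm away from every ion
    # the library emits (all adducts, isotopologues and charge states), so
    # the unchanged background never aliases an annotated species.
    grids$species_id <- shorthand(grids$class_name, grids$carbons,
                                  grids$double_bonds)
    grids$primary_adduct <- unname(.CLASS_PRIMARY_ADDUCT[grids$class_name])
    grids$base_abundance <- 1 # placeholder; only ion m/z values are needed
    protected <- .emitted_ions(grids)$theo_mz
    # occupancy bins of 2.5 ppm width in log-m/z; values >= 3 bins apart are
    # >= 5 ppm apart
    h <- 2.5e-6
    bin_of <- function(mz) as.integer(floor(log(mz / 100) / log1p(h)))
    n_bins <- bin_of(1400) + 3L
    occupied <- logical(n_bins)
    occupied[pmin(pmax(bin_of(protected), 1L), n_bins)] <- TRUE

    n_draw <- 4L * n_background
    c_n <- sample(12:70, n_draw, replace = TRUE)
    h_n <- c_n + floor(stats::runif(n_draw) * (c_n + 3))
    n_n <- sample(0:2, n_draw, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    o_n <- sample(2:13, n_draw, replace = TRUE)
    p_n <- sample(0:1, n_draw, replace = TRUE, prob = c(0.85, 0.15))
    m_all <- c_n * .ATOMIC_MASS[["C"]] + h_n * .ATOMIC_MASS[["H"]] +
      n_n * .ATOMIC_MASS[["N"]] + o_n * .ATOMIC_MASS[["O"]] +
      p_n * .ATOMIC_MASS[["P"]]
    mz_all <- theoretical_mz(m_all, default_adducts("[M-H]-"))
    b0 <- bin_of(mz_all)
    b1 <- bin_of(mz_all + .C13_MASS_SHIFT)
    ok <- mz_all >= 130 & mz_all <= 1190
    sel <- integer(0)
    for (i in which(ok)) {
      probe <- c(b0[i] + (-2:2), b1[i] + (-2:2))
      if (any(occupied[probe])) next
      occupied[c(b0[i], b1[i])] <- TRUE
      sel <- c(sel, i)
      if (length(sel) == n_background) break
    }
    if (length(sel) < n_background) stop("background sampling exhausted")
    counts <- cbind(C = c_n[sel], H = h_n[sel], N = n_n[sel], O = o_n[sel],
                    P = p_n[sel])
    bg <- data.frame(
      class_name = "FA-background", carbons = c_n[sel], double_bonds = 0L,
      blank_level = 0.08,
      formula = vapply(seq_along(sel), function(i) {
        format_formula(counts[i, ])
      }, character(1)),
      mono_mass = m_all[sel],
      stringsAsFactors = FALSE
    )
    bg$species_id <- paste0("bg:", bg$formula)
    lib <- rbind(grids[, names(bg)], bg)

    # species-level abundance spread around the class base intensity
    lib$base_abundance <- .CLASS_BASE_ABUNDANCE[lib$class_name] *
      stats::rlnorm(nrow(lib), meanlog = 0, sdlog = 0.7)
    lib
  })

  lib$primary_adduct <- unname(.CLASS_PRIMARY_ADDUCT[lib$class_name])
  rownames(lib) <- NULL
  lib <- lib[, c("species_id", "class_name", "carbons", "double_bonds",
                 "formula", "mono_mass", "base_abundance", "primary_adduct",
                 "blank_level")]
  stopifnot(all(lib$carbons >= lib$double_bonds), all(lib$double_bonds >= 0))
  .lipidpipe_cache[[key]] <- lib
  lib
}
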