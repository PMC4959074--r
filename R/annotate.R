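# Exact-mass annotation against the lipid library: adduct-series matching,
# 13C isotopologue flagging and charge-state detection.

# index ranges of sorted `theo` values within +/- tol_ppm of each mz
.window_match <- function(mz, theo_sorted, tol_ppm) {
  lo <- findInterval(mz * (1 - tol_ppm * 1e-6), theo_sorted) + 1L
  hi <- findInterval(mz * (1 + tol_ppm * 1e-6), theo_sorted)
  list(lo = lo, hi = hi, n = pmax(hi - lo + 1L, 0L))
}

#' Match feature m/z values against the lipid library
#'
#' Every (species, adduct) theoretical m/z within `tol_ppm` of a feature m/z
#' becomes a candidate annotation; features may carry several candidates
#' (isobars are kept and ranked by |ppm error|).  Unmatched features are
#' annotated `"unknown"`.
#'
#' @param mz Feature m/z values (strictly increasing), or a
#'   `feature_matrix`.
#' @param library Species table ([default_library()]).
#' @param adducts Adduct set ([default_adducts()]), or a character vector of
#'   adduct names.
#' @param tol_ppm Symmetric relative tolerance (default 2 ppm).
#' @return Annotation data frame: `feature`, `feature_mz`, `species_id`,
#'   `class_name`, `carbons`, `double_bonds`, `adduct`, `charge`, `iso`
#'   (0 = monoisotopic), `ion_carbons`, `theo_mz`, `ppm`, `primary_adduct`,
#'   `name` (shorthand with ion form), `rank` (1 = best per feature),
#'   `flagged_isotope`, `parent_feature`.
#' @export
match_features <- function(mz, library = default_library(),
                           adducts = default_adducts(), tol_ppm = 2) {
  if (inherits(mz, "feature_matrix")) {
    feature_ids <- rownames(mz$intensity)
    mz <- mz$mz
  } else {
    feature_ids <- sprintf("F%05d", seq_along(mz))
  }
  if (is.character(adducts)) adducts <- default_adducts(adducts)
  stopifnot(nrow(library) > 0L, nrow(adducts) > 0L)
  formula_c <- as.integer(sub("^C([0-9]+).*$", "\\1", library$formula))
  theo <- do.call(rbind, lapply(seq_len(nrow(adducts)), function(ai) {
    ad <- adducts[ai, , drop = FALSE]
    gain_c <- if (nzchar(ad$gain)) {
      cnt <- parse_formula(ad$gain)
      if ("C" %in% names(cnt)) cnt[["C"]] else 0L
    } else 0L
    data.frame(
      sp = seq_len(nrow(library)), adduct = ad$name, charge = ad$charge,
      ion_carbons = formula_c + gain_c,
      theo_mz = theoretical_mz(library$mono_mass, ad),
      stringsAsFactors = FALSE
    )
  }))
  theo <- theo[order(theo$theo_mz), , drop = FALSE]
  w <- .window_match(mz, theo$theo_mz, tol_ppm)
  feat_i <- rep(seq_along(mz), w$n)
  theo_i <- sequence(w$n, from = w$lo)
  sp <- theo$sp[theo_i]
  ann <- data.frame(
    feature = feature_ids[feat_i], feature_mz = mz[feat_i],
    species_id = library$species_id[sp], class_name = library$class_name[sp],
    carbons = library$carbons[sp], double_bonds = library$double_bonds[sp],
    adduct = theo$adduct[theo_i], charge = theo$charge[theo_i],
    iso = rep(0L, length(feat_i)),
    ion_carbons = theo$ion_carbons[theo_i], theo_mz = theo$theo_mz[theo_i],
    ppm = ppm_error(mz[feat_i], theo$theo_mz[theo_i]),
    primary_adduct = library$primary_adduct[sp],
    stringsAsFactors = FALSE
  )
  ann$name <- if (nrow(ann)) {
    shorthand(ann$class_name, ann$carbons, ann$double_bonds, ann$adduct)
  } else {
    character(0)
  }
  unmatched <- setdiff(seq_along(mz), unique(feat_i))
  if (length(unmatched)) {
    ann <- rbind(ann, data.frame(
      feature = feature_ids[unmatched], feature_mz = mz[unmatched],
      species_id = NA_character_, class_name = NA_character_,
      carbons = NA_integer_, double_bonds = NA_integer_,
      adduct = NA_character_, charge = NA_integer_, iso = NA_integer_,
      ion_carbons = NA_integer_, theo_mz = NA_real_, ppm = NA_real_,
      primary_adduct = NA_character_, name = "unknown",
      stringsAsFactors = FALSE
    ))
  }
  ann <- ann[order(match(ann$feature, feature_ids), abs(ann$ppm)), , drop = FALSE]
  ann$rank <- stats::ave(seq_len(nrow(ann)), ann$feature,
                         FUN = seq_along)
  ann$flagged_isotope <- FALSE
  ann$parent_feature <- NA_character_
  rownames(ann) <- NULL
  ann
}

#' Flag 13C isotopologue features
#'
#' For every annotated monoisotopic candidate the feature at
#' `parent m/z + 1.00336 / |charge|` (within tolerance) whose intensity
#' ratio to the parent lies within `ratio_window` times the expected
#' `0.0107 x ion carbon count` is flagged as the 13C1 isotopologue, linked
#' to its parent (nearest-m/z parent if ambiguous) and annotated with the
#' parent's species and adduct at `iso = 1`.  Isotopologues are excluded
#' from class summaries.
#'
#' @param mz Feature m/z values (or a `feature_matrix`).
#' @param intensity Per-feature representative intensity (mean over
#'   biological samples); taken from the `feature_matrix` when given.
#' @param annotations Annotation table from [match_features()].
#' @param tol_ppm Matching tolerance.
#' @param ratio_window Multiplicative acceptance window around the expected
#'   isotope ratio (default `c(0.25, 1.75)`).
#' @return The updated annotation table.
#' @export
flag_isotopes <- function(mz, intensity = NULL, annotations,
                          tol_ppm = 2, ratio_window = c(0.25, 1.75)) {
  if (inherits(mz, "feature_matrix")) {
    fm <- mz
    bio <- fm$samples$role == "biological"
    intensity <- rowMeans(fm$intensity[, bio, drop = FALSE], na.rm = TRUE)
    feature_ids <- rownames(fm$intensity)
    mz <- fm$mz
  } else {
    feature_ids <- unique(annotations$feature)
  }
  stopifnot(!is.unsorted(mz), length(intensity) == length(mz))
  ann <- annotations
  cand <- ann[!is.na(ann$species_id) & ann$iso == 0L, , drop = FALSE]
  if (!nrow(cand)) return(ann)
  pidx <- match(cand$feature, feature_ids)
  iso_mz <- mz[pidx] + .C13_MASS_SHIFT / abs(cand$charge)
  # nearest feature to the expected isotopologue position
  j <- findInterval(iso_mz, mz)
  jlo <- pmax(j, 1L)
  jhi <- pmin(j + 1L, length(mz))
  g <- ifelse(abs(mz[jlo] - iso_mz) <= abs(mz[jhi] - iso_mz), jlo, jhi)
  within <- abs(mz[g] - iso_mz) <= tol_ppm * 1e-6 * iso_mz & g != pidx
  expected <- .C13_ABUNDANCE * cand$ion_carbons
  ratio <- intensity[g] / intensity[pidx]
  pass <- within & is.finite(ratio) &
    ratio >= ratio_window[1] * expected & ratio <= ratio_window[2] * expected
  if (any(pass)) {
    add <- cand[pass, , drop = FALSE]
    gi <- g[pass]
    add$parent_feature <- add$feature
    add$feature <- feature_ids[gi]
    add$feature_mz <- mz[gi]
    add$iso <- 1L
    add$theo_mz <- add$theo_mz + .C13_MASS_SHIFT / abs(add$charge)
    add$ppm <- ppm_error(mz[gi], add$theo_mz)
    add$name <- paste0(add$name, " +13C")
    add$flagged_isotope <- TRUE
    add <- add[!duplicated(add[c("feature", "species_id", "adduct")]), ,
               drop = FALSE]
    # a flagged isotopologue is no longer "unknown"
    drop_unknown <- ann$name == "unknown" & ann$feature %in% add$feature
    ann <- rbind(ann[!drop_unknown, , drop = FALSE], add)
    ann <- ann[order(match(ann$feature, feature_ids), ann$iso,
                     abs(ann$ppm)), , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

#' Detect charge states from isotopologue spacing
#'
#' A feature whose flagged 13C isotopologue sits ~0.50168 Da away is doubly
#' charged; a spacing of ~1.00336 Da means singly charged.  Features without
#' an isotopologue default to charge 1.  Doubly charged features are linked
#' to their singly charged partner at `2 m/z + 1.00728` when present.
#'
#' @param mz Feature m/z values (or a `feature_matrix`).
#' @param annotations Annotation table processed by [flag_isotopes()].
#' @param tol_ppm Matching tolerance.
#' @return Data frame per feature: `feature`, `charge`, `partner_feature`
#'   (singly charged partner of a doubly charged ion, or `NA`).
#' @export
detect_charge <- function(mz, annotations, tol_ppm = 2) {
  if (inherits(mz, "feature_matrix")) {
    feature_ids <- rownames(mz$intensity)
    mz <- mz$mz
  } else {
    feature_ids <- unique(annotations$feature)
  }
  charge <- rep(1L, length(mz))
  iso <- annotations[annotations$flagged_isotope, , drop = FALSE]
  if (nrow(iso)) {
    p <- match(iso$parent_feature, feature_ids)
    g <- match(iso$feature, feature_ids)
    spacing <- mz[g] - mz[p]
    tol_da <- tol_ppm * 1e-6 * mz[g]
    z2 <- abs(spacing - .C13_MASS_SHIFT / 2) <= tol_da
    z1 <- abs(spacing - .C13_MASS_SHIFT) <= tol_da
    charge[p[z2]] <- 2L
    charge[g[z2]] <- 2L
    charge[p[z1 & !z2]] <- 1L
  }
  partner <- rep(NA_character_, length(mz))
  dbl <- which(charge == 2L)
  if (length(dbl)) {
    # singly charged partner: 2*(m/z) + mass of one proton
    target <- 2 * mz[dbl] + (.ATOMIC_MASS[["H"]] - .ELECTRON_MASS)
    w <- .window_match(target, mz, tol_ppm)
    hit <- w$n > 0L
    partner[dbl[hit]] <- feature_ids[w$lo[hit]]
  }
  data.frame(feature = feature_ids, charge = charge,
             partner_feature = partner, stringsAsFactors = FALSE)
}

#' Annotate a feature matrix
#'
#' Runs [match_features()], [flag_isotopes()] and [detect_charge()] and
#' merges the detected charge into the annotation table.
#'
#' @param fm A `feature_matrix`.
#' @param library,adducts,tol_ppm Passed through.
#' @return Annotation table with an extra `detected_charge` column.
#' @export
annotate_features <- function(fm, library = default_library(),
                              adducts = default_adducts(), tol_ppm = 2) {
  ann <- match_features(fm, library = library, adducts = adducts,
                        tol_ppm = tol_ppm)
  ann <- flag_isotopes(fm, annotations = ann, tol_ppm = tol_ppm)
  ch <- detect_charge(fm, ann, tol_ppm = tol_ppm)
  ann$detected_charge <- ch$charge[match(ann$feature, ch$feature)]
  ann
}
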