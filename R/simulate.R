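# Synthetic DIMS / LC FT-ICR study generator.

# log-normal with unit mean for a given coefficient of variation
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Ion series emitted per species: primary adduct, a chloride secondary (with
# its 37Cl isotope peak) for annotated lipids, a doubly charged [M-2H]2- form
# for the intense PE/PG classes, and a 13C1 isotopologue for every singly- and
# doubly-charged monoisotopic ion.
.emitted_ions <- function(library) {
  key <- paste0("ions_", nrow(library), "_",
                format(sum(library$mono_mass), digits = 15))
  if (!is.null(.lipidpipe_cache[[key]])) return(.lipidpipe_cache[[key]])
  adds <- default_adducts()
  row_of <- function(name) adds[adds$name == name, , drop = FALSE]
  is_bg <- library$class_name == "FA-background"
  is_dbl <- library$class_name %in% c("PE", "PG")
  # carbon count of the full (neutral) formula, headgroup included; `carbons`
  # in the library counts only chain carbons
  formula_c <- as.integer(sub("^C([0-9]+).*$", "\\1", library$formula))

  pieces <- list()
  add_series <- function(idx, adduct_name, rel, with_iso = TRUE) {
    if (!length(idx)) return()
    ad <- row_of(adduct_name)
    gain_c <- if (nzchar(ad$gain)) {
      cnt <- parse_formula(ad$gain)
      if ("C" %in% names(cnt)) cnt[["C"]] else 0L
    } else 0L
    ion_c <- formula_c[idx] + gain_c
    mz0 <- theoretical_mz(library$mono_mass[idx], ad)
    base <- data.frame(
      species_idx = idx, adduct = adduct_name, charge = ad$charge, iso = 0L,
      rel = rel, ion_carbons = ion_c, theo_mz = mz0, stringsAsFactors = FALSE
    )
    pieces[[length(pieces) + 1L]] <<- base
    if (with_iso) {
      iso <- base
      iso$iso <- 1L
      iso$theo_mz <- mz0 + .C13_MASS_SHIFT / abs(ad$charge)
      iso$rel <- rel * ion_c * .C13_ABUNDANCE / (1 - .C13_ABUNDANCE)
      pieces[[length(pieces) + 1L]] <<- iso
    }
  }

  prim <- split(seq_len(nrow(library)), library$primary_adduct)
  for (a in names(prim)) add_series(prim[[a]], a, rel = 1)
  lip <- which(!is_bg)
  add_series(lip, "[M+Cl]-", rel = 0.15)
  # 37Cl/35Cl natural ratio ~ 0.2424/0.7576; no 13C peak emitted for it
  add_series(lip, "[M+37Cl]-", rel = 0.15 * 0.2424 / 0.7576, with_iso = FALSE)
  add_series(which(is_dbl), "[M-2H]2-", rel = 0.08)

  ions <- do.call(rbind, pieces)
  ions <- ions[order(ions$theo_mz), , drop = FALSE]
  rownames(ions) <- NULL
  .lipidpipe_cache[[key]] <- ions
  ions
}

#' Simulate a synthetic lipidomics study
#'
#' Draws a full acquisition set (biological samples per group, pooled QCs,
#' solvent blanks; technical replicates; SIM windows for DIMS) from the
#' species library under the configured ground-truth effects.  Per biological
#' sample each species' abundance is `base_abundance x group factor x`
#' log-normal biological noise; technical replicates add log-normal technical
#' noise and (DIMS) a per-window gain; each emitted ion's m/z is jittered by
#' a normal ppm error; intensities below the detection limit are censored
#' (peak absent).  QC acquisitions are technical draws around the pooled mean
#' of all biological samples; blanks contain only background species at their
#' `blank_level`.
#'
#' @param design A [study_design()].
#' @param library Species table from [default_library()].
#' @param effects An [effect_config][effect_config()].
#' @return A `lipid_study` list: `design`, `samples`, `manifest`, `peaks`
#'   (named list of per-acquisition peak data frames with columns `mz`,
#'   `intensity`[, `rt`]), `truth` (per emitted ion: species, adduct,
#'   isotopologue, charge, theoretical m/z, true group means and percent
#'   changes), `library`, `effects`.
#' @examples
#' d <- study_design(seed = 1, n_windows = 2, mz_range = c(120, 500))
#' st <- simulate_study(d, default_library(n_background = 20), default_effects())
#' head(st$manifest)
#' @export
simulate_study <- function(design, library = default_library(),
                           effects = default_effects()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)

  groups <- rep(names(design$group_sizes), design$group_sizes)
  bio_ids <- unlist(lapply(names(design$group_sizes), function(g) {
    paste0(g, "_", seq_len(design$group_sizes[[g]]))
  }))
  samples <- data.frame(
    sample_id = c(bio_ids, paste0("QC_", seq_len(design$n_qc)),
                  paste0("blank_", seq_len(design$n_blank))),
    role = c(rep("biological", length(bio_ids)), rep("QC", design$n_qc),
             rep("blank", design$n_blank)),
    group = c(groups, rep("QC", design$n_qc), rep("blank", design$n_blank)),
    stringsAsFactors = FALSE
  )

  n_sp <- nrow(library)
  factors <- vapply(unique(groups), function(g) {
    effect_factor(effects, library$class_name, library$carbons,
                  library$double_bonds, g)
  }, numeric(n_sp))

  # per-(species, biological sample) abundance
  abund <- vapply(seq_along(bio_ids), function(i) {
    library$base_abundance * factors[, groups[i]] *
      .rlnorm_cv(n_sp, design$cv_biological)
  }, numeric(n_sp))
  colnames(abund) <- bio_ids
  qc_mean <- rowMeans(abund)
  blank_mean <- library$base_abundance * library$blank_level

  ions <- .emitted_ions(library)
  n_ion <- nrow(ions)

  # ion -> SIM window assignment (overlap peaks appear in both windows)
  if (design$mode == "DIMS") {
    win <- design$windows
    memb <- lapply(seq_len(nrow(win)), function(w) {
      which(ions$theo_mz >= win$start[w] & ions$theo_mz <= win$end[w])
    })
    ion_idx <- unlist(memb)
    win_idx <- rep(seq_len(nrow(win)), lengths(memb))
  } else {
    ion_idx <- seq_len(n_ion)
    win_idx <- rep(NA_integer_, n_ion)
    rt <- 60 + 540 * (library$mono_mass - min(library$mono_mass)) /
      diff(range(library$mono_mass))
  }

  manifest <- list()
  peaks <- list()
  truth_means <- sapply(colnames(factors), function(g) {
    library$base_abundance[ions$species_idx] * factors[ions$species_idx, g]
  })

  emit <- function(sample_id, role, group, rep_i, abundance) {
    tech <- .rlnorm_cv(n_sp, design$cv_technical)
    ion_int <- (abundance * tech)[ions$species_idx] * ions$rel
    if (design$mode == "DIMS") {
      gains <- .rlnorm_cv(nrow(design$windows), design$cv_window)
      int_all <- ion_int[ion_idx] * gains[win_idx]
      mz_all <- ions$theo_mz[ion_idx] *
        (1 + stats::rnorm(length(ion_idx), 0, design$ppm_sd * 1e-6))
      keep <- int_all > 0 & int_all >= design$detection_limit
      for (w in seq_len(nrow(design$windows))) {
        sel <- which(keep & win_idx == w)
        sel <- sel[order(mz_all[sel])]
        acq <- sprintf("%s_r%d_w%02d", sample_id, rep_i, w)
        peaks[[acq]] <<- data.frame(mz = mz_all[sel], intensity = int_all[sel])
        manifest[[acq]] <<- data.frame(
          acquisition_id = acq, sample_id = sample_id, role = role,
          group = group, replicate = rep_i, window = w,
          stringsAsFactors = FALSE
        )
      }
    } else {
      mz_all <- ions$theo_mz *
        (1 + stats::rnorm(n_ion, 0, design$ppm_sd * 1e-6))
      rt_all <- rt[ions$species_idx] +
        stats::rnorm(n_ion, 0, design$rt_sd)
      keep <- ion_int > 0 & ion_int >= design$detection_limit
      sel <- which(keep)[order(mz_all[keep])]
      acq <- sprintf("%s_r%d", sample_id, rep_i)
      peaks[[acq]] <<- data.frame(mz = mz_all[sel], intensity = ion_int[sel],
                                  rt = rt_all[sel])
      manifest[[acq]] <<- data.frame(
        acquisition_id = acq, sample_id = sample_id, role = role,
        group = group, replicate = rep_i, window = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }

  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    ab <- switch(samples$role[i],
                 biological = abund[, sid],
                 QC = qc_mean,
                 blank = blank_mean)
    for (r in seq_len(design$tech_reps)) {
      emit(sid, samples$role[i], samples$group[i], r, ab)
    }
  }

  truth <- data.frame(
    species_id = library$species_id[ions$species_idx],
    class_name = library$class_name[ions$species_idx],
    carbons = library$carbons[ions$species_idx],
    double_bonds = library$double_bonds[ions$species_idx],
    adduct = ions$adduct, charge = ions$charge, iso = ions$iso,
    theo_mz = ions$theo_mz, rel = ions$rel,
    is_background = library$class_name[ions$species_idx] == "FA-background",
    stringsAsFactors = FALSE
  )
  for (g in colnames(truth_means)) {
    truth[[paste0("mean_", g)]] <- truth_means[, g]
  }
  for (g in setdiff(colnames(truth_means), "control")) {
    truth[[paste0("pct_", g)]] <-
      100 * (truth_means[, g] / truth_means[, "control"] - 1)
  }

  structure(list(
    design = design, samples = samples,
    manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
    peaks = peaks, truth = truth, library = library, effects = effects
  ), class = "lipid_study")
}

#' @export
print.lipid_study <- function(x, ...) {
  cat("Synthetic", x$design$mode, "lipidomics study:",
      nrow(x$samples), "samples,", length(x$peaks), "acquisitions,",
      nrow(x$truth), "emitted ions\n")
  print(table(x$samples$group))
  invisible(x)
}
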