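# Exact-mass annotation, isotopologue flagging and charge detection.

test_that("matching the library against its own ions gives 0 ppm", {
  lib <- small_lib()[1:40, ]
  mz <- sort(theoretical_mz(lib$mono_mass, default_adducts("[M-H]-")))
  ann <- match_features(mz, lib, adducts = "[M-H]-")
  hit <- ann[!is.na(ann$species_id), ]
  expect_equal(nrow(hit), 40L)
  expect_lt(max(abs(hit$ppm)), 1e-9)
})

test_that("features beyond the ppm tolerance stay unknown", {
  lib <- small_lib()[5, ]
  mz0 <- theoretical_mz(lib$mono_mass, default_adducts("[M-H]-"))
  ann <- match_features(mz0 * (1 + 3e-6), lib, adducts = "[M-H]-",
                        tol_ppm = 2)
  expect_equal(ann$name, "unknown")
  ann2 <- match_features(mz0 * (1 + 1.5e-6), lib, adducts = "[M-H]-",
                         tol_ppm = 2)
  expect_equal(ann2$ppm, 1.5, tolerance = 1e-3)
})

test_that("isobaric candidates are kept and ranked by ppm error", {
  lib <- small_lib()
  # PE(n+3:d) and PC(n:d) are exactly isobaric; their chloride adducts match
  # the same m/z
  pc <- lib[lib$class_name == "PC" & lib$carbons == 34 &
              lib$double_bonds == 1, ]
  mz <- theoretical_mz(pc$mono_mass, default_adducts("[M+Cl]-"))
  ann <- match_features(mz, lib, adducts = default_adducts())
  ids <- ann$species_id[!is.na(ann$species_id)]
  expect_true(all(c("PC 34:1", "PE 37:1") %in% ids))
  expect_true(all(diff(ann$rank) >= 0 | diff(abs(ann$ppm)) >= 0))
})

test_that("noise-free annotation recovers every emitted assignment", {
  st <- nf_study()
  fm <- nf_fm()
  ann <- annotate_features(fm, library = st$library)
  tr <- st$truth
  # ions surviving the filters (solvent FFAs are blank-filtered out)
  sat_ffa <- st$library$species_id[st$library$blank_level >= 0.5]
  tr <- tr[!(tr$species_id %in% sat_ffa), ]
  key_truth <- paste(tr$species_id, tr$adduct, tr$iso)
  # locate each ion's feature by m/z and check its candidate list
  idx <- findInterval(tr$theo_mz, fm$mz)
  idx[idx == 0L] <- 1L
  near <- ifelse(abs(fm$mz[idx] - tr$theo_mz) <=
                   abs(fm$mz[pmin(idx + 1L, length(fm$mz))] - tr$theo_mz),
                 idx, pmin(idx + 1L, length(fm$mz)))
  feat <- rownames(fm$intensity)[near]
  key_ann <- paste(ann$feature, ann$species_id, ann$adduct, ann$iso)
  recovered <- paste(feat, tr$species_id, tr$adduct, tr$iso) %in% key_ann
  # every non-background feature carries (at least) its generating
  # assignment; near-isobar ion merges may hide a minor co-generator, so the
  # assignment-level rate can sit a hair below 1
  lipid_feat <- unique(feat[!tr$is_background])
  expect_true(all(lipid_feat %in% unique(feat[recovered])))
  expect_gte(mean(recovered), 0.999)
})

test_that("isotopologues are flagged, linked and excluded from summaries", {
  st <- nf_study()
  fm <- nf_fm()
  ann <- annotate_features(fm, library = st$library)
  iso <- ann[ann$flagged_isotope, ]
  expect_gt(nrow(iso), 100)
  expect_true(all(!is.na(iso$parent_feature)))
  # every flagged isotopologue sits one 13C spacing above its parent
  pmz <- fm$mz[match(iso$parent_feature, rownames(fm$intensity))]
  imz <- fm$mz[match(iso$feature, rownames(fm$intensity))]
  expect_equal(imz - pmz, 1.0033548 / abs(iso$charge), tolerance = 1e-5)
})

test_that("a lone feature without a +1 partner is not flagged", {
  lib <- small_lib()[10, ]
  mz <- theoretical_mz(lib$mono_mass, default_adducts("[M-H]-"))
  ann <- match_features(mz, lib, adducts = "[M-H]-")
  out <- flag_isotopes(mz, intensity = 1e6, annotations = ann)
  expect_false(any(out$flagged_isotope))
})

test_that("an implausible isotope ratio blocks the flag", {
  lib <- small_lib()[10, ] # ~40 carbons -> expected ratio ~ 0.4
  mz0 <- theoretical_mz(lib$mono_mass, default_adducts("[M-H]-"))
  mz <- c(mz0, mz0 + 1.0033548)
  ann <- match_features(mz, lib, adducts = "[M-H]-")
  ok <- flag_isotopes(mz, intensity = c(1e6, 0.4 * 1e6), annotations = ann)
  expect_true(any(ok$flagged_isotope))
  bad <- flag_isotopes(mz, intensity = c(1e6, 5 * 0.4 * 1e6),
                       annotations = ann)
  expect_false(any(bad$flagged_isotope))
})

test_that("isotopologue spacing determines the charge state", {
  lib <- small_lib()
  pe <- lib[lib$class_name == "PE" & lib$carbons == 36 &
              lib$double_bonds == 2, ]
  mz2 <- theoretical_mz(pe$mono_mass, default_adducts("[M-2H]2-"))
  mz1 <- theoretical_mz(pe$mono_mass, default_adducts("[M-H]-"))
  mz <- sort(c(mz2, mz2 + 1.0033548 / 2, mz1, mz1 + 1.0033548))
  nC <- as.integer(sub("^C([0-9]+).*", "\\1", pe$formula))
  ratio <- 0.0107 * nC
  int <- c(1e5, ratio * 1e5, 1e6, ratio * 1e6)[order(c(mz2, mz2 + 0.5, mz1, mz1 + 1))]
  ann <- match_features(mz, pe, adducts = c("[M-H]-", "[M-2H]2-"))
  ann <- flag_isotopes(mz, intensity = int, annotations = ann)
  ch <- detect_charge(mz, ann)
  feat2 <- ann$feature[ann$adduct == "[M-2H]2-" & ann$iso == 0L][1]
  feat1 <- ann$feature[ann$adduct == "[M-H]-" & ann$iso == 0L][1]
  expect_equal(ch$charge[ch$feature == feat2], 2L)
  expect_equal(ch$charge[ch$feature == feat1], 1L)
  # the doubly charged ion links to its singly charged partner
  expect_equal(ch$partner_feature[ch$feature == feat2], feat1)
})

test_that("features without any isotopologue default to charge 1", {
  lib <- small_lib()[10, ]
  mz <- theoretical_mz(lib$mono_mass, default_adducts("[M-H]-"))
  ann <- match_features(mz, lib, adducts = "[M-H]-")
  ann <- flag_isotopes(mz, intensity = 1e6, annotations = ann)
  ch <- detect_charge(mz, ann)
  expect_equal(ch$charge, 1L)
})
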