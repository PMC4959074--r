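# End-to-end orchestration, plain-TSV interchange and provenance logging.

#' Pipeline configuration
#'
#' @param filter A [filter_config()].
#' @param pqn_reference `"biological"` or `"qc"` (PQN reference spectrum).
#' @param knn_k Neighbours for missing-value imputation.
#' @param glog_lambda `"estimate"` (QC-calibrated) or a fixed number.
#' @param folds Venetian-blinds fold count.
#' @param permutation_B Permutations per PLS-DA model (0 disables
#'   permutation testing).
#' @param A_max Largest PLS-DA model size scanned in CV.
#' @param forward_selection Run VIP forward selection on each model.
#' @param q_threshold Univariate significance threshold on q.
#' @param annotation_tol_ppm Annotation tolerance.
#' @param multivariate Fit PCA/PLS-DA models (disable for univariate-only
#'   runs).
#' @param seed Seed for the stochastic stages (permutations).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(filter = filter_config(),
                            pqn_reference = "biological", knn_k = 5,
                            glog_lambda = "estimate", folds = 3,
                            permutation_B = 1000, A_max = 5,
                            forward_selection = FALSE,
                            q_threshold = 0.05, annotation_tol_ppm = 2,
                            multivariate = TRUE, seed = 1) {
  stopifnot(inherits(filter, "filter_config"),
            pqn_reference %in% c("biological", "qc"),
            knn_k >= 1, folds >= 2, permutation_B >= 0, A_max >= 1,
            q_threshold > 0, q_threshold < 1, annotation_tol_ppm > 0)
  if (!(identical(glog_lambda, "estimate") ||
        (is.numeric(glog_lambda) && glog_lambda >= 0))) {
    stop("glog_lambda must be \"estimate\" or a non-negative number")
  }
  structure(list(filter = filter, pqn_reference = pqn_reference,
                 knn_k = knn_k, glog_lambda = glog_lambda, folds = folds,
                 permutation_B = permutation_B, A_max = A_max,
                 forward_selection = forward_selection,
                 q_threshold = q_threshold,
                 annotation_tol_ppm = annotation_tol_ppm,
                 multivariate = multivariate, seed = seed),
            class = "pipeline_config")
}

.stage_record <- function(stage, n_features, n_samples, params = "") {
  data.frame(stage = stage, n_features = n_features, n_samples = n_samples,
             params = params, timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on a study
#'
#' Preprocessing (stitch, replicate merge, align, blank + sample filters),
#' PQN normalization, KNN imputation, QC-calibrated glog transform, PCA and
#' PLS-DA models (three-group, each pairwise, and control versus pooled
#' infected) with venetian-blinds CV and optional permutation testing and
#' forward selection, per-feature ANOVA/FDR/percent changes, exact-mass
#' annotation and the per-class summary.
#'
#' @param study A `lipid_study` (from [simulate_study()] or [read_study()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given all report tables are
#'   written as TSV.
#' @return A `lipid_run` list: `feature_matrix`, `normalized` (PQN result),
#'   `imputed`, `glog` (`feature_matrix` + `params`), `pca`, `models`
#'   (per-comparison PLS-DA summaries), `differential`, `annotations`,
#'   `class_summary`, `provenance`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(study, "lipid_study"),
            inherits(config, "pipeline_config"))
  set.seed(config$seed)
  prov <- list()
  note <- function(...) prov[[length(prov) + 1L]] <<- .stage_record(...)

  fm <- preprocess_study(study, config$filter)
  note("preprocess", nrow(fm$intensity), ncol(fm$intensity),
       sprintf("replicate_min=%d blank_factor=%g sample_fraction=%g mz_tol=%gppm",
               config$filter$replicate_min, config$filter$blank_factor,
               config$filter$sample_fraction, config$filter$mz_tolerance))

  norm <- pqn_normalize(fm, reference = config$pqn_reference)
  note("pqn_normalize", nrow(fm$intensity), ncol(fm$intensity),
       sprintf("reference=%s", config$pqn_reference))

  imp <- knn_impute(norm$fm, k = config$knn_k)
  note("knn_impute", nrow(imp$intensity), ncol(imp$intensity),
       sprintf("k=%d", config$knn_k))

  is_qc <- imp$samples$role == "QC"
  if (identical(config$glog_lambda, "estimate")) {
    if (sum(is_qc) >= 3L) {
      gp <- estimate_glog_lambda(imp$intensity[, is_qc, drop = FALSE])
    } else {
      warning("fewer than 3 QC samples; glog lambda fixed at 0")
      gp <- structure(list(lambda = 0, objective = NA_real_, base = "e"),
                      class = "glog_params")
    }
  } else {
    gp <- structure(list(lambda = config$glog_lambda, objective = NA_real_,
                         base = "e"), class = "glog_params")
  }
  glog_fm <- imp
  glog_fm$intensity <- glog_transform(imp$intensity, gp$lambda)
  glog_fm$log <- c(glog_fm$log, sprintf("glog: lambda=%.6g", gp$lambda))
  note("glog", nrow(glog_fm$intensity), ncol(glog_fm$intensity),
       sprintf("lambda=%.6g", gp$lambda))

  is_bio <- imp$samples$role == "biological"
  groups <- imp$samples$group[is_bio]
  X <- t(glog_fm$intensity[, is_bio, drop = FALSE])

  pca <- NULL
  models <- NULL
  if (config$multivariate) {
    pca <- fit_pca(X)
    comparisons <- list(
      "three-group" = unique(groups),
      "control-vs-wMel" = c("control", "wMel"),
      "control-vs-wMelPop" = c("control", "wMelPop"),
      "wMel-vs-wMelPop" = c("wMel", "wMelPop"),
      "control-vs-infected" = NULL # pooled reclassification
    )
    comparisons <- comparisons[vapply(comparisons, function(g) {
      is.null(g) || all(g %in% groups)
    }, logical(1))]
    models <- lapply(names(comparisons), function(nm) {
      g <- comparisons[[nm]]
      if (is.null(g)) {
        sel <- rep(TRUE, length(groups))
        y <- ifelse(groups == "control", "control", "infected")
      } else {
        sel <- groups %in% g
        y <- groups[sel]
      }
      Xs <- X[sel, , drop = FALSE]
      cv <- venetian_cv(Xs, y, folds = config$folds, A_max = config$A_max)
      fit <- suppressWarnings(fit_plsda(Xs, y, A = cv$A))
      vip <- variable_importance(fit)
      perm <- if (config$permutation_B > 0) {
        permutation_test(Xs, y, B = config$permutation_B,
                         folds = config$folds, A_max = config$A_max)
      } else NULL
      fsel <- if (config$forward_selection) {
        forward_select(Xs, y, vip, folds = config$folds,
                       A_max = config$A_max)
      } else NULL
      list(comparison = nm, model = fit, cv = cv, vip = vip,
           permutation = perm, forward_selection = fsel)
    })
    names(models) <- names(comparisons)
    note("multivariate", ncol(X), nrow(X),
         sprintf("models=%d folds=%d A_max=%d B=%d seed=%d",
                 length(models), config$folds, config$A_max,
                 config$permutation_B, config$seed))
  }

  diff <- differential_analysis(imp, q_threshold = config$q_threshold)
  note("univariate", nrow(diff), sum(is_bio),
       sprintf("q_threshold=%g", config$q_threshold))

  ann <- annotate_features(imp, library = study$library,
                           tol_ppm = config$annotation_tol_ppm)
  note("annotation", length(unique(ann$feature)), NA_integer_,
       sprintf("tol=%gppm", config$annotation_tol_ppm))

  cs <- class_summary(diff, ann)
  note("class_summary", nrow(cs$classes), NA_integer_, "")

  run <- structure(list(
    feature_matrix = fm, normalized = norm, imputed = imp,
    glog = list(fm = glog_fm, params = gp), pca = pca, models = models,
    differential = diff, annotations = ann, class_summary = cs,
    provenance = do.call(rbind, prov), config = config
  ), class = "lipid_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.lipid_run <- function(x, ...) {
  cat("lipidpipe run\n")
  print(x$provenance[, c("stage", "n_features", "n_samples", "params")])
  invisible(x)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write the report tables of a run
#'
#' @param run A `lipid_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fm <- run$feature_matrix
  mat <- function(f) {
    data.frame(feature = rownames(f$intensity), mz = f$mz, f$intensity,
               check.names = FALSE)
  }
  .write_tsv(mat(fm), file.path(out_dir, "feature_matrix.tsv"))
  .write_tsv(mat(run$imputed), file.path(out_dir, "normalized_matrix.tsv"))
  .write_tsv(mat(run$glog$fm), file.path(out_dir, "glog_matrix.tsv"))
  .write_tsv(run$differential, file.path(out_dir, "differential_results.tsv"))
  .write_tsv(run$annotations, file.path(out_dir, "annotations.tsv"))
  .write_tsv(run$class_summary$classes, file.path(out_dir, "class_summary.tsv"))
  .write_tsv(run$class_summary$species, file.path(out_dir, "species_summary.tsv"))
  if (!is.null(run$pca)) {
    .write_tsv(data.frame(sample = rownames(run$pca$scores),
                          run$pca$scores[, seq_len(min(5, ncol(run$pca$scores)))]),
               file.path(out_dir, "pca_scores.tsv"))
  }
  if (!is.null(run$models)) {
    summ <- do.call(rbind, lapply(run$models, function(m) {
      data.frame(comparison = m$comparison, A = m$cv$A,
                 cv_error = m$cv$error,
                 permutation_p = if (is.null(m$permutation)) NA_real_
                                 else m$permutation$p,
                 forward_k = if (is.null(m$forward_selection)) NA_integer_
                             else m$forward_selection$k,
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(summ, file.path(out_dir, "plsda_summary.tsv"))
  }
  .write_tsv(run$provenance, file.path(out_dir, "provenance.tsv"))
  invisible(out_dir)
}

#' Write a study to disk as plain TSV
#'
#' One peak-list file per acquisition plus `manifest.tsv`, the ground-truth
#' table and the species library.
#'
#' @param study A `lipid_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  man <- study$manifest
  man$file <- file.path("peaks", paste0(man$acquisition_id, ".tsv"))
  for (i in seq_len(nrow(man))) {
    .write_tsv(study$peaks[[man$acquisition_id[i]]],
               file.path(dir, man$file[i]))
  }
  .write_tsv(man, file.path(dir, "manifest.tsv"))
  .write_tsv(study$truth, file.path(dir, "ground_truth.tsv"))
  .write_tsv(study$library, file.path(dir, "library.tsv"))
  design <- study$design
  design$windows <- NULL
  .write_tsv(data.frame(key = names(design),
                        value = vapply(design, function(v) {
                          paste(v, collapse = ",")
                        }, character(1))),
             file.path(dir, "design.tsv"))
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' Validates the manifest (unique acquisition ids, existing files) and each
#' peak list (sorted m/z, non-negative intensities); DIMS peaks outside the
#' acquired m/z range raise a warning but are kept.
#'
#' @param dir Study directory.
#' @return A `lipid_study` (without effects; the ground truth carries the
#'   true means).
#' @export
read_study <- function(dir) {
  man <- .read_tsv(file.path(dir, "manifest.tsv"))
  if (anyDuplicated(man$acquisition_id)) {
    stop("duplicate acquisition ids in manifest: ",
         paste(unique(man$acquisition_id[duplicated(man$acquisition_id)]),
               collapse = ", "))
  }
  dkv <- .read_tsv(file.path(dir, "design.tsv"))
  dget <- function(k) dkv$value[match(k, dkv$key)]
  mode <- dget("mode")
  mz_range <- as.numeric(strsplit(dget("mz_range"), ",")[[1]])
  design <- study_design(
    n_control = sum(man$group == "control" & man$replicate == 1 &
                      (is.na(man$window) | man$window == 1)),
    n_wmel = sum(man$group == "wMel" & man$replicate == 1 &
                   (is.na(man$window) | man$window == 1)),
    n_wmelpop = sum(man$group == "wMelPop" & man$replicate == 1 &
                      (is.na(man$window) | man$window == 1)),
    tech_reps = max(man$replicate),
    n_windows = if (all(is.na(man$window))) 1L else max(man$window),
    mz_range = mz_range,
    window_overlap = as.numeric(dget("window_overlap")),
    n_qc = sum(man$role == "QC" & man$replicate == 1 &
                 (is.na(man$window) | man$window == 1)),
    n_blank = sum(man$role == "blank" & man$replicate == 1 &
                    (is.na(man$window) | man$window == 1)),
    seed = as.integer(dget("seed")), mode = mode
  )
  peaks <- list()
  for (i in seq_len(nrow(man))) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) {
      stop("manifest references a missing peak-list file: ", man$file[i])
    }
    pk <- .read_tsv(path)
    if (any(pk$intensity < 0)) {
      stop("negative intensities in ", man$file[i])
    }
    if (is.unsorted(pk$mz)) {
      stop("m/z not sorted in ", man$file[i])
    }
    if (mode == "DIMS" && nrow(pk) &&
        (min(pk$mz) < mz_range[1] || max(pk$mz) > mz_range[2])) {
      warning("peaks outside the acquired m/z range in ", man$file[i],
              "; kept")
    }
    peaks[[man$acquisition_id[i]]] <- pk
  }
  samples <- unique(man[, c("sample_id", "role", "group")])
  rownames(samples) <- NULL
  truth_path <- file.path(dir, "ground_truth.tsv")
  lib_path <- file.path(dir, "library.tsv")
  structure(list(
    design = design, samples = samples, manifest = man, peaks = peaks,
    truth = if (file.exists(truth_path)) .read_tsv(truth_path) else NULL,
    library = if (file.exists(lib_path)) .read_tsv(lib_path) else
      default_library(),
    effects = NULL
  ), class = "lipid_study")
}
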