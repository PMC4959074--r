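# Shared fixtures, all generated in code.  Heavy objects are built once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(expr)
  }
  .fixture_cache[[name]]
}

# compact library: full annotated classes, small background panel
small_lib <- function() fixture("small_lib", default_library(n_background = 60))

small_design <- function(seed = 1, n_windows = 3, ...) {
  study_design(n_control = 3, n_wmel = 3, n_wmelpop = 3, n_qc = 3,
               n_blank = 2, n_windows = n_windows, seed = seed, ...)
}

# noisy small study + its preprocessed matrix
small_study <- function() {
  fixture("small_study", simulate_study(small_design(seed = 7), small_lib()))
}
small_fm <- function() {
  fixture("small_fm", suppressWarnings(preprocess_study(small_study())))
}

# noise-free small study (exactness checks)
nf_study <- function() {
  fixture("nf_study",
          simulate_study(noise_free(small_design(seed = 8)), small_lib()))
}
nf_fm <- function() {
  fixture("nf_fm", suppressWarnings(preprocess_study(nf_study())))
}

# a feature_matrix built by hand around given biological values
manual_fm <- function(values, groups, mz = NULL, roles = NULL) {
  values <- as.matrix(values)
  n <- ncol(values)
  if (is.null(roles)) roles <- rep("biological", n)
  if (is.null(mz)) mz <- 100 + seq_len(nrow(values))
  ids <- sprintf("S%02d", seq_len(n))
  colnames(values) <- ids
  rownames(values) <- sprintf("F%05d", seq_len(nrow(values)))
  feature_matrix(mz = mz, intensity = values,
                 samples = data.frame(sample_id = ids, role = roles,
                                      group = groups,
                                      stringsAsFactors = FALSE))
}
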