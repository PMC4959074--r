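# SIM stitching, replicate merging, alignment and the occupancy filters.

two_windows <- data.frame(window = 1:2, start = c(100, 200), end = c(210, 310))

test_that("identical overlap peaks stitch with scale 1 and merge", {
  w1 <- data.frame(mz = c(150, 205), intensity = c(10, 20))
  w2 <- data.frame(mz = c(205, 300), intensity = c(20, 5))
  out <- stitch_sim_windows(list(w1, w2), two_windows)
  expect_equal(out$mz, c(150, 205, 300))
  expect_equal(out$intensity, c(10, 20, 5))
})

test_that("a doubled window is rescaled by the median overlap ratio", {
  w1 <- data.frame(mz = c(150, 203, 205), intensity = c(10, 8, 20))
  w2 <- data.frame(mz = c(203, 205, 300), intensity = c(16, 40, 10))
  out <- stitch_sim_windows(list(w1, w2), two_windows)
  # both shared peaks give ratio 1/2 -> window 2 halved
  expect_equal(out$intensity[out$mz == 300], 5)
  expect_equal(out$intensity[abs(out$mz - 205) < 0.01], 20)
})

test_that("a single window passes through unchanged", {
  w1 <- data.frame(mz = c(150, 205), intensity = c(10, 20))
  out <- stitch_sim_windows(list(w1), two_windows[1, ])
  expect_equal(out, w1)
})

test_that("an empty overlap warns and uses scale 1", {
  w1 <- data.frame(mz = 150, intensity = 10)
  w2 <- data.frame(mz = 300, intensity = 5)
  expect_warning(out <- stitch_sim_windows(list(w1, w2), two_windows),
                 "no shared peaks")
  expect_equal(out$intensity, c(10, 5))
})

test_that("replicate filter keeps 2-of-3 peaks and drops singletons", {
  r1 <- data.frame(mz = c(700.0000, 800.0000), intensity = c(10, 5))
  r2 <- data.frame(mz = c(700.0005, 900.0000), intensity = c(12, 7))
  r3 <- data.frame(mz = 1000.0000, intensity = 3)
  out <- merge_replicates(list(r1, r2, r3))
  # ~700 in replicates 1+2 -> kept; 800/900/1000 singletons -> dropped
  expect_equal(nrow(out), 1L)
  expect_equal(out$mz, stats::weighted.mean(c(700.0000, 700.0005), c(10, 12)))
  expect_equal(out$intensity, mean(c(10, 12)))
})

test_that("merging identical triplicates is idempotent", {
  r <- data.frame(mz = c(150.05, 700.1, 900.2), intensity = c(1, 2, 3))
  out <- merge_replicates(list(r, r, r))
  expect_equal(out, r)
})

test_that("empty replicate input warns and returns an empty list", {
  empty <- data.frame(mz = numeric(0), intensity = numeric(0))
  expect_warning(out <- merge_replicates(list(empty, empty, empty)), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("alignment splits features at the ppm tolerance", {
  info <- data.frame(sample_id = c("a", "b"), role = "biological",
                     group = c("g1", "g2"), stringsAsFactors = FALSE)
  # 1.4 ppm apart -> one feature
  fm1 <- align_samples(list(a = data.frame(mz = 700.0000, intensity = 10),
                            b = data.frame(mz = 700.0010, intensity = 12)),
                       info)
  expect_equal(length(fm1$mz), 1L)
  expect_equal(unname(fm1$intensity[1, ]), c(10, 12))
  # 2.9 ppm apart -> two features
  fm2 <- align_samples(list(a = data.frame(mz = 700.0000, intensity = 10),
                            b = data.frame(mz = 700.0020, intensity = 12)),
                       info)
  expect_equal(length(fm2$mz), 2L)
  expect_true(anyNA(fm2$intensity))
})

test_that("single-sample alignment yields a complete one-column matrix", {
  info <- data.frame(sample_id = "a", role = "biological", group = "g1",
                     stringsAsFactors = FALSE)
  fm <- align_samples(list(a = data.frame(mz = c(150, 700), intensity = c(1, 2))),
                      info)
  expect_equal(dim(fm$intensity), c(2L, 1L))
  expect_false(anyNA(fm$intensity))
})

test_that("same-sample peaks farther than the tolerance split the cluster", {
  info <- data.frame(sample_id = c("a", "b"), role = "biological",
                     group = "g1", stringsAsFactors = FALSE)
  # chain 700.0000-700.0009-700.0018: gaps ~1.3 ppm but sample a spans 2.6 ppm
  fm <- align_samples(list(
    a = data.frame(mz = c(700.0000, 700.0018), intensity = c(10, 10)),
    b = data.frame(mz = 700.0009, intensity = 5)
  ), info)
  expect_equal(length(fm$mz), 2L)
})

test_that("blank filter applies the 2x rule feature by feature", {
  vals <- rbind(c(130, 130, 60, 60),   # bio mean 130 >= 2*60 -> kept
                c(100, 100, 60, 60),   # 100 < 120 -> dropped
                c(5, 5, NA, NA))       # absent from blanks -> kept
  fm <- manual_fm(vals, groups = c("g1", "g1", "blank", "blank"),
                  roles = c("biological", "biological", "blank", "blank"))
  out <- blank_filter(fm)
  expect_equal(rownames(out$intensity), c("F00001", "F00003"))
  expect_false(any(out$samples$role == "blank"))
})

test_that("blank filter treats missing as zero in both means", {
  vals <- rbind(c(130, NA, 60, NA))    # bio mean 65, blank mean 30 -> kept
  fm <- manual_fm(vals, groups = c("g1", "g1", "blank", "blank"),
                  roles = c("biological", "biological", "blank", "blank"))
  out <- blank_filter(fm)
  expect_equal(nrow(out$intensity), 1L)
  vals2 <- rbind(c(110, NA, 60, NA))   # bio mean 55 < 60 -> dropped
  fm2 <- manual_fm(vals2, groups = c("g1", "g1", "blank", "blank"),
                   roles = c("biological", "biological", "blank", "blank"))
  expect_equal(nrow(blank_filter(fm2)$intensity), 0L)
})

test_that("blank filter without blanks warns and passes through", {
  fm <- manual_fm(rbind(c(1, 2)), groups = c("g1", "g1"))
  expect_warning(out <- blank_filter(fm), "no blank")
  expect_equal(out$intensity, fm$intensity)
})

test_that("sample filter retains features seen in 75% of one group", {
  groups <- c(rep("control", 7), rep("wMel", 6), rep("wMelPop", 6))
  v1 <- c(rep(1, 6), NA, rep(NA, 12))            # 6/7 control = 86%
  v2 <- c(rep(1, 4), rep(NA, 3), rep(1, 4), NA, NA,
          rep(1, 4), NA, NA)                     # 57/67/67% everywhere
  v3 <- rep(1, 19)
  fm <- manual_fm(rbind(v1, v2, v3), groups = groups)
  out <- sample_filter(fm)
  expect_equal(nrow(out$intensity), 2L)
  expect_equal(unname(out$intensity[1, 1]), 1)
  # overall mode: v1 is 6/19 -> dropped, v3 kept
  cfg <- filter_config(sample_filter_mode = "overall")
  out2 <- sample_filter(fm, cfg)
  expect_equal(nrow(out2$intensity), 1L)
})

test_that("filters only drop features, never alter retained intensities", {
  fm <- small_fm()
  st <- small_study()
  raw <- suppressWarnings({
    man <- st$manifest
    merged <- lapply(split(man, man$sample_id), function(rows) {
      rows <- rows[order(rows$replicate, rows$window), ]
      reps <- lapply(split(rows, rows$replicate), function(rr) {
        stitch_sim_windows(st$peaks[rr$acquisition_id],
                           st$design$windows[rr$window, ])
      })
      merge_replicates(unname(reps))
    })
  })
  # re-running the blank+sample filter chain on its own output is a no-op
  refiltered <- suppressWarnings(sample_filter(blank_filter(fm)))
  expect_equal(refiltered$intensity, fm$intensity)
  expect_equal(refiltered$mz, fm$mz)
  expect_true(length(raw) == nrow(st$samples))
})

test_that("noise-free studies lose nothing but solvent background", {
  st <- nf_study()
  fm_all <- suppressWarnings(align_samples(
    {
      man <- st$manifest
      merged <- lapply(split(man, man$sample_id), function(rows) {
        reps <- lapply(split(rows, rows$replicate), function(rr) {
          rr <- rr[order(rr$window), ]
          stitch_sim_windows(st$peaks[rr$acquisition_id],
                             st$design$windows[rr$window, ])
        })
        merge_replicates(unname(reps))
      })
      ids <- unique(man$sample_id)
      merged[ids]
    },
    unique(st$manifest[, c("sample_id", "role", "group")])
  ))
  # aligned feature count equals the count of emitted m/z values that are
  # resolvable at the alignment tolerance (2 ppm single-linkage clusters)
  u <- sort(unique(st$truth$theo_mz))
  n_resolvable <- sum(diff(u) / u[-length(u)] > 2e-6) + 1L
  expect_equal(length(fm_all$mz), n_resolvable)
  # every non-background species' primary ion survives the full filter chain
  fm <- nf_fm()
  tr <- st$truth
  prim <- tr[!tr$is_background & tr$iso == 0L & tr$rel == 1, ]
  idx <- findInterval(prim$theo_mz, fm$mz)
  near <- pmin(abs(prim$theo_mz - fm$mz[pmax(idx, 1)]),
               abs(prim$theo_mz - fm$mz[pmin(idx + 1, length(fm$mz))]))
  expect_true(all(near / prim$theo_mz * 1e6 < 0.1))
})
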