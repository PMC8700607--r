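test_that("default templates encode the class fingerprint structure", {
  tpl <- build_default_templates()
  expect_setequal(names(tpl), c("black", "green", "oolong", "red",
                                "white_a", "white_b", "chicory"))
  peak_col <- function(t, f) vapply(t$peaks, `[[`, numeric(1), f)
  teas <- setdiff(names(tpl), "chicory")
  for (nm in names(tpl)) {
    rt <- peak_col(tpl[[nm]], "rt_min")
    expect_true(all(rt >= 0 & rt <= 25))
    expect_true(all(peak_col(tpl[[nm]], "width_min") > 0))
    expect_true(all(peak_col(tpl[[nm]], "amp_uv") >= 0))
    expect_true(all(peak_col(tpl[[nm]], "amp_fld") >= 0))
  }
  # every tea shares an intense peak near 11 min
  for (nm in teas) {
    rt <- peak_col(tpl[[nm]], "rt_min")
    expect_true(any(rt >= 10.5 & rt <= 11.5), label = nm)
  }
  uv_count <- vapply(tpl, function(t) sum(peak_col(t, "amp_uv") > 0), 1L)
  fld_count <- vapply(tpl, function(t) sum(peak_col(t, "amp_fld") > 0), 1L)
  uv_max <- vapply(tpl, function(t) max(peak_col(t, "amp_uv")), 1)
  fld_max <- vapply(tpl, function(t) max(peak_col(t, "amp_fld")), 1)
  # chicory: UV peak-richest but ~100-fold weaker than any tea
  expect_true(all(uv_count["chicory"] > uv_count[teas]))
  expect_lte(uv_max["chicory"], 0.01 * min(uv_max[teas]))
  # white teas most intense in UV; black/green most intense in FLD
  expect_true(all(sort(uv_max[teas], decreasing = TRUE)[1:2] ==
                    sort(uv_max[c("white_a", "white_b")], decreasing = TRUE)))
  expect_setequal(names(sort(fld_max, decreasing = TRUE)[1:2]),
                  c("black", "green"))
  # red and chicory give the most FLD peaks
  expect_setequal(names(sort(fld_count, decreasing = TRUE)[1:2]),
                  c("red", "chicory"))
})

test_that("chromatogram generation is the exact peak sum when stochastics are off", {
  tpl <- toy_template()
  grid <- default_grid(step = 0.05)
  tr <- generate_chromatogram(tpl, "uv", injection_index = 1,
                              drift = drift_model(0, 0), seed = 42,
                              grid = grid, noise_frac = 0,
                              baseline_frac = 0)
  expect_equal(tr$intensity,
               gauss_oracle(grid, c(5, 11), c(0.3, 0.4), c(2, 5)),
               tolerance = 1e-12)
  expect_length(tr$intensity, length(grid))
})

test_that("chromatogram generation is deterministic in the seed", {
  tpl <- toy_template(amp_cv = 0.1, rt_jitter_sd = 0.05)
  grid <- default_grid(step = 0.05)
  args <- list(tpl, "fld", injection_index = 3, drift = drift_model(),
               seed = 7, grid = grid, n_injections = 10)
  a <- do.call(generate_chromatogram, args)
  b <- do.call(generate_chromatogram, args)
  expect_identical(a$intensity, b$intensity)
  c2 <- do.call(generate_chromatogram, modifyList(args, list(seed = 8)))
  expect_false(identical(a$intensity, c2$intensity))
})

test_that("a -15% drift slope scales the last injection to 0.85 of the first", {
  tpl <- toy_template()
  grid <- default_grid(step = 0.05)
  drift <- drift_model(slope = -0.15, walk_sd = 0)
  n <- 20L
  first <- generate_chromatogram(tpl, "uv", 1L, drift, seed = 1, grid = grid,
                                 n_injections = n, noise_frac = 0,
                                 baseline_frac = 0)
  last <- generate_chromatogram(tpl, "uv", n, drift, seed = 1, grid = grid,
                                n_injections = n, noise_frac = 0,
                                baseline_frac = 0)
  expect_equal(max(last$intensity) / max(first$intensity), 0.85,
               tolerance = 1e-10)
  expect_equal(drift_factors(drift, n, seed = 1),
               1 - 0.15 * (0:(n - 1)) / (n - 1), tolerance = 1e-12)
})

test_that("injection sequences follow the QC/blank cadence", {
  s10 <- build_injection_sequence(sprintf("s%02d", 1:10), seed = 1)
  expect_identical(s10$role, c("qc", rep("sample", 10), "blank", "qc"))
  s1 <- build_injection_sequence("only", seed = 1)
  expect_identical(s1$role, c("qc", "sample", "blank", "qc"))
  s25 <- build_injection_sequence(sprintf("s%02d", 1:25), seed = 3)
  expect_identical(sum(s25$role == "blank"), 3L)
  expect_identical(sum(s25$role == "qc"), 4L)
  expect_identical(s25$injection_index, seq_len(nrow(s25)))
  # seeded random order: deterministic, and a permutation of the input
  s25b <- build_injection_sequence(sprintf("s%02d", 1:25), seed = 3)
  expect_identical(s25, s25b)
  expect_setequal(s25$sample_id[s25$role == "sample"], sprintf("s%02d", 1:25))
  expect_error(build_injection_sequence(c("a", "a")), "unique")
})

test_that("the default dataset reproduces the study design", {
  ds <- default_dataset()
  for (ch in c("uv", "fld")) {
    meta <- ds[[ch]]$metadata
    expect_identical(sum(meta$role == "sample"), 107L)
    expect_identical(sum(meta$role == "qc"), 12L)     # ceiling(107/10) + 1
    expect_identical(sum(meta$role == "blank"), 11L)
  }
  counts <- table(ds$truth$class_label)
  expect_identical(as.integer(counts[c("black", "green", "oolong", "red",
                                       "white", "chicory")]),
                   c(35L, 20L, 10L, 12L, 10L, 20L))
  expect_identical(sum(ds$truth$template_class == "white_a"), 5L)
  expect_identical(sum(ds$truth$template_class == "white_b"), 5L)
  # uv and fld share the sequence and grid
  expect_identical(ds$uv$metadata, ds$fld$metadata)
  expect_identical(ds$uv$time_min, ds$fld$time_min)
})

test_that("dataset generation is bit-reproducible and handles empty designs", {
  cfg <- coarse_config(class_counts = c(black = 3, chicory = 3))
  a <- generate_dataset(cfg, seed = 11)
  b <- generate_dataset(cfg, seed = 11)
  expect_identical(a$uv$intensity, b$uv$intensity)
  expect_identical(a$fld$intensity, b$fld$intensity)
  expect_identical(a$sequence, b$sequence)
  empty <- generate_dataset(coarse_config(class_counts = c(black = 0)),
                            seed = 1)
  expect_identical(nrow(empty$uv$intensity), 0L)
  expect_identical(nrow(empty$sequence), 0L)
})

test_that("the pooled QC is the unweighted mean of drift-free sample traces", {
  m <- matrix(c(1, 2, 3, 5, 6, 7), nrow = 2, byrow = TRUE)
  expect_equal(make_pooled_qc(m), c(3, 4, 5))
  expect_equal(make_pooled_qc(m[1, , drop = FALSE]), c(1, 2, 3))
  expect_error(make_pooled_qc(m[0, , drop = FALSE]), "zero samples")
  ds <- default_dataset()
  expect_equal(make_pooled_qc(ds$ideal$uv), ds$ideal$qc_uv, tolerance = 1e-12)
})

test_that("fingerprint mixing is linear and conserves area", {
  tpl <- build_default_templates()
  grid <- default_grid(step = 0.05)
  mk <- function(t) generate_chromatogram(t, "uv", 1, drift_model(0, 0),
                                          seed = 5, grid = grid,
                                          noise_frac = 0, baseline_frac = 0)
  tea <- mk(tpl$black)
  chic <- mk(tpl$chicory)
  expect_equal(mix_fingerprints(tea, chic, 0)$intensity, tea$intensity)
  expect_equal(mix_fingerprints(tea, chic, 100)$intensity, chic$intensity)
  expect_equal(mix_fingerprints(tea, chic, 50)$intensity,
               (tea$intensity + chic$intensity) / 2)
  for (p in c(10, 30, 85)) {
    expect_equal(sum(mix_fingerprints(tea, chic, p)$intensity),
                 (1 - p / 100) * sum(tea$intensity) +
                   p / 100 * sum(chic$intensity),
                 tolerance = 1e-9)
  }
  expect_error(mix_fingerprints(tea, chic, 101), "\\[0, 100\\]")
  expect_error(mix_fingerprints(tea, chic, -1), "\\[0, 100\\]")
})

test_that("raw QC dispersion under drift far exceeds the noise-only dispersion", {
  qc_rsd <- function(drift) {
    ds <- generate_dataset(coarse_config(drift = drift), seed = 2)
    tot <- rowSums(ds$uv$intensity[ds$uv$metadata$role == "qc", ])
    stats::sd(tot) / mean(tot)
  }
  expect_gt(qc_rsd(drift_model(-0.15, 0.005)),
            3 * qc_rsd(drift_model(0, 0)))
})

test_that("classes separate in PCA space at the default variability", {
  feats <- default_features("uv")
  sc <- pca_fit(autoscale(feats$intensity)$scaled, 10)$scores
  lab <- feats$metadata$class_label
  d <- as.matrix(stats::dist(sc))
  cls <- unique(lab)
  for (a in cls) {
    for (b in cls) {
      if (a < b) {
        within_a <- mean(d[lab == a, lab == a][upper.tri(d[lab == a, lab == a])])
        within_b <- mean(d[lab == b, lab == b][upper.tri(d[lab == b, lab == b])])
        between <- mean(d[lab == a, lab == b])
        expect_lt(max(within_a, within_b), between,
                  label = paste(a, "vs", b))
      }
    }
  }
})
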