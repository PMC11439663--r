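test_that("block BOLD converges to its target correlations at large T", {
  b <- generate_block_bold(c(A = 3, B = 3), 5000, 0.6, 0.0, seed = 17)
  r <- unclass(compute_fc(b))
  within <- c(r[1, 2], r[1, 3], r[2, 3], r[4, 5], r[4, 6], r[5, 6])
  between <- as.vector(r[1:3, 4:6])
  expect_lt(abs(mean(within) - 0.6), 0.05)
  expect_lt(abs(mean(between) - 0.0), 0.05)
})

test_that("equal within/between correlations give zero segregation", {
  b <- generate_block_bold(c(VN = 4, SMN = 4), 5000, 0.3, 0.3, seed = 5)
  s <- system_segregation(fisher_z(compute_fc(b)),
                          bold_partition(b, c("VN", "SMN")))
  expect_lt(abs(s$overall$sysseg), 0.05)
})

test_that("membership scrambling can only lower empirical segregation", {
  ps <- c(VN = 6, SMN = 6, DMN = 6)
  seg_of <- function(mix) {
    b <- generate_block_bold(ps, 2000, 0.6, 0.05, mixing_fraction = mix,
                             seed = 23)
    system_segregation(fisher_z(compute_fc(b)),
                       bold_partition(b, names(ps)))$overall$sysseg
  }
  expect_lte(seg_of(1.0), seg_of(0.0))
})

test_that("invalid block parameters are rejected", {
  expect_error(generate_block_bold(c(A = 3, B = 3), 100, 1.0, 0.1),
               "below 1")
  expect_error(generate_block_bold(c(A = 3, B = 3), 100, 0.4, 0.6),
               "r_between")
  expect_message(generate_block_bold(c(A = 3, B = 3), 4, 0.4, 0.1,
                                     seed = 1),
                 "timepoints")
})

test_that("the closed-form generating segregation matches the sampled matrix", {
  set.seed(31)
  canonical <- rep(c("VN", "SMN", "DMN"), each = 5)
  for (mix in c(0, 0.4)) {
    b <- generate_block_bold(c(VN = 5, SMN = 5, DMN = 5), 10, 0.5, 0.1,
                             mixing_fraction = mix, seed = 77)
    sig <- attr(b, "sigma")
    gen <- attr(b, "generating_membership")
    # evaluate SysSeg directly on the generating matrix (exact z values)
    z <- atanh(pmin(sig, 1 - 1e-7))
    diag(z) <- 0
    dimnames(z) <- list(names(gen), names(gen))
    direct <- system_segregation(
      as_fc_matrix(z, "fisher_z"),
      canonical_partition(names(gen), canonical,
                          analysis_set = c("VN", "SMN", "DMN")))
    closed <- block_segregation_expected(canonical, unname(gen), 0.5, 0.1,
                                         analysis_set = c("VN", "SMN",
                                                          "DMN"))
    expect_equal(closed, direct$overall$sysseg, tolerance = 1e-12)
  }
})

test_that("cohort generation is bit-identical under one seed", {
  spec <- cohort_spec(n_decliners = 3, n_nondecliners = 3, n_nodes = 40,
                      timepoints = 60, seed = 6)
  c1 <- generate_cohort(spec, grid_shape = c(16, 16, 16))
  c2 <- generate_cohort(spec, grid_shape = c(16, 16, 16))
  expect_identical(cohort_records(c1), cohort_records(c2))
  expect_identical(lapply(c1, function(s) unclass(s$bold)),
                   lapply(c2, function(s) unclass(s$bold)))
  expect_identical(lapply(c1, function(s) s$pet_volume$data),
                   lapply(c2, function(s) s$pet_volume$data))
  expect_identical(lapply(c1, function(s) s$lesion_mask$data),
                   lapply(c2, function(s) s$lesion_mask$data))
})

test_that("null configuration leaves no group difference in generating segregation", {
  sp0 <- cohort_spec(n_decliners = 4, n_nondecliners = 4, n_nodes = 40,
                     timepoints = 50, segregation_shift = 0,
                     mixing_fraction = 0,
                     outcome_coefs = c(intercept = 0, segregation = 0,
                                       wmh_decliner = 0,
                                       wmh_nondecliner = 0, suvr = 0),
                     seed = 3)
  c0 <- generate_cohort(sp0, include_bold = FALSE,
                        include_volumes = FALSE,
                        enforce_classification = FALSE)
  r0 <- cohort_records(c0)
  seg <- tapply(r0$generating_segregation, r0$group, mean)
  expect_identical(seg[["decliner"]], seg[["non_decliner"]])
})

test_that("generating segregation drives MMSE change under nonzero coupling", {
  spec <- cohort_spec(n_decliners = 25, n_nondecliners = 25, n_nodes = 60,
                      seed = 12)
  rec <- cohort_records(generate_cohort(spec, include_bold = FALSE,
                                        include_volumes = FALSE))
  rho <- cor(rec$generating_segregation, rec$mmse_change,
             method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("group labels and the classification rule agree on >= 90% of subjects", {
  spec <- cohort_spec(seed = 11)   # default 11 decliners / 10 non-decliners
  rec <- cohort_records(generate_cohort(spec, include_bold = FALSE,
                                        include_volumes = FALSE))
  called <- classify_decliner(rec$mmse_baseline, rec$mmse_final,
                              rec$interval_months)
  expect_gte(mean(called == rec$group), 0.9)
  expect_true(all(rec$mmse_baseline >= 0 & rec$mmse_baseline <= 30))
  expect_true(all(rec$interval_months > 0))
})

test_that("decliner segregation decreases monotonically with the shift grid", {
  shifts <- c(0, 0.1, 0.2, 0.3)
  means <- vapply(shifts, function(sh) {
    sp <- cohort_spec(n_decliners = 5, n_nondecliners = 2, n_nodes = 50,
                      timepoints = 400, segregation_shift = sh,
                      mixing_fraction = 0, seed = 9)
    ch <- generate_cohort(sp, include_volumes = FALSE,
                          enforce_classification = FALSE)
    part <- cohort_partition(ch)
    rec <- cohort_records(ch)
    segs <- vapply(ch, function(s)
      system_segregation(fisher_z(compute_fc(s$bold)),
                         part)$overall$sysseg, numeric(1))
    mean(segs[rec$group == "decliner"])
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("subject volumes reproduce the recorded SUVR and WMH read-outs", {
  spec <- cohort_spec(n_decliners = 2, n_nondecliners = 2, n_nodes = 40,
                      timepoints = 50, seed = 21)
  ch <- generate_cohort(spec, include_bold = FALSE,
                        grid_shape = c(16, 16, 16))
  for (s in ch) {
    rs <- regional_suvr(s$pet_volume, s$label_volume,
                        SYNTHETIC_REFERENCE_LABEL)
    g <- global_suvr(rs, SYNTHETIC_COMPOSITES)$global_suvr
    expect_equal(g, s$record$global_suvr, tolerance = 1e-12)
    expect_equal(wmh_volume_fraction(s$lesion_mask, s$brain_mask),
                 s$record$wmh_fraction_pct, tolerance = 1e-12)
    expect_true(all(s$lesion_mask$data <= s$brain_mask$data))
  }
})

test_that("cohort specs read from YAML and JSON and unsatisfiable specs fail", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_decliners: 3", "n_nondecliners: 2", "n_nodes: 40",
               "timepoints: 50", "seed: 4"), yml)
  sp <- read_cohort_spec(yml)
  expect_s3_class(sp, "cohort_spec")
  expect_equal(sp$n_decliners, 3L)
  expect_equal(sum(sp$partition_spec), 40)

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_decliners": 2, "n_nondecliners": 2, "n_nodes": 30,
               "timepoints": 40, "seed": 8}', js)
  expect_equal(read_cohort_spec(js)$n_nodes, 30L)

  # an outcome model that cannot produce decliner-range drops
  bad <- cohort_spec(n_decliners = 4, n_nondecliners = 4, n_nodes = 30,
                     timepoints = 40,
                     outcome_coefs = c(intercept = 0, segregation = 0,
                                       wmh_decliner = 0,
                                       wmh_nondecliner = 0, suvr = 0),
                     noise_sd = 0.1, seed = 2)
  expect_error(generate_cohort(bad, include_bold = FALSE,
                               include_volumes = FALSE, max_retries = 3),
               "unsatisfiable")
})

test_that("a written cohort is fully reconstructable from its manifest", {
  spec <- cohort_spec(n_decliners = 2, n_nondecliners = 1, n_nodes = 30,
                      timepoints = 40, seed = 14)
  ch <- generate_cohort(spec, grid_shape = c(12, 12, 12))
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(ch, dir)
  man <- jsonlite::read_json(manifest_path)
  expect_true(file.exists(man$records))
  rec <- read.csv(man$records)
  expect_equal(nrow(rec), 3)
  part <- read_partition(man$partition)
  expect_equal(nrow(part), 30)
  for (id in names(man$subjects)) {
    entry <- man$subjects[[id]]
    b <- read_bold(entry$bold)
    expect_equal(dim(b), c(40, 30))
    pv <- read_volume(entry$pet_volume, "intensity",
                      space_tag = "synthetic-grid")
    expect_equal(pv$grid_shape, c(12, 12, 12))
  }
})
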