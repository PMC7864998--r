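small_cfg <- function(n_scans = 3, amplitude = 3, seed = 5)
  scene_config(height = 64, width = 64, mean_rows = c(16, 34, 44),
               undulation_amplitude = amplitude, n_scans = n_scans,
               seed = seed)

test_that("truth sampling is deterministic, flat at zero amplitude, and range-bounded", {
  flat <- sample_truth(small_cfg(amplitude = 0))
  for (b in flat) {
    expect_equal(b$ilm, rep(16, 64))
    expect_equal(b$cci, rep(34, 64))
    expect_equal(b$csi, rep(44, 64))
  }

  t1 <- sample_truth(small_cfg(seed = 9))
  t2 <- sample_truth(small_cfg(seed = 9))
  expect_identical(t1, t2)
  t3 <- sample_truth(small_cfg(seed = 10))
  expect_false(identical(t1, t3))

  wavy <- sample_truth(scene_config(height = 64, width = 128,
                                    mean_rows = c(16, 34, 44),
                                    undulation_amplitude = 4.5,
                                    n_scans = 4, seed = 2))
  for (b in wavy) {
    expect_true(all(abs(b$ilm - 16) <= 4.5 + 1e-12))
    expect_true(all(abs(b$cci - 34) <= 4.5 + 1e-12))
    expect_true(all(abs(b$csi - 44) <= 4.5 + 1e-12))
  }

  expect_error(scene_config(mean_rows = c(300, 280, 360)), "ascending")
  expect_error(scene_config(undulation_amplitude = 200), "amplitude")
})

test_that("grader simulation applies bias and noise as specified", {
  truth <- flat_boundaries(16, 34, 44, 512)
  ident <- simulate_grader(truth, grader_profile("g", noise_sd = 0), 64, seed = 1)
  expect_equal(ident$ilm, truth$ilm)
  expect_equal(ident$csi, truth$csi)

  shifted <- simulate_grader(truth, grader_profile("g", bias = c(0, 0, 4),
                                                   noise_sd = 0), 64, seed = 1)
  expect_equal(shifted$csi, truth$csi + 4)
  expect_equal(shifted$ilm, truth$ilm)

  noisy <- simulate_grader(truth,
                           grader_profile("g", noise_sd = 2,
                                          correlation_length = 32L),
                           64, seed = 3)
  dev <- noisy$cci - truth$cci
  expect_lt(abs(sd(dev) - 2) / 2, 0.25)
  # integer rows, ordering restored
  expect_true(all(noisy$ilm == round(noisy$ilm)))
  expect_true(all(noisy$ilm <= noisy$cci & noisy$cci <= noisy$csi))
})

test_that("the consensus model averages grader boundaries", {
  b1 <- flat_boundaries(100, 200, 300, 8)
  expect_equal(simulate_model(list(g1 = b1), consensus_model(c(g1 = 1))), b1)

  b2 <- flat_boundaries(104, 204, 304, 8)
  mid <- simulate_model(list(g1 = b1, g2 = b2),
                        consensus_model(c(g1 = 0.5, g2 = 0.5)))
  expect_equal(mid$ilm, rep(102, 8))
  expect_equal(mid$csi, rep(302, 8))

  expect_error(consensus_model(c(0.5, 0.6)), "sum to 1")
  expect_error(consensus_model(c(-0.5, 1.5)), "non-negative")

  # model ignoring a distant grader sits farthest from that grader
  e <- offset_ensemble(list(g1 = c(0, 0, 1), g2 = c(0, 0, -1),
                            g3 = c(0, 0, 12)),
                       model_offset = c(0, 0, 0), n_scans = 2)
  t <- build_distance_table(e, scopes = "all")
  m <- mean_distance_matrix(t, "all")
  dm <- unclass(m)["cnn", c("g1", "g2", "g3")]
  expect_identical(names(which.max(dm)), "g3")
})

test_that("zero-noise graders obey the analytic offset law exactly", {
  cfg <- small_cfg(n_scans = 2, amplitude = 0)
  truth <- sample_truth(cfg)
  pA <- grader_profile("A", bias = c(2, 0, 4), noise_sd = 0)
  pB <- grader_profile("B", bias = c(-1, 0, -2), noise_sd = 0)
  for (s in names(truth)) {
    a <- lines_to_labelmap(simulate_grader(truth[[s]], pA, 64, 1), 64, 64, s, "A")
    b <- lines_to_labelmap(simulate_grader(truth[[s]], pB, 64, 1), 64, 64, s, "B")
    expect_equal(hamming(a, b), (abs(2 - -1) + abs(4 - -2)) / 64)
  }
})

test_that("augmentation triples the set with mirror and rotation copies", {
  items <- lapply(1:10, function(i)
    list(labelmap = rand_labelmap(20, 16, paste0("s", i), "g1", seed = i)))
  aug <- augment_training_set(items, seed = 4)
  expect_length(aug, 30L)
  expect_equal(vapply(aug, `[[`, "", "augmentation"),
               rep(c("original", "mirrored", "rotated"), each = 10L))
  angles <- vapply(aug[21:30], `[[`, 0, "angle")
  expect_true(all(abs(angles) <= 8))

  # mirrored copy is the column reversal; double mirror restores
  expect_equal(unclass(aug[[11]]$labelmap),
               unclass(items[[1]]$labelmap)[, 16:1], ignore_attr = TRUE)
  expect_equal(unclass(mirror_labelmap(aug[[11]]$labelmap)),
               unclass(items[[1]]$labelmap), ignore_attr = TRUE)

  # rotation by 0 is the identity; any rotation keeps the code alphabet
  m <- items[[3]]$labelmap
  expect_identical(unclass(rotate_labelmap(m, 0)), unclass(m))
  r <- rotate_labelmap(m, 7.3)
  expect_true(all(unclass(r) %in% 0:3))
  expect_identical(dim(r), dim(m))
})

test_that("mirroring both gradings leaves all distances unchanged", {
  e <- simulate_study(small_cfg(n_scans = 2))
  for (s in e$scan_ids[1]) for (p in list(c("g1", "g2"), c("g2", "cnn"))) {
    a <- trex:::ensemble_map(e, s, p[1])
    b <- trex:::ensemble_map(e, s, p[2])
    expect_equal(hamming(mirror_labelmap(a), mirror_labelmap(b)), hamming(a, b))
    expect_equal(compartment_hamming(mirror_labelmap(a), mirror_labelmap(b), "sclera"),
                 compartment_hamming(a, b, "sclera"))
  }
})

test_that("sub-seeded streams make gradings stable when graders are added", {
  cfg <- small_cfg(n_scans = 2, seed = 21)
  two <- simulate_study(cfg, graders = default_graders()[1:2], model = NULL)
  three <- simulate_study(cfg, graders = default_graders(), model = NULL)
  for (s in two$scan_ids) for (g in c("g1", "g2"))
    expect_identical(unclass(trex:::ensemble_map(two, s, g)),
                     unclass(trex:::ensemble_map(three, s, g)))
})

test_that("the pipeline recovers planted grader structure", {
  # graders biased +4 / 0 / -4 rows on the CSI; model averages g1 and g2
  cfg <- scene_config(height = 128, width = 128, mean_rows = c(32, 68, 88),
                      undulation_amplitude = 4, n_scans = 8, seed = 17)
  graders <- list(
    grader_profile("g1", bias = c(0, 0, 4), noise_sd = 0.75),
    grader_profile("g2", bias = c(0, 0, 0), noise_sd = 0.75),
    grader_profile("g3", bias = c(0, 0, -4), noise_sd = 0.75))
  e <- simulate_study(cfg, graders,
                      model = consensus_model(c(g1 = 0.5, g2 = 0.5)))
  t <- build_distance_table(e, scopes = "all")
  m <- unclass(mean_distance_matrix(t, "all"))

  # (a) distance ranking consistent with the planted biases
  expect_gt(m["g1", "g3"], m["g1", "g2"])
  expect_gt(m["g1", "g3"], m["g2", "g3"])
  expect_lt(abs(m["g1", "g2"] - m["g2", "g3"]) / m["g1", "g2"], 0.35)

  # (b) the model's MDS point lies strictly closer to g1 and g2 than to g3
  emb <- mds_embed(mean_distance_matrix(t, "all"))
  xy <- emb$coords
  d_to <- function(g) sqrt(sum((xy["cnn", ] - xy[g, ])^2))
  expect_lt(d_to("g1"), d_to("g3"))
  expect_lt(d_to("g2"), d_to("g3"))

  # (c) systematically smaller model distances drive p to the floor
  g <- assemble_groups(t, c("g1", "g2", "g3"), "cnn")
  r <- mc_permutation_test(g, n_resamples = 999, seed = 2)
  expect_equal(r$p_two_sided, 2 / 1000)
})

test_that("scene configurations round trip through YAML", {
  cfg <- small_cfg()
  graders <- default_graders()
  model <- consensus_model(c(g1 = 0.35, g2 = 0.5, g3 = 0.15))
  path <- tempfile(fileext = ".yaml")
  write_scene_config(cfg, graders, model, path)
  back <- read_scene_config(path)
  expect_equal(back$cfg, cfg)
  expect_equal(back$graders, graders)
  expect_equal(back$model$weights, model$weights)
})
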