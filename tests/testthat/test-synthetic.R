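test_that("fixed seed gives identical outputs", {
  cfg <- synthetic_config(n_frames = 500, seed = 11)
  a <- generate_pocket_trajectory(cfg)
  b <- generate_pocket_trajectory(cfg)
  expect_identical(a, b)
  expect_identical(generate_electronic_records(a$truth, cfg),
                   generate_electronic_records(b$truth, cfg))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_frames = 0), "n_frames")
  expect_error(synthetic_config(
    n_frames = 10,
    residues = list(Q = list(in_mean = 2.9, in_sd = 0.2, out_mean = 6.5,
                             out_sd = 0.8, dwell_in = 0.5, dwell_out = 250))),
    "dwell")
  expect_error(synthetic_config(
    n_frames = 10,
    residues = list(Q = list(in_mean = 2.9, in_sd = -1, out_mean = 6.5,
                             out_sd = 0.8, dwell_in = 250, dwell_out = 250))),
    "sd")
  expect_error(synthetic_config(
    n_frames = 10,
    energy_model = list(IN = list(exc_mean = -3, exc_sd = 0.02,
                                  emi_mean = 2.8, emi_sd = 0.02))),
    "positive")
})

test_that("empirical dwell time matches the geometric-residence mean", {
  # analytic oracle: mean dwell of a geometric residence distribution with
  # leave probability spacing/dwell is exactly dwell/spacing frames
  cfg <- synthetic_config(n_frames = 50000, frame_spacing = 1, seed = 1)
  tr <- generate_pocket_trajectory(cfg)
  dwell <- mean(c(mean_dwell_frames(tr$truth$states[, 1]),
                  mean_dwell_frames(tr$truth$states[, 2])))
  expect_lt(abs(dwell - 250) / 250, 0.10)
})

test_that("symmetric dwell times give half/half occupancies", {
  # fast-switching symmetric chain so that 50k frames hold many independent
  # residence periods; stationary occupancy of each state is exactly 1/2
  res <- list(Q = list(in_mean = 2.9, in_sd = 0.2, out_mean = 6.5,
                       out_sd = 0.8, dwell_in = 20, dwell_out = 20))
  cfg <- synthetic_config(n_frames = 50000, residues = res, seed = 1)
  tr <- generate_pocket_trajectory(cfg)
  occ <- mean(tr$truth$states[, 1] == "in")
  expect_lt(abs(occ - 0.5), 0.02)
})

test_that("distance table matches distances recomputed from the frames", {
  cfg <- synthetic_config(n_frames = 300, seed = 3)
  tr <- generate_pocket_trajectory(cfg)
  defs <- lovpocket:::embedding_defs(tr, cfg)
  rec <- compute_distances(tr$frames, defs)
  expect_lt(max(abs(as.matrix(rec[-1]) - as.matrix(tr$distances[-1]))), 1e-6)
})

test_that("planted class populations converge to the stationary mix", {
  cfg <- planted_three_class_config(50000, seed = 5, class_dwell = 10)
  tr <- generate_pocket_trajectory(cfg)
  pops <- tr$truth$populations[match(c("IN", "OUT_A", "OUT_B"),
                                     tr$truth$population_names)]
  expect_true(all(abs(pops - c(0.78, 0.17, 0.05)) < 0.02))
})

test_that("electronic records recover class-conditional energy means", {
  # two classes, ~1000 frames each; SEM of the class mean is
  # 0.02/sqrt(1000) ~ 0.0006 eV, well inside the 0.005 eV check
  res <- list(Q = list(in_mean = 2.9, in_sd = 0.2, out_mean = 6.5,
                       out_sd = 0.8, dwell_in = 5, dwell_out = 5))
  cfg <- synthetic_config(n_frames = 2000, residues = res, seed = 2)
  tr <- generate_pocket_trajectory(cfg)
  recs <- generate_electronic_records(tr$truth, cfg)
  m_in <- mean(recs$exc_eV[recs$cluster == "IN"])
  m_out <- mean(recs$exc_eV[recs$cluster == "OUT"])
  expect_gt(sum(recs$cluster == "IN"), 500)
  expect_lt(abs(m_in - 3.22), 0.005)
  expect_lt(abs(m_out - 3.27), 0.005)
  expect_true(all(recs$exc_eV > recs$emi_eV))
})

test_that("zero-sd energies reproduce the class means exactly", {
  em <- list(IN  = list(exc_mean = 3.22, exc_sd = 0, emi_mean = 2.82, emi_sd = 0),
             OUT = list(exc_mean = 3.27, exc_sd = 0, emi_mean = 2.88, emi_sd = 0))
  cfg <- synthetic_config(n_frames = 50, energy_model = em, seed = 4)
  tr <- generate_pocket_trajectory(cfg)
  recs <- generate_electronic_records(tr$truth, cfg)
  expect_true(all(recs$exc_eV %in% c(3.22, 3.27)))
  expect_true(all(recs$emi_eV %in% c(2.82, 2.88)))
})

test_that("inverted energy ordering is rejected", {
  em <- list(IN = list(exc_mean = 2.8, exc_sd = 0.02,
                       emi_mean = 3.2, emi_sd = 0.02),
             OUT = list(exc_mean = 3.27, exc_sd = 0.02,
                        emi_mean = 2.88, emi_sd = 0.02))
  cfg <- synthetic_config(n_frames = 50, energy_model = em, seed = 4)
  tr <- generate_pocket_trajectory(cfg)
  expect_error(generate_electronic_records(tr$truth, cfg),
               "emission mean must be below")
  cfg2 <- synthetic_config(n_frames = 50, seed = 4,
                           energy_model = list(
                             OUT = list(exc_mean = 3.27, exc_sd = 0.02,
                                        emi_mean = 2.88, emi_sd = 0.02)))
  tr2 <- generate_pocket_trajectory(cfg2)
  if (any(tr2$truth$class == "IN"))
    expect_error(generate_electronic_records(tr2$truth, cfg2), "no entry")
})

test_that("mode-set generation reports the reorganization energy", {
  sd1 <- generate_mode_set(data.frame(frequency_cm1 = 1400, huang_rhys = 0.7))
  expect_equal(sd1$reorganization, 980)
  sd2 <- generate_mode_set(data.frame(frequency_cm1 = c(1250, 1550),
                                      huang_rhys = c(0.4, 0.3)))
  expect_equal(sd2$reorganization, 965)  # 0.4*1250 + 0.3*1550, by hand
  expect_error(generate_mode_set(data.frame(frequency_cm1 = numeric(0),
                                            huang_rhys = numeric(0))),
               "non-empty")
  expect_error(generate_mode_set(data.frame(frequency_cm1 = -5,
                                            huang_rhys = 0.1)))
  expect_error(generate_mode_set(data.frame(frequency_cm1 = 100,
                                            huang_rhys = -0.1)))
})
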