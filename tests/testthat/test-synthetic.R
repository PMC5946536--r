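test_that("simulation is reproducible from its seed and leaves RNG alone", {
  cfg <- sim_config(seed = 99)
  sched <- assessment_schedule(rest_s = 2)
  set.seed(1234)
  r1 <- simulate_emg(cfg, sched)
  after <- rnorm(1)
  set.seed(1234)
  r2 <- simulate_emg(cfg, sched)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$annotations, r2$annotations)
  expect_identical(rnorm(1), after)   # caller RNG state restored
  # different seeds: different samples, identical ground truth
  cfg2 <- cfg
  cfg2$seed <- 100
  r3 <- simulate_emg(cfg2, sched)
  expect_false(identical(r1$samples, r3$samples))
  expect_identical(r1$annotations, r3$annotations)
})

test_that("steady-state MAV matches the Gaussian envelope prediction", {
  cfg <- identity_config(seed = 8)
  rec <- simulate_emg(cfg, assessment_schedule(rest_s = 2))
  ann <- rec$annotations
  for (k in 1:5) {
    m <- default_motions()[k]
    st <- ann[ann$phase == "steady" & ann$motion == m, ]
    seg <- rec$samples[(st$start + 1L):st$end, , drop = FALSE]
    expected <- sqrt(0.3^2 + cfg$noise_mv^2) * sqrt(2 / pi)
    expect_lt(abs(mean(abs(seg[, k])) - expected) / expected, 0.10)
    # non-target channels sit at the noise floor
    floor_mav <- cfg$noise_mv * sqrt(2 / pi)
    expect_true(all(colMeans(abs(seg[, -k, drop = FALSE])) <
                    3 * floor_mav))
  }
})

test_that("steady-hold MAV error shrinks as the hold grows (seeded)", {
  mean_err <- function(hold) {
    mean(vapply(1:6, function(seed) {
      cfg <- identity_config(seed = 200 + seed)
      rec <- simulate_emg(cfg, motion_schedule("hand close", 1, hold))
      st <- rec$annotations[rec$annotations$phase == "steady", ]
      est <- mean(abs(rec$samples[(st$start + 1L):st$end, "Ch1"]))
      abs(est - sqrt(0.3^2 + cfg$noise_mv^2) * sqrt(2 / pi))
    }, numeric(1L)))
  }
  expect_lt(mean_err(8), mean_err(2))
})

test_that("carrier power stays inside the configured band", {
  cfg <- sim_config(seed = 17, noise_mv = 1e-6)   # isolate the carrier
  rec <- simulate_emg(cfg, motion_schedule("hand close", 0.5, 8))
  st <- rec$annotations[rec$annotations$phase == "steady", ]
  x <- rec$samples[(st$start + 1L):st$end, "Ch1"]
  sp <- stats::spec.pgram(stats::ts(x, frequency = cfg$fs), taper = 0,
                          plot = FALSE)
  inband <- sp$freq >= cfg$carrier_band[1L] & sp$freq <= cfg$carrier_band[2L]
  expect_lt(sum(sp$spec[!inband]) / sum(sp$spec), 0.05)
})

test_that("the default coupled configuration reproduces near-unity
           independence, like the clinical coupling it emulates", {
  cfg <- sim_config()
  recs <- lapply(1:3, function(i) {
    cfg$seed <- i
    simulate_emg(cfg, assessment_schedule(rest_s = 2))
  })
  sc <- independence_score(mav_grid(recs))
  paired <- setdiff(default_motions(), "wrist rotation")
  # theoretical ratio for 0.8 coupling: sqrt(.3^2+.02^2)/sqrt(.24^2+.02^2)
  theory <- sqrt(0.3^2 + 0.02^2) / sqrt(0.24^2 + 0.02^2)
  expect_true(all(abs(sc[paired] - theory) / theory < 0.02))
  expect_gt(sc[["wrist rotation"]], 1)   # only background coupling there
})

test_that("LDA accuracy degrades monotonically with off-diagonal coupling", {
  acc_at <- function(offdiag) {
    accs <- vapply(1:3, function(seed) {
      m <- default_coupling(strong = offdiag, weak = offdiag)
      cfg <- sim_config(coupling = m, seed = seed)
      fit <- trained_model(cfg)
      cfg2 <- cfg
      cfg2$seed <- seed + 50L
      test <- simulate_emg(cfg2, assessment_schedule(rest_s = 2))
      ds <- run_pipeline(test, fit$model, "none")
      score_stream(ds, test)$steady_accuracy
    }, numeric(1L))
    mean(accs)
  }
  accs <- vapply(c(0, 0.5, 1), acc_at, numeric(1L))
  expect_true(all(diff(accs) <= 0))
  expect_gt(accs[1L], 0.95)   # uncoupled channels are easy
})

test_that("training sessions realize the 35 s plan exactly", {
  cfg <- sim_config(seed = 30)
  rec <- make_training_session(cfg, session_plan())
  expect_identical(nrow(rec$samples), 65100L)    # 35 s x 1860 Hz
  expect_equal(duration_s(rec), 35)
  # one steady + one onset-transient annotation per motion, chronological
  ann <- rec$annotations
  expect_setequal(unique(ann$motion), default_motions())
  st <- ann[ann$phase == "steady", ]
  expect_identical(st$motion[order(st$start)], session_plan()$motion_order)
})

test_that("schedule and config constructors reject invalid input", {
  expect_error(motion_schedule("hand close", 0, -1), "parameter error")
  expect_error(motion_schedule(c("a", "b"), c(5, 1), c(1, 1)),
               "chronological")
  expect_error(motion_schedule("a", 0, 1, level = -0.5), "negative")
  expect_error(sim_config(noise_mv = 0), "noise_mv")
  expect_error(sim_config(transient_s = -1), "transient_s")
  bad <- default_coupling()
  bad[1L, 1L] <- -0.2
  expect_error(sim_config(coupling = bad), "coupling")
  cfg <- sim_config()
  expect_error(simulate_emg(cfg, motion_schedule("fist", 0, 1)),
               "missing from coupling")
  expect_error(simulate_emg(cfg, motion_schedule(c("hand close", "hand open"),
                                                 c(0, 2), c(5, 5))),
               "overlapping")
})

test_that("YAML round trip for simulator config and schedule", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(fs = 1000, transient_s = 0.3,
                                noise_mv = 0.05, seed = 4L)), cfg_path)
  cfg <- read_sim_config(cfg_path)
  expect_equal(cfg$fs, 1000)
  expect_equal(cfg$transient_s, 0.3)
  expect_equal(cfg$coupling, default_coupling())
  sched_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(entries = list(
    list(motion = "hand close", onset_s = 1, hold_s = 5),
    list(motion = "hand open", onset_s = 8, hold_s = 5, level = 0.5)))),
    sched_path)
  sched <- read_motion_schedule(sched_path)
  expect_equal(sched$level, c(1, 0.5))
  expect_equal(sched$onset_s, c(1, 8))
})
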