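test_that("bundled presets carry the reference settings", {
  p <- scenario_presets()
  expect_setequal(
    names(p),
    c("figure1-untreated", "figure2-emk", "figure5-adaptive",
      "figure11-reestimation")
  )
  un <- p[["figure1-untreated"]]
  expect_identical(un$controller, "none")
  expect_equal(c(un$model$a, un$model$b, un$model$c), c(1, 2, 9))
  expect_equal(un$config$initial_state, c(0.5, 0))
  expect_null(un$gains)
  em <- p[["figure2-emk"]]
  expect_equal(c(em$gains$k1, em$gains$k2), c(1.1, 10))
  ad <- p[["figure5-adaptive"]]
  expect_equal(c(ad$gains$k1, ad$gains$k2), c(1.22, 10))
  expect_equal(unclass(ad$gamma), diag(0.1, 3), ignore_attr = TRUE)
  expect_equal(ad$config$initial_estimate, c(6, 2.5, 5))
  re <- p[["figure11-reestimation"]]
  expect_identical(re$controller, "adaptive")
  expect_gt(re$config$duration, ad$config$duration)
})

test_that("scenario construction enforces controller/field consistency", {
  m <- ref_model()
  cfg <- sim_config(2)
  expect_error(
    scenario("x", m, "none", gains = control_gains(1, 1), config = cfg),
    class = "moodswing_invalid"
  )
  expect_error(
    scenario("x", m, "adaptive", gains = control_gains(1, 1), gamma = 0.1,
             config = cfg),  # no initial_estimate
    class = "moodswing_invalid"
  )
  expect_error(
    scenario("x", m, "emk", gains = control_gains(1, 1), gamma = 0.1,
             config = cfg),
    class = "moodswing_invalid"
  )
})

test_that("YAML scenarios load, validate, and reject malformed input", {
  example <- system.file("extdata", "emk-example.yaml", package = "moodswing")
  sc <- load_scenario(example)
  expect_identical(sc$controller, "emk")
  expect_equal(c(sc$gains$k1, sc$gains$k2), c(1.1, 10))
  expect_equal(sc$config$duration, 10)
  ad <- load_scenario(system.file("extdata", "adaptive-example.yaml",
                                  package = "moodswing"))
  expect_identical(ad$controller, "adaptive")
  expect_equal(ad$config$initial_estimate, c(6, 2.5, 5))

  write_cfg <- function(text) {
    f <- tempfile(fileext = ".yaml")
    writeLines(text, f)
    f
  }
  base <- c("controller: emk",
            "model: {a: 1, b: 2, c: 9}",
            "gains: {k1: 1.1, k2: 10}",
            "sim: {duration: 10}")
  expect_s3_class(load_scenario(write_cfg(base)), "mood_scenario")
  # unknown key, by name
  err <- tryCatch(load_scenario(write_cfg(c(base, "dose: 3"))), error = identity)
  expect_s3_class(err, "moodswing_unknown_key")
  expect_match(conditionMessage(err), "dose")
  # missing required key
  err <- tryCatch(load_scenario(write_cfg(base[-4])), error = identity)
  expect_s3_class(err, "moodswing_missing_key")
  expect_match(conditionMessage(err), "sim")
  # constraint violation: negative gain
  bad <- sub("k1: 1.1", "k1: -1", base)
  expect_error(load_scenario(write_cfg(bad)), class = "moodswing_invalid")
  # parse failure
  err <- tryCatch(load_scenario(write_cfg("model: [unclosed")), error = identity)
  expect_s3_class(err, "moodswing_parse_error")
  # nonexistent file
  expect_error(load_scenario(file.path(tempdir(), "nope.yaml")),
               class = "moodswing_invalid")
  # a 3x3 matrix adaptation gain given as rows
  mat <- c("controller: adaptive",
           "model: {a: 1, b: 2, c: 9}",
           "gains: {k1: 1.22, k2: 10}",
           "adaptation:",
           "  gamma:",
           "    - [0.2, 0.0, 0.0]",
           "    - [0.0, 0.1, 0.0]",
           "    - [0.0, 0.0, 0.1]",
           "init: {state: [0.5, 0], estimate: [6, 2.5, 5]}",
           "sim: {duration: 10}")
  scm <- load_scenario(write_cfg(mat))
  expect_equal(unclass(scm$gamma), diag(c(0.2, 0.1, 0.1)), ignore_attr = TRUE)
})

test_that("trajectory CSVs round-trip every value exactly", {
  m <- ref_model()
  tr <- simulate_emk(m, control_gains(1.1, 10), sim_config(2, thin = 20L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(names(back), c("t", "x1", "x2", "u", "V"))
  for (col in names(back)) expect_identical(back[[col]], tr[[col]])

  ta <- simulate_adaptive(m, control_gains(1.22, 10), 0.1,
                          sim_config(2, initial_estimate = c(6, 2.5, 5),
                                     thin = 20L))
  fa <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(ta, fa)
  backa <- read_trajectory(fa)
  expect_identical(ncol(backa), 8L)
  expect_identical(attr(backa, "kind"), "adaptive")
  for (col in names(backa)) expect_identical(backa[[col]], ta[[col]])
})

test_that("an empty trajectory writes a header-only file", {
  tr <- simulate_untreated(ref_model(), sim_config(2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr[0, ], f)
  expect_identical(readLines(f), "t,x1,x2,u")
  expect_identical(nrow(read_trajectory(f)), 0L)
})
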