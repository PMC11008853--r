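test_that("the scenario registry covers all 13 study conditions", {
  reg <- scenario_defaults()
  expect_length(reg, 13)
  expect_identical(anyDuplicated(names(reg)), 0L)
  for (sc in reg) {
    tt <- scenario_times(sc)
    expect_equal(tt[1], 0)
    expect_equal(diff(range(tt)), sc$duration_h)
    expect_equal(length(tt), sc$duration_h * 60 / sc$interval_min + 1)
  }
})

test_that("noise-free endpoints hit the quality-control windows and the
           disease/temperature contrasts", {
  reg <- scenario_defaults()
  ep <- vapply(reg, function(sc) {
    v <- scenario_curve(sc)$values
    v[length(v)]
  }, 0)
  for (sc in reg) {
    if (!is.null(sc$qc_window)) {
      expect_gt(ep[[sc$id]], sc$qc_window[1])
      expect_lt(ep[[sc$id]], sc$qc_window[2])
    }
  }
  expect_gt(ep[["psoriasis-imq-24h"]] / ep[["psoriasis-control-24h"]], 4)
  expect_gt(ep[["psoriasis-imq-96h"]] / ep[["psoriasis-control-96h"]], 3.5)
  expect_equal(100 * (ep[["acd-tncb"]] - ep[["acd-control"]]) / ep[["acd-control"]],
               30, tolerance = 1e-8)
  expect_gt(ep[["caffeine-32c-6h"]], ep[["caffeine-rt-6h"]])
})

test_that("every noise-free scenario curve is nonnegative and nondecreasing", {
  for (sc in scenario_defaults()) {
    y <- scenario_curve(sc)$values
    expect_gte(min(y), 0)
    expect_true(all(diff(y) >= 0))
  }
})

test_that("synthetic replicates are deterministic and honest about noise", {
  sc <- scenario_defaults()[["caffeine-rt-6h"]]
  # zero noise: replicates equal the model curve
  g0 <- generate_scenario(sc, noise_model(0, 0), seed = 3)
  for (r in g0$replicates) expect_identical(r$values, g0$noise_free$values)
  # determinism
  g1 <- generate_scenario(sc, seed = 11)
  g2 <- generate_scenario(sc, seed = 11)
  expect_identical(lapply(g1$replicates, `[[`, "values"),
                   lapply(g2$replicates, `[[`, "values"))
  g3 <- generate_scenario(sc, seed = 12)
  expect_false(identical(g1$replicates[[1]]$values, g3$replicates[[1]]$values))
  # replicate mean concentrates on the model curve (unit-mean noise)
  g50 <- generate_scenario(sc, n_replicates = 50, seed = 21)
  vals <- vapply(g50$replicates, `[[`, numeric(13), "values")
  mu <- rowMeans(vals)
  sem <- apply(vals, 1, stats::sd) / sqrt(ncol(vals))
  idx <- which(sem > 0)
  expect_true(all(abs(mu - g50$noise_free$values)[idx] <= 3 * sem[idx]))
})

test_that("sample concentrations convert to cumulative mass per area", {
  # 1 ug/mL at 4 uL/min for 30 min = 0.12 ug per fraction, /0.5 cm2
  y <- concentration_to_cumulative_mass(rep(1, 4), 30)
  expect_equal(y$values, c(0.24, 0.48, 0.72, 0.96))
  expect_equal(y$times, c(0.5, 1, 1.5, 2))
  expect_equal(concentration_to_cumulative_mass(rep(0, 5), 15)$values, rep(0, 5))
  set.seed(9)
  r <- concentration_to_cumulative_mass(stats::runif(20), 15)
  expect_true(all(diff(r$values) >= 0))
  expect_error(concentration_to_cumulative_mass(c(1, -0.1), 30), "nonnegative")
})

test_that("exclusion windows drop out-of-range records and report them", {
  crit <- exclusion_criteria_default()
  w <- data.frame(id = c("m1", "m2", "m3"), attribute = "mouse_body_weight",
                  value = c(19, 25, 33))
  res <- apply_exclusion_criteria(w, crit[crit$attribute == "mouse_body_weight", ])
  expect_identical(res$kept$id, "m2")
  expect_identical(nrow(res$report), 2L)
  expect_setequal(res$report$violation, c("below minimum", "above maximum"))

  caf <- data.frame(id = c("a", "b", "c"), attribute = "caffeine_6h_rt",
                    value = c(18, 35, 55))
  res2 <- apply_exclusion_criteria(caf, crit[crit$attribute == "caffeine_6h_rt", ])
  expect_identical(res2$kept$id, "b")
  expect_identical(sort(res2$report$limit), c(20, 50))

  # bounds are inclusive
  edge <- data.frame(id = c("lo", "hi"), attribute = "mouse_body_weight",
                     value = c(20, 32))
  res3 <- apply_exclusion_criteria(edge, crit[crit$attribute == "mouse_body_weight", ])
  expect_identical(nrow(res3$kept), 2L)

  # idempotence
  res4 <- apply_exclusion_criteria(res$kept, crit[crit$attribute == "mouse_body_weight", ])
  expect_identical(res4$kept, res$kept)
  expect_identical(nrow(res4$report), 0L)

  # empty records
  res5 <- apply_exclusion_criteria(w[0, ], crit[crit$attribute == "mouse_body_weight", ])
  expect_identical(nrow(res5$kept), 0L)
  expect_identical(nrow(res5$report), 0L)

  # criterion targeting an attribute the records do not carry
  expect_error(apply_exclusion_criteria(w, crit), "absent from records")
})

test_that("dataset summaries aggregate replicates and form ratios", {
  tt <- c(1, 2, 3)
  mk <- function(vals, rep, id) observation_series(tt, vals, replicate = rep,
                                                   scenario_id = id)
  single <- summarize_dataset(list(mk(c(1, 2, 3), 1, "a")))
  expect_equal(single$curve$mean, c(1, 2, 3))
  expect_equal(single$curve$sem, c(0, 0, 0))

  trio <- summarize_dataset(list(mk(c(0, 5, 10), 1, "a"),
                                 mk(c(0, 6, 12), 2, "a"),
                                 mk(c(0, 7, 14), 3, "a")))
  expect_equal(trio$curve$mean[3], 12)
  expect_equal(trio$curve$sem[3], 2 / sqrt(3))
  expect_equal(sort(trio$endpoints$endpoint), c(10, 12, 14))

  both <- summarize_dataset(list(mk(c(1, 2, 4), 1, "a"), mk(c(1, 2, 4), 1, "b")),
                            ratio_pairs = list(c("a", "b")))
  expect_equal(both$ratios$ratio, 1)

  expect_error(summarize_dataset(list(mk(c(1, 2, 3), 1, "a"),
                                      observation_series(c(1, 2), c(1, 2),
                                                         replicate = 2,
                                                         scenario_id = "a"))),
               "mismatched")
})

test_that("fitting noise-free synthetic data returns the generating rates", {
  sc <- scenario_defaults()[["psoriasis-imq-24h"]]
  g <- generate_scenario(sc, noise_model(0, 0), n_replicates = 1, seed = 1)
  fit <- multistart_fit(g$replicates[[1]], fit_config(n_starts = 6, seed = 2))
  expect_lt(fit$V_min, 1e-8)
  expect_lt(rel_err(unclass(fit$params), unclass(g$truth)), 1e-3)
})
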