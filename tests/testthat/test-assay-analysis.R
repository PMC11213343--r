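plate_row <- function(construct, conc, bio, tech, fl) {
  tibble::tibble(construct = construct, maltose_mM = conc,
                 biological_rep = bio, technical_rep = tech,
                 fluorescence = fl)
}

test_that("technical replicates collapse to condition means", {
  plate <- dplyr::bind_rows(
    plate_row("A", 0, 1L, 1:3, c(10, 20, 30)),
    plate_row("A", 1, 1L, 1L, 7),
    plate_row("B", 0, 2L, 1:2, c(4, 6))
  )
  agg <- aggregate_technical(plate)
  expect_equal(agg$fluorescence[agg$construct == "A" & agg$maltose_mM == 0], 20)
  expect_equal(agg$fluorescence[agg$construct == "A" & agg$maltose_mM == 1], 7)
  expect_equal(nrow(agg), 3L)

  # grouping agrees with an independent base-R aggregate
  set.seed(3)
  big <- tidyr::expand_grid(construct = c("A", "B"), maltose_mM = c(0, 1),
                            biological_rep = 1:2, technical_rep = 1:3)
  big$fluorescence <- stats::runif(nrow(big), 10, 100)
  got <- aggregate_technical(big)
  want <- stats::aggregate(
    fluorescence ~ construct + maltose_mM + biological_rep, data = big, FUN = mean)
  merged <- merge(got, want, by = c("construct", "maltose_mM", "biological_rep"))
  expect_equal(merged$fluorescence.x, merged$fluorescence.y, tolerance = 1e-12)
})

test_that("background subtraction uses the matching-concentration control mean", {
  agg <- dplyr::bind_rows(
    plate_row("A", 0, 1L, 1L, 120),
    plate_row("A", 1, 1L, 1L, 20),
    plate_row("pET28a", 0, 1L, 1L, 15),
    plate_row("pET28a", 0, 2L, 1L, 25),
    plate_row("pET28a", 1, 1L, 1L, 20)
  )[, -4L]  # already aggregated: drop technical_rep
  out <- background_subtract(agg)
  expect_equal(out$fluorescence[out$maltose_mM == 0], 100)  # 120 - mean(15,25)
  expect_equal(out$fluorescence[out$maltose_mM == 1], 0)

  no_ctrl_1mm <- agg[agg$maltose_mM == 0 | agg$construct == "A", ]
  expect_error(background_subtract(no_ctrl_1mm), "1 mM")
  expect_error(background_subtract(agg[agg$construct == "A", ]), "pET28a")
})

test_that("dF/F0 follows the ratio definition with the zero-baseline guard", {
  expect_equal(delta_f_over_f0(100, 125), 0.25)
  expect_equal(delta_f_over_f0(50, 50), 0)
  expect_equal(delta_f_over_f0(22, 72), 2.2727, tolerance = 1e-4)
  expect_warning(na <- delta_f_over_f0(0, 10), "undefined")
  expect_true(is.na(na))
})

test_that("viability is an absolute-threshold any-concentration call", {
  m <- tibble::tibble(
    construct = c("a", "b", "b", "c"),
    dff0_mean = c(0.741, 0.24, 0.10, -0.30)
  )
  v <- classify_viability(m, threshold = 0.25)
  expect_equal(v$viable[v$construct == "a"], TRUE)
  expect_equal(v$viable[v$construct == "b"], FALSE)
  expect_equal(v$viable[v$construct == "c"], TRUE)
})

test_that("biological summaries use the sample SD", {
  s <- summarize_biological(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(summarize_biological(rep(4, 3))$sd, 0)
  expect_true(is.na(summarize_biological(7)$sd))

  set.seed(23)
  for (k in 1:20) {
    x <- stats::rnorm(sample(2:10, 1L))
    # two-pass oracle
    want <- sqrt(sum((x - mean(x))^2) / (length(x) - 1L))
    expect_equal(summarize_biological(x)$sd, want, tolerance = 1e-12)
  }
})

test_that("the noiseless pipeline inverts the generator exactly", {
  truth <- plate_truth()
  plate <- generate_plate_assay(truth, noise_sigma = 0, seed = NULL)
  m <- sensor_metrics(plate)
  joined <- dplyr::inner_join(tibble::as_tibble(m), truth,
                              by = c("construct", "maltose_mM"))
  expect_equal(joined$dff0_mean, joined$dff0, tolerance = 1e-12)
  expect_equal(joined$dff0_sd, rep(0, nrow(joined)), tolerance = 1e-12)
  # pooled order gives the same answer without noise
  mp <- sensor_metrics(plate, method = "pooled")
  joined_p <- dplyr::inner_join(tibble::as_tibble(mp), truth,
                                by = c("construct", "maltose_mM"))
  expect_equal(joined_p$dff0_mean, joined_p$dff0, tolerance = 1e-12)
})

test_that("noisy plates recover the true dF/F0 within 3 SE", {
  # per-condition means pooled over independent simulated plates: the
  # pooled mean must sit within 3 standard errors of the generating truth
  truth <- plate_truth()
  per_seed <- purrr::map_dfr(1:20, function(s) {
    plate <- generate_plate_assay(truth, noise_sigma = 12, seed = 100L + s)
    tibble::as_tibble(sensor_metrics(plate))
  })
  pooled <- dplyr::summarise(
    dplyr::group_by(per_seed, construct, maltose_mM),
    est = mean(dff0_mean), se = stats::sd(dff0_mean) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  joined <- dplyr::inner_join(pooled, truth, by = c("construct", "maltose_mM"))
  expect_true(all(abs(joined$est - joined$dff0) <= 3 * joined$se))
})

test_that("dF/F0 is invariant to rescaling all fluorescence values", {
  plate <- generate_plate_assay(plate_truth(), noise_sigma = 5, seed = 9L)
  m1 <- tibble::as_tibble(sensor_metrics(plate))
  plate2 <- dplyr::mutate(plate, fluorescence = fluorescence * 3.7)
  m2 <- tibble::as_tibble(sensor_metrics(plate2))
  expect_equal(m1$dff0_mean, m2$dff0_mean, tolerance = 1e-10)
})

test_that("sensor metrics expose viability and glance summaries", {
  plate <- generate_plate_assay(plate_truth(), noise_sigma = 0, seed = NULL)
  m <- sensor_metrics(plate)
  v <- attr(m, "viability")
  expect_true(v$viable[v$construct == "MBP_233-cpGFP"])
  expect_false(v$viable[v$construct == "MBP_131-cpGFP"])
  g <- glance(m)
  expect_equal(g$n_viable, 2L)
  expect_equal(g$threshold, 0.25)
})
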