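test_that("the source-sink estimator reproduces hand-computed rates", {
  # ((0.01 - 0.003663) / ((0.776 - 0.003663) * 7)) * 4 umol -> nmol/h
  est <- ammonification_rate(0.776, 0.003663, 0.01, t = 7, mean_nh4 = 4)
  hand <- (0.01 - 0.003663) / ((0.776 - 0.003663) * 7) * 4 * 1000
  expect_equal(est$value, hand, tolerance = 1e-12)
  expect_equal(est$value, 4.6886, tolerance = 1e-4)
  expect_equal(est$units, "nmol_h")

  # no sink movement -> zero; linearity in the sink gain
  expect_equal(ammonification_rate(0.776, 0.01, 0.01, 7, 4)$value, 0)
  base <- ammonification_rate(0.776, 0.003663, 0.010, 7, 4)$value
  doubled <- ammonification_rate(0.776, 0.003663,
                                 0.003663 + 2 * (0.010 - 0.003663),
                                 7, 4)$value
  expect_equal(doubled, 2 * base, tolerance = 1e-12)
})

test_that("estimator guards: degenerate gradients, bad windows, flags", {
  expect_error(ammonification_rate(0.01, 0.01, 0.02, 7, 4), "degenerate")
  expect_error(ammonification_rate(0.776, 0.003, 0.01, 0, 4), "positive")
  expect_error(ammonification_rate(0.776, 0.003, 0.01, 7, 0), "positive")
  neg <- ammonification_rate(0.776, 0.01, 0.005, 7, 4)
  expect_lt(neg$value, 0)
  expect_equal(neg$flag, "negative")
  # the literal published numerator is available for audit and is
  # negative whenever the sink sits below the source
  printed <- ammonification_rate(0.776, 0.003663, 0.01, 7, 4,
                                 printed_form = TRUE)
  expect_lt(printed$value, 0)
})

test_that("the estimate grows with sink enrichment and pool size", {
  sink <- seq(0.004, 0.05, length.out = 20)
  vals <- vapply(sink, function(s) {
    ammonification_rate(0.776, 0.003663, s, 7, 4)$value
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  pools <- seq(0.5, 10, length.out = 20)
  vals2 <- vapply(pools, function(p) {
    ammonification_rate(0.776, 0.003663, 0.01, 7, p)$value
  }, numeric(1))
  expect_true(all(diff(vals2) > 0))
})

test_that("the estimator inverts forward data built on its own assumptions", {
  for (rate in c(1, 5, 20)) {
    rec <- eq1_forward_records(rate)
    est <- estimate_ammonification(rec, intervals = "full")
    expect_equal(est$value, rate, tolerance = 1e-9)
  }
})

test_that("night partitioning anchors the sink at the day-end mean", {
  est <- night_rate_partition(c(0.008), 0.015, 0.776, 13.3, 4)
  hand <- (0.015 - 0.008) / ((0.776 - 0.008) * 13.3) * 4 * 1000
  expect_equal(est$value, hand, tolerance = 1e-12)
  expect_equal(est$value, 2.7412, tolerance = 1e-4)
  expect_equal(est$interval, "night")
  # morning equal to the day-end mean -> zero
  expect_equal(night_rate_partition(c(0.007, 0.009), 0.008, 0.776,
                                    13.3, 4)$value, 0)
  # several day-end bottles: anchored at their arithmetic mean
  multi <- night_rate_partition(c(0.006, 0.010), 0.015, 0.776, 13.3, 4)
  expect_equal(multi$value,
               night_rate_partition(0.008, 0.015, 0.776, 13.3, 4)$value,
               tolerance = 1e-12)
  expect_error(night_rate_partition(numeric(0), 0.01, 0.776, 13, 4),
               "nonempty")
})

test_that("host attribution subtracts the seawater-only cell mean", {
  rates <- dplyr::bind_rows(
    rate_estimate(6, interval = "day", attribution = "bottle_total",
                  bottle_id = "sg1", site = "control", treatment = "seagrass"),
    rate_estimate(5, interval = "day", attribution = "bottle_total",
                  bottle_id = "sg2", site = "control", treatment = "seagrass"),
    rate_estimate(3, interval = "day", attribution = "bottle_total",
                  bottle_id = "sg3", site = "control", treatment = "seagrass"),
    rate_estimate(1.5, interval = "day", attribution = "seawater_only",
                  bottle_id = "sw1", site = "control",
                  treatment = "seawater_only"),
    rate_estimate(2.5, interval = "day", attribution = "seawater_only",
                  bottle_id = "sw2", site = "control",
                  treatment = "seawater_only"))
  out <- attribute_host_rate(rates)
  host <- out[out$attribution == "host_attributed", ]
  # brute-force per-row subtraction
  expect_equal(host$value[match(c("sg1", "sg2", "sg3"), host$bottle_id)],
               c(6, 5, 3) - mean(c(1.5, 2.5)), tolerance = 1e-12)
  # a bottle equal to the seawater mean attributes exactly zero
  zero <- attribute_host_rate(dplyr::bind_rows(
    rate_estimate(2, interval = "day", bottle_id = "sg", site = "control",
                  treatment = "seagrass"),
    rate_estimate(2, interval = "day", attribution = "seawater_only",
                  bottle_id = "sw", site = "control",
                  treatment = "seawater_only")))
  expect_equal(zero$value[zero$attribution == "host_attributed"], 0)
  # per-cell mean identity: mean(host) + mean(sw) = mean(bottle totals)
  expect_equal(mean(host$value) + mean(c(1.5, 2.5)),
               mean(c(6, 5, 3)), tolerance = 1e-12)
  # negative attributions flagged, not dropped
  neg <- attribute_host_rate(dplyr::bind_rows(
    rate_estimate(1, interval = "day", bottle_id = "sg", site = "control",
                  treatment = "seagrass"),
    rate_estimate(2, interval = "day", attribution = "seawater_only",
                  bottle_id = "sw", site = "control",
                  treatment = "seawater_only")))
  h <- neg[neg$attribution == "host_attributed", ]
  expect_equal(h$flag, "negative")
  # a missing seawater cell is an error that names the cell
  expect_error(attribute_host_rate(
    rate_estimate(1, interval = "night", bottle_id = "sg",
                  site = "vent", treatment = "seagrass")),
    "vent x night")
})

test_that("tissue uptake reproduces the atom-percent-excess arithmetic", {
  s <- tissue_sample("meristem", dry_mass = 0.5, percent_n = 2.1,
                     atom_fraction_15n = 0.0041630,
                     baseline_atom_fraction_15n = 0.0036630)
  n_t <- 0.5 * 2.1 / 100 / 14.0067 * 1e6   # ~749.6 umol
  expect_equal(s$n_umol, n_t, tolerance = 1e-12)
  est <- nitrogen_uptake_rate(s, mean_pool_enrichment = 0.05, t = 7)
  expect_equal(est$value, 5e-4 / (0.05 * 7) * n_t / 0.5, tolerance = 1e-12)
  expect_equal(est$value, 2.1418, tolerance = 1e-3)
  expect_equal(est$units, "umol_gDM_h")
  # zero excess -> zero rate; negative excess -> flagged
  s0 <- tissue_sample("meristem", dry_mass = 0.5, percent_n = 2.1,
                      atom_fraction_15n = 0.0036630,
                      baseline_atom_fraction_15n = 0.0036630)
  expect_equal(nitrogen_uptake_rate(s0, 0.05, 7)$value, 0)
  sneg <- tissue_sample("meristem", dry_mass = 0.5, percent_n = 2.1,
                        atom_fraction_15n = 0.0030,
                        baseline_atom_fraction_15n = 0.0036630)
  expect_equal(nitrogen_uptake_rate(sneg, 0.05, 7)$flag, "negative")
  expect_error(nitrogen_uptake_rate(s, 0, 7), "positive")
  # POM variant normalises per litre filtered
  pom <- tissue_sample("pom_filter", atom_fraction_15n = 0.01,
                       baseline_atom_fraction_15n = 0.0036630,
                       n_umol = 0.66)
  est_pom <- nitrogen_uptake_rate(pom, 0.05, 7, filtered_volume = 0.4)
  expect_equal(est_pom$units, "umol_L_h")
  expect_equal(est_pom$value,
               (0.01 - 0.0036630) / (0.05 * 7) * 0.66 / 0.4,
               tolerance = 1e-12)
})

test_that("uptake estimates recover simulator truth on noiseless bottles", {
  ex <- simulate_experiment(design = recovery_uptake_params(),
                            spikes = recovery_uptake_spikes(),
                            n_replicates = 4, noise = zero_noise(),
                            seed = 8)
  up <- estimate_uptake(ex, what = "tissue")
  day <- up$value[up$interval == "day"]
  expect_equal(mean(day), 1.2, tolerance = 0.05)
})

test_that("oxygen-to-carbon conversion follows the photosynthetic quotient", {
  est <- oxygen_to_carbon_rate(100, t = 7, dry_mass = 0.5,
                               water_column_rate = 10 / 7)
  hand <- (100 / 7 - 10 / 7) * 12.011 / 1000 / 0.5
  expect_equal(est$value, hand, tolerance = 1e-12)
  expect_equal(est$value, 0.3089, tolerance = 1e-3)
  expect_equal(est$units, "mgC_gDM_h")
  # water-column only, per litre
  wc <- oxygen_to_carbon_rate(33, t = 6, volume = 1)
  expect_equal(wc$value, 33 / 6 * 12.011 / 1000, tolerance = 1e-12)
  expect_equal(wc$value, 0.0661, tolerance = 1e-3)
  expect_equal(wc$units, "mgC_L_h")
  # nighttime O2 decline comes out as flagged respiration
  night <- oxygen_to_carbon_rate(-50, t = 14, dry_mass = 0.5)
  expect_lt(night$value, 0)
  expect_equal(night$flag, "negative")
  # halving the quotient doubles the carbon rate
  pq2 <- oxygen_to_carbon_rate(100, t = 7, dry_mass = 0.5, pq = 0.5)
  pq1 <- oxygen_to_carbon_rate(100, t = 7, dry_mass = 0.5, pq = 1)
  expect_equal(pq2$value, 2 * pq1$value, tolerance = 1e-12)
})

test_that("amplification is the fold increase times the C:N ratio", {
  a <- amplification_factor(1.6, 1, 5.09)
  expect_equal(a$fold_n, 1.6, tolerance = 1e-12)
  expect_equal(a$amplification, 1.6 * 5.09, tolerance = 1e-12)
  b <- amplification_factor(2.5, 1, 5.97)
  expect_equal(b$amplification, 14.925, tolerance = 1e-12)
  # fold of 1 collapses to the C:N ratio itself
  expect_equal(amplification_factor(3, 3, 5.09)$amplification, 5.09,
               tolerance = 1e-12)
  # strictly increasing in both inputs
  expect_gt(amplification_factor(1.7, 1, 5.09)$amplification,
            a$amplification)
  expect_gt(amplification_factor(1.6, 1, 5.2)$amplification,
            a$amplification)
  expect_error(amplification_factor(1, 0, 5), "positive")
})

test_that("net fluxes carry the production/uptake sign convention", {
  expect_equal(net_flux(10, 8, 6), -1 / 3, tolerance = 1e-12)
  expect_equal(net_flux(4.2, 4.2, 10), 0)
  expect_equal(net_flux(0, 3, 3), 1)
  expect_error(net_flux(1, 2, 0), "positive")
})

test_that("factorial ANOVA decomposes planted effects sensibly", {
  set.seed(31)
  # equal means -> F near 0 for two equal-mean groups
  d <- data.frame(y = rep(c(5, 5), each = 20) + rnorm(40, 0, 1e-9),
                  g = rep(c("a", "b"), each = 20))
  out <- factorial_anova(d, "y", "g")
  expect_lt(out$statistic[out$term == "g"], 1)
  expect_gt(out$p_value[out$term == "g"], 0.1)

  # a planted 5-sd site effect is detected essentially always
  hits <- 0
  for (i in 1:50) {
    n <- 8
    dd <- data.frame(
      site = rep(c("control", "vent"), each = n),
      treatment = rep(c("sg", "sw"), times = n),
      y = rnorm(2 * n, 10, 1) + rep(c(0, 5), each = n))
    res <- factorial_anova(dd, "y", c("site", "treatment"))
    if (res$p_value[res$term == "site"] < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 48)

  # the log switch equals manual logging
  dd <- data.frame(y = exp(rnorm(24, 1, 0.3)),
                   a = rep(c("x", "y"), 12),
                   b = rep(c("u", "v"), each = 12))
  auto <- factorial_anova(dd, "y", c("a", "b"), log_transform = TRUE)
  dd$ly <- log(dd$y)
  manual <- factorial_anova(dd, "ly", c("a", "b"))
  expect_equal(auto$statistic, manual$statistic, tolerance = 1e-10)
  expect_error(factorial_anova(
    data.frame(y = c(-1, 1, 2, 3), g = c("a", "a", "b", "b")),
    "y", "g", log_transform = TRUE), "positive")
  # empty cells make interactions inestimable
  bad <- data.frame(y = c(1, 2, 3, 4, 5),
                    a = c("x", "x", "y", "y", "y"),
                    b = c("u", "v", "u", "u", "u"))  # cell y x v empty
  expect_error(factorial_anova(bad, "y", c("a", "b")), "cells")
})
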