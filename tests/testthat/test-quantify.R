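# Molecule counting and statistics

test_that("single-fluorophore fit recovers known Gaussian parameters", {
  set.seed(41)
  x <- rnorm(5000, 1000, 150)
  cm <- fit_single_fluorophore(x)
  expect_lt(abs(cm$unit_mu_adu - 1000) / 1000, 0.02)
  expect_lt(abs(cm$unit_sigma_adu - 150) / 150, 0.10)
  expect_gt(cm$fit_quality, 0.9)
  expect_equal(cm$n_calibration_spots, 5000L)
})

test_that("degenerate and contaminated calibration inputs are handled", {
  cm <- fit_single_fluorophore(rep(800, 150))
  expect_equal(cm$unit_mu_adu, 800)
  expect_equal(cm$unit_sigma_adu, 0)
  # dimer contamination at 2 mu: fit restricted to the dominant mode
  set.seed(42)
  xb <- c(rnorm(4000, 1000, 150), rnorm(1000, 2000, 212))
  cmb <- fit_single_fluorophore(xb)
  expect_lt(abs(cmb$unit_mu_adu - 1000) / 1000, 0.05)
  expect_error(fit_single_fluorophore(rnorm(50, 1000, 100)), "at least 100")
  # peak indistinguishable from zero is refused
  set.seed(43)
  expect_error(fit_single_fluorophore(abs(rnorm(2000, 100, 400))),
               "unreliable|not positive|converge")
})

test_that("ratio counting is the exact intensity ratio", {
  cal <- structure(list(unit_mu_adu = 1000, unit_sigma_adu = 100),
                   class = "calibration_model")
  expect_equal(counts_by_ratio(5000, cal)$counts, 5)
  r <- counts_by_ratio(c(1000, 2000, 3000), cal)
  expect_equal(r$counts, c(1, 2, 3))
  expect_equal(r$mean_count, 2)
})

test_that("ratio counting recovers a Poisson copy-number mean from a scene", {
  # particles with true counts ~ zero-truncated Poisson(10), unit CV 20%
  p <- scene_params(field_size_px = c(500L, 500L),
                    particle_density_per_um2 = 0.05,
                    category_probs = c(0, 0, 1, 0, 0, 0, 0),  # CD63+ sEVs
                    seed = 60)
  sc <- quiet(generate_scene(p))
  truth_mean <- 10 / (1 - exp(-10))   # zero-truncated Poisson mean
  cal <- structure(list(unit_mu_adu = 1000, unit_sigma_adu = 150),
                   class = "calibration_model")
  got <- counts_by_ratio(sc$truth$intensity_CD63, cal)
  expect_gt(nrow(sc$truth), 500)
  expect_lt(abs(got$mean_count - truth_mean) / truth_mean, 0.10)
})

test_that("deconvolution identifies a single n-fold component", {
  cal <- list(unit_mu_adu = 1000, unit_sigma_adu = 150)
  set.seed(44)
  x <- rnorm(5000, 3000, sqrt(3) * 150)
  d <- counts_by_deconvolution(x, cal, n_max = 10)
  expect_gte(d$weights[3], 0.9)
  expect_equal(sum(d$weights), 1, tolerance = 1e-9)
  expect_true(all(d$weights >= 0))
})

test_that("deconvolution recovers a two-component mixture within TV 0.1", {
  cal <- list(unit_mu_adu = 1000, unit_sigma_adu = 150)
  set.seed(45)
  comp <- sample(c(2, 5), 10000, replace = TRUE)
  x <- rnorm(10000, comp * 1000, sqrt(comp) * 150)
  d <- counts_by_deconvolution(x, cal, n_max = 20)
  truth <- numeric(20); truth[2] <- 0.5; truth[5] <- 0.5
  tv <- 0.5 * sum(abs(d$weights - truth))
  expect_lt(tv, 0.1)
  # ratio and deconvolution means agree within 15%
  r <- counts_by_ratio(x, structure(cal, class = "calibration_model"))
  expect_lt(abs(d$mean_count - r$mean_count) /
              r$mean_count, 0.15)
})

test_that("NNLS deconvolution matches a dense grid-search oracle", {
  cal <- list(unit_mu_adu = 1000, unit_sigma_adu = 100)
  set.seed(46)
  w_true <- 0.3
  comp <- ifelse(runif(4000) < w_true, 2, 5)
  x <- rnorm(4000, comp * 1000, sqrt(comp) * 100)
  d <- counts_by_deconvolution(x, cal, n_max = 8, ridge = 0)
  # oracle: exhaustive search over the 2-component weight simplex using the
  # same binned histogram
  bw <- 250
  edges <- seq(0, max(x) + 3 * 100 * sqrt(8) + bw, by = bw)
  dens <- hist(pmin(pmax(x, 0), max(edges) - 1e-9), breaks = edges,
               plot = FALSE)$counts
  dens <- dens / sum(dens)
  m2 <- diff(pnorm(edges, 2000, sqrt(2) * 100))
  m5 <- diff(pnorm(edges, 5000, sqrt(5) * 100))
  grid <- seq(0, 1, by = 1e-4)
  rss <- vapply(grid, function(w) sum((dens - (w * m2 + (1 - w) * m5))^2),
                numeric(1))
  w_oracle <- grid[which.min(rss)]
  expect_lt(abs(d$weights[2] - w_oracle), 1e-3)
  expect_lt(abs(d$weights[5] - (1 - w_oracle)), 1e-3)
})

test_that("deconvolution warns when the unit distribution is too wide", {
  cal <- list(unit_mu_adu = 100, unit_sigma_adu = 300)
  set.seed(47)
  x <- abs(rnorm(600, 500, 300))
  expect_warning(counts_by_deconvolution(x, cal, n_max = 10),
                 "ill-conditioned")
  expect_error(counts_by_deconvolution(rnorm(100, 1000, 10),
                                       list(unit_mu_adu = 1000,
                                            unit_sigma_adu = 10)),
               "at least 500")
})

test_that("pairwise correlation: exact, null, and copula recovery", {
  mkparts <- function(x, y) data.frame(
    field_id = "f", x_px = 0, y_px = 0,
    pos_COE = TRUE, pos_CFSE = TRUE, pos_CD63 = FALSE,
    intensity_COE = x, intensity_CFSE = y, intensity_CD63 = 0,
    label = "sEV CFSE+CD63-", flag_edge = FALSE, flag_aggregate = FALSE,
    flag_string = FALSE)
  x <- seq(1000, 5000, length.out = 100)
  expect_equal(pairwise_correlation(mkparts(x, x))$r, 1)
  # independent log-normals: |r| < 0.05 in >= 95% of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(5000 + s)
    a <- rlnorm(2000, log(8000), log(1.8))
    b <- rlnorm(2000, log(8000), log(1.8))
    abs(cor(log(a), log(b))) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # latent copula rho = 0.8 recovered on the log scale at n = 2000
  p <- scene_params(seed = 61)
  content <- sevpimage:::with_seed(
    61, sevpimage:::draw_particle_content(2000, rep(1L, 2000), p))
  parts <- mkparts(content$intensity_COE, content$intensity_CFSE)
  r <- pairwise_correlation(parts, markers = c("COE", "CFSE"), log = TRUE)
  expect_lt(abs(r$r - 0.8), 0.05)
  expect_error(pairwise_correlation(mkparts(x, x)[1:10, ]), "need >= 30")
})

test_that("size proxy is the square root of membrane intensity", {
  expect_equal(size_proxy(0), 0)
  expect_equal(size_proxy(c(1, 4, 9)), c(1, 2, 3))
  expect_error(size_proxy(-1), "negative")
  # diameters mapped through area come back linearly
  d <- seq(60, 110, by = 5)
  intens <- 0.9 * d^2
  fit <- lm(size_proxy(intens) ~ d)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.99)
  expect_lt(abs(coef(fit)[2] - sqrt(0.9)) / sqrt(0.9), 0.02)
})

test_that("normalized variance matches the closed form and is scale-free", {
  expect_equal(normalized_variance(c(5, 5, 5)), 0)
  expect_equal(normalized_variance(c(1, 2, 3)), 1 / 6)
  expect_equal(normalized_variance(7 * c(1, 2, 3)),
               normalized_variance(c(1, 2, 3)))
  expect_error(normalized_variance(2), "at least 2")
  expect_error(normalized_variance(c(0, 0)), "zero")
})

test_that("captured fraction follows the mass-balance arithmetic", {
  expect_equal(captured_fraction(0, 65, 1e8, 0.1), 0)
  expect_warning(f <- captured_fraction(0.37, 65, 1e8, 0.1),
                 "mass-balance")
  expect_equal(f, 2.405)
  # linear in density, inverse-linear in concentration (exact identities)
  f1 <- captured_fraction(0.1, 65, 1e9, 0.1)
  expect_equal(captured_fraction(0.2, 65, 1e9, 0.1), 2 * f1)
  expect_equal(captured_fraction(0.1, 65, 2e9, 0.1), f1 / 2)
  expect_error(captured_fraction(0.1, 65, 0, 0.1), "bulk")
})

test_that("group comparison is calibrated and powered", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # N(0,1) vs N(3,1), n = 5: empirical power matches the closed-form
  # power.t.test oracle, and the effect is nearly always caught at 0.05
  p01 <- vapply(1:400, function(s) {
    set.seed(6000 + s)
    compare_groups(rnorm(5), rnorm(5, 3))$p_value
  }, numeric(1))
  want <- power.t.test(n = 5, delta = 3, sd = 1, sig.level = 0.01,
                       type = "two.sample")$power
  expect_lt(abs(mean(p01 < 0.01) - want), 0.05)
  expect_gte(mean(p01 < 0.05), 0.95)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("pixel-length conversions match the acquisition geometry", {
  expect_equal(physical_length(30, 0.25), 7.5)
  expect_equal(physical_length(50, 0.25), 12.5)
  expect_equal(physical_length(0), 0)
  expect_equal(plan_acquisition(65, c(100, 100)), 6500L)
  expect_equal(plan_acquisition(1, c(1000, 1000)), 1L)
  expect_equal(plan_acquisition(0.5, c(100, 100)), 50L)
})

test_that("subpopulation summary aggregates content per label", {
  pt <- particles_from_truth(std_scene$truth)
  cal <- structure(list(unit_mu_adu = 1000, unit_sigma_adu = 150),
                   class = "calibration_model")
  s <- subpopulation_summary(pt, cal)
  expect_setequal(s$table$label, subpop_labels())
  expect_equal(sum(s$table$n), sum(!pt$flag_edge))
  # CD63-negative labels have no CD63 mean
  expect_true(is.na(s$table$mean_CD63[s$table$label == "sEV CFSE+CD63-"]))
  expect_true(all(s$variance >= 0, na.rm = TRUE))
})
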