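test_that("spot generation is deterministic under a seed", {
  cfg <- synthetic_cohort_config(n_patients = 2, n_markers = 6,
                                 n_epithelial = 60, n_stromal = 60,
                                 seed = 3)
  a <- generate_spot(cfg, seed = 99)
  b <- generate_spot(cfg, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_spot(cfg, seed = 100)
  expect_false(identical(a$M01, c$M01))
})

test_that("spot geometry separates the compartments radially", {
  cfg <- synthetic_cohort_config(n_markers = 4, n_epithelial = 200,
                                 n_stromal = 200, seed = 1)
  spot <- generate_spot(cfg, seed = 7)
  r <- sqrt((spot$x - 300)^2 + (spot$y - 300)^2)
  expect_true(all(r[spot$ecad_positive] <= cfg$blob_radius_um + 1e-9))
  expect_true(all(r[!spot$ecad_positive] >= cfg$blob_radius_um - 1e-9))
  expect_true(all(r <= cfg$spot_diameter_um / 2 + 1e-9))
})

test_that("zero factor loadings leave markers uncorrelated", {
  cfg <- synthetic_cohort_config(n_markers = 4, n_epithelial = 500,
                                 n_stromal = 100, loading_sd = 0,
                                 n_factors = 2, seed = 2)
  spot <- generate_spot(cfg, seed = 21)
  epi <- spot[spot$ecad_positive, ]
  taus <- combn(cfg$markers, 2, function(p) {
    kendall_tau(epi[[p[1]]], epi[[p[2]]])
  })
  expect_true(all(abs(taus) < 0.1))
})

test_that("a planted shared factor raises the pair's tau in its domain only", {
  cfg <- synthetic_cohort_config(n_markers = 4, n_epithelial = 500,
                                 n_stromal = 500, loading_sd = 0,
                                 tau_loading = 2, seed = 3)
  st <- list(loadings = domainsurv:::.baseline_loadings(cfg),
             drivers = list(list(type = "tau", domain = "epithelial",
                                 m = c(1L, 2L), value = 2,
                                 feature = "tau__M01__M02")))
  spot <- generate_spot(cfg, st, seed = 31)
  epi <- spot[spot$ecad_positive, ]
  str <- spot[!spot$ecad_positive, ]
  tau_epi <- kendall_tau(epi$M01, epi$M02)
  tau_str <- kendall_tau(str$M01, str$M02)
  expect_gte(tau_epi - tau_str, 0.3)
})

test_that("generated taus approach the latent-model value in large spots", {
  cfg <- synthetic_cohort_config(n_markers = 3, n_epithelial = 2000,
                                 n_stromal = 50, loading_sd = 0,
                                 tau_loading = 1.5, cell_sd = 1, seed = 4)
  st <- list(loadings = domainsurv:::.baseline_loadings(cfg),
             drivers = list(list(type = "tau", domain = "epithelial",
                                 m = c(1L, 2L), value = 10,  # strength -> 1.5
                                 feature = "tau__M01__M02")))
  spot <- generate_spot(cfg, st, seed = 41)
  epi <- spot[spot$ecad_positive, ]
  # bivariate normal with shared loading s on unit noise:
  # r = s^2/(s^2+1), tau = 2/pi asin(r)
  r_target <- 1.5^2 / (1.5^2 + 1)
  tau_target <- 2 / pi * asin(r_target)
  expect_lt(abs(kendall_tau(epi$M01, epi$M02) - tau_target), 0.05)
})

test_that("null cohorts carry no survival signal and planted ones do", {
  cfg0 <- synthetic_cohort_config(n_patients = 150, n_markers = 4,
                                  n_epithelial = 30, n_stromal = 30,
                                  target_event_frac = 0.3, seed = 5)
  ch0 <- generate_cohort(cfg0, seed = 5)
  expect_true(all(ch0$truth$eta == 0))

  planted <- data.frame(domain = "epithelial", feature = "mean__M01",
                        beta = log(3))
  cfg1 <- synthetic_cohort_config(n_patients = 400, n_markers = 4,
                                  n_epithelial = 30, n_stromal = 30,
                                  planted = planted,
                                  target_event_frac = 0.3, seed = 6)
  ch1 <- generate_cohort(cfg1, seed = 6)
  cidx <- survival::concordance(
    survival::coxph(survival::Surv(ch1$surv$time, ch1$surv$event) ~
                      ch1$truth$eta))$concordance
  expect_gt(cidx, 0.7)
  # ground-truth risk is monotone in the planted driver
  expect_equal(ch1$truth$eta,
               log(3) * ch1$truth$drivers[, "mean__M01"])
})

test_that("the baseline hazard calibration hits the target event fraction", {
  planted <- data.frame(domain = "epithelial", feature = "mean__M01",
                        beta = 0.8)
  cfg <- synthetic_cohort_config(n_patients = 800, n_markers = 3,
                                 n_epithelial = 20, n_stromal = 20,
                                 planted = planted,
                                 target_event_frac = 0.25, seed = 7)
  ch <- generate_cohort(cfg, seed = 7)
  frac <- mean(ch$surv$event == 1 & ch$surv$time <= 5)
  expect_lt(abs(frac - 0.25), 0.05)
})

test_that("shared drivers with opposing effects shift both compartments", {
  planted <- data.frame(domain = c("epithelial", "stromal"),
                        feature = c("mean__M01", "mean__M01"),
                        beta = c(1, 0), driver = c(1, 1),
                        effect = c(1, -1))
  cfg <- synthetic_cohort_config(n_patients = 2, n_markers = 3,
                                 n_epithelial = 400, n_stromal = 400,
                                 mean_effect_sd = 1, planted = planted,
                                 seed = 8)
  parsed <- domainsurv:::.parse_planted(cfg$planted, cfg$markers)
  st <- list(loadings = domainsurv:::.baseline_loadings(cfg),
             drivers = lapply(parsed, function(p) c(p, list(value = 2))))
  spot <- generate_spot(cfg, st, seed = 81)
  epi_mean <- mean(spot$M01[spot$ecad_positive])
  str_mean <- mean(spot$M01[!spot$ecad_positive])
  expect_gt(epi_mean - str_mean, 3)  # +2 vs -2 shift at sd 1
})

test_that("the cohort preset mirrors the study shape exactly", {
  ch <- make_paper_scale_fixture(seed = 2, n_epithelial = 12,
                                 n_stromal = 12)
  expect_equal(nrow(ch$surv), 432L)
  expect_equal(sum(ch$surv$event), 65L)
  expect_true(all(ch$surv$time[ch$surv$event == 1] <= 5))
  expect_true(all(ch$surv$time[ch$surv$event == 0] > 5))
  # events populate every year up to the horizon
  yrs <- ceiling(ch$surv$time[ch$surv$event == 1])
  expect_setequal(sort(unique(yrs)), 1:5)
  expect_length(ch$spots, 432L)
  ch2 <- make_paper_scale_fixture(seed = 2, n_epithelial = 12,
                                  n_stromal = 12)
  expect_identical(ch$surv$time, ch2$surv$time)
  expect_identical(as.data.frame(ch$spots[[5]]),
                   as.data.frame(ch2$spots[[5]]))
})
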