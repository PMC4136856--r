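test_that("detection histories are segmented into 5-day occasions correctly", {
  dep <- tibble::tibble(site_id = 1L, start = 1, length = 38, lure = TRUE,
                        temperature = "low", camera_view = "open")
  det <- tibble::tibble(site_id = 1L, day = 12)  # day offset 11 -> occasion 3
  h <- build_detection_history(dep, det)
  expect_equal(ncol(h$y), 7)  # 38 days -> 7 occasions, 3-day tail dropped
  expect_equal(as.numeric(h$y[1, ]), c(0, 0, 1, 0, 0, 0, 0))
  # too-short deployment excluded with warning
  dep2 <- dplyr::bind_rows(dep, tibble::tibble(
    site_id = 2L, start = 1, length = 4, lure = FALSE, temperature = "high",
    camera_view = "limited"))
  expect_warning(h2 <- build_detection_history(dep2, det), "excluded")
  expect_equal(nrow(h2$y), 1)
  # detection outside the window errors
  expect_error(build_detection_history(dep, tibble::tibble(site_id = 1L, day = 60)),
               "outside deployment")
})

test_that("negative log-likelihood matches hand-computed closed forms", {
  X_occ <- matrix(1, 1, 1); X_det <- matrix(1, 2, 1)
  # psi = 0.5, p = 0.5, y = (0,0): L = 0.5*0.25 + 0.5 = 0.625
  y00 <- matrix(c(0, 0), 1, 2)
  expect_equal(occupancy_negloglik(c(0, 0), X_occ, X_det, y00), -log(0.625),
               tolerance = 1e-12)
  expect_equal(round(occupancy_negloglik(c(0, 0), X_occ, X_det, y00), 4), 0.4700)
  # psi = 0.8, p = 0.5, y = (1,0): L = 0.8 * 0.25 = 0.2
  y10 <- matrix(c(1, 0), 1, 2)
  expect_equal(occupancy_negloglik(c(qlogis(0.8), 0), X_occ, X_det, y10),
               -log(0.2), tolerance = 1e-12)
  expect_equal(round(occupancy_negloglik(c(qlogis(0.8), 0), X_occ, X_det, y10), 4),
               1.6094)
  expect_error(occupancy_negloglik(c(NA, 0), X_occ, X_det, y00), "non-finite")
})

test_that("NLL equals the independent per-site summation on random instances", {
  for (s in 1:10) {
    h <- random_history(25, 5, seed = s, p_na = 0.1)
    sd_ <- withr::with_seed(s, tibble::tibble(x1 = rnorm(25), x2 = rnorm(25)))
    od <- corridorscape:::build_occ_design(sd_, c("x1", "x2"))
    X_det <- corridorscape:::build_det_design(h, c("lure", "temperature"))
    par <- withr::with_seed(100 + s, rnorm(3 + 4, 0, 0.8))
    expect_equal(occupancy_negloglik(par, od$X, X_det, h$y),
                 oracle_occupancy_nll(par[1:3], par[4:7], od$X, X_det, h$y),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to site order and within-site occasion order", {
  h <- random_history(30, 6, seed = 4)
  sd_ <- withr::with_seed(4, tibble::tibble(x1 = rnorm(30)))
  od <- corridorscape:::build_occ_design(sd_, "x1")
  X_det <- corridorscape:::build_det_design(h, "lure")
  par <- c(0.3, -0.5, 0.2, 0.6)
  base <- occupancy_negloglik(par, od$X, X_det, h$y)
  # permute sites
  perm <- withr::with_seed(5, sample(30))
  h2 <- h; h2$y <- h$y[perm, ]
  h2$occ_cov <- lapply(h$occ_cov, function(m) m[perm, ])
  od2 <- corridorscape:::build_occ_design(sd_[perm, , drop = FALSE], "x1",
                                          info = od$info)
  expect_equal(occupancy_negloglik(par, od2$X,
                                   corridorscape:::build_det_design(h2, "lure"),
                                   h2$y), base, tolerance = 1e-12)
  # permute occasions within sites (covariates constant in time)
  h3 <- h; h3$y <- h$y[, 6:1]
  expect_equal(occupancy_negloglik(par, od$X, X_det, h3$y), base,
               tolerance = 1e-12)
})

test_that("analytic gradient matches numerical differentiation", {
  h <- random_history(20, 4, seed = 8)
  sd_ <- withr::with_seed(8, tibble::tibble(x1 = rnorm(20)))
  od <- corridorscape:::build_occ_design(sd_, "x1")
  X_det <- corridorscape:::build_det_design(h, c("lure", "camera_view"))
  par <- c(0.2, -0.4, 0.1, 0.5, -0.3)
  g <- unname(corridorscape:::occupancy_negloglik_grad(par, od$X, X_det, h$y))
  eps <- 1e-6
  gn <- vapply(seq_along(par), function(k) {
    pp <- par; pp[k] <- pp[k] + eps
    pm <- par; pm[k] <- pm[k] - eps
    (occupancy_negloglik(pp, od$X, X_det, h$y) -
       occupancy_negloglik(pm, od$X, X_det, h$y)) / (2 * eps)
  }, 0)
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("intercept-only MLE matches a dense 2-D grid search", {
  sv <- small_survey(n_sites = 200, n_occasions = 6, seed = 21)
  fit <- fit_occupancy(occu_spec(), sv$history, sv$sites, n_starts = 3)
  X_occ <- matrix(1, 200, 1)
  X_det <- matrix(1, 200 * 6, 1)
  grid_min <- function(as, bs) {
    g <- expand.grid(a = as, b = bs)
    v <- mapply(function(a, b) occupancy_negloglik(c(a, b), X_occ, X_det,
                                                   sv$history$y), g$a, g$b)
    list(val = min(v), a = g$a[which.min(v)], b = g$b[which.min(v)])
  }
  coarse <- grid_min(seq(-4, 4, by = 0.05), seq(-4, 4, by = 0.05))
  fine <- grid_min(seq(coarse$a - 0.06, coarse$a + 0.06, by = 0.002),
                   seq(coarse$b - 0.06, coarse$b + 0.06, by = 0.002))
  expect_lt(-fit$logLik, fine$val + 1e-4)
})

test_that("all-detected data drives estimates to the logit cap with a flag", {
  n <- 30; T_ <- 4
  h <- random_history(n, T_, seed = 3)
  h$y[] <- 1
  fit <- fit_occupancy(occu_spec(), h, tibble::tibble(dummy = rep(1, n)),
                       n_starts = 1)
  expect_true(fit$boundary)
  expect_equal(unname(fit$beta[1]), 15)
  expect_equal(unname(fit$alpha[1]), 15)
})

test_that("detection-model selection recovers a strong lure effect", {
  # AIC admits a spurious one-parameter covariate with probability
  # P(chisq_1 > 2) ~ 0.16, so exact-set recovery cannot exceed ~0.7; assert
  # that the lure term itself is always kept and that {lure} is the modal
  # selected subset with a majority share.
  fx <- small_landscape()
  n_rep <- 20
  picks <- character(n_rep)
  lure_truth <- true_model(alpha = c(`(Intercept)` = -0.5, lure = 1.6,
                                     temperaturemedium = 0, temperaturehigh = 0,
                                     camera_viewlimited = 0))
  for (r in seq_len(n_rep)) {
    sv <- simulate_surveys(fx$truth_map, survey_design(n_sites = 150,
                                                       n_occasions = 6),
                           lure_truth, stack = fx$land$stack, seed = 3000 + r)
    sel <- select_detection_model(sv$history, sv$sites,
                                  c("elevation", "bamboo", "forest_age"),
                                  n_starts = 1)
    expect_true("lure" %in% sel$best)
    picks[r] <- paste(sort(sel$best), collapse = "+")
  }
  expect_gte(mean(picks == "lure"), 0.5)
  expect_equal(names(sort(table(picks), decreasing = TRUE))[1], "lure")
  # empty pool returns the empty subset trivially
  sv <- small_survey(n_sites = 60, n_occasions = 4, seed = 77)
  sel0 <- select_detection_model(sv$history, sv$sites, "elevation",
                                 det_pool = character(0), n_starts = 1)
  expect_identical(sel0$best, character(0))
})

test_that("AIC weights follow the exp(-dAIC/2) normalisation and its invariances", {
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(round(w, 3), c(0.731, 0.269))
  sv <- small_survey(n_sites = 120, n_occasions = 5, seed = 15)
  ms <- all_subsets_selection(sv$history, sv$sites, c("elevation", "bamboo"),
                              det_terms = "lure", n_starts = 1)
  expect_equal(sum(ms$weight), 1, tolerance = 1e-12)
  expect_equal(ms$dAIC[1], 0)
  expect_equal(ms$cum_weight[nrow(ms)], 1, tolerance = 1e-12)
  expect_true(all(diff(ms$AIC) >= 0))
  # weights invariant to a constant AIC shift
  shifted <- exp(-(ms$AIC + 100 - min(ms$AIC + 100)) / 2)
  expect_equal(ms$weight, shifted / sum(shifted), tolerance = 1e-12)
})

test_that("model averaging renormalises, zero-substitutes and scores importance", {
  sv <- small_survey(n_sites = 120, n_occasions = 5, seed = 16)
  ms <- all_subsets_selection(sv$history, sv$sites,
                              c("elevation", "bamboo", "forest_age"),
                              det_terms = "lure", n_starts = 1)
  # single-model top set reproduces that model's coefficients
  one <- ms[1, ]
  attr(one, "fits") <- attr(ms, "fits")[1]
  attr(one, "occ_pool") <- attr(ms, "occ_pool")
  attr(one, "det_terms") <- attr(ms, "det_terms")
  attr(one, "site_summary") <- attr(ms, "site_summary")
  class(one) <- class(ms)
  avg1 <- model_average(one, delta_threshold = 0)
  f1 <- attr(ms, "fits")[[1]]
  expect_equal(avg1$coef_occ[names(f1$beta)], f1$beta, tolerance = 1e-12)
  # hand-built two-model set with equal AIC: coefficient halves
  avg <- model_average(ms)
  expect_equal(sum(avg$top_weights), 1, tolerance = 1e-12)
  expect_true(all(avg$importance$importance >= 0 & avg$importance$importance <= 1))
  # a covariate present in every top model has importance 1
  in_all <- vapply(attr(ms, "occ_pool"), function(tm) {
    all(vapply(avg$top$model, function(m) {
      tm %in% ms$occ_terms[[match(m, ms$model)]]
    }, TRUE))
  }, TRUE)
  for (tm in names(in_all)[in_all]) {
    expect_equal(avg$importance$importance[avg$importance$covariate == tm], 1,
                 tolerance = 1e-12)
  }
})

test_that("two equal-weight models average a lone coefficient to half its value", {
  # synthetic modelset built by hand
  fitA <- list(beta = c(`(Intercept)` = 0.5, elevation = 1.0),
               alpha = c(`(Intercept)` = 0.1),
               design_info = list(meta = list(elevation = list(
                 type = "numeric", center = 0, scale = 1))))
  fitB <- list(beta = c(`(Intercept)` = 0.3),
               alpha = c(`(Intercept)` = 0.1),
               design_info = list(meta = list()))
  tab <- tibble::tibble(model = c("elevation", "(intercept)"),
                        occ_terms = list("elevation", character(0)),
                        K = c(3, 2), logLik = c(-10, -10.5),
                        AIC = c(100, 100), dAIC = c(0, 0),
                        weight = c(0.5, 0.5), cum_weight = c(0.5, 1))
  attr(tab, "fits") <- list(elevation = fitA, `(intercept)` = fitB)
  attr(tab, "occ_pool") <- "elevation"
  attr(tab, "det_terms") <- character(0)
  attr(tab, "site_summary") <- list(elevation = list(type = "numeric", mean = 0,
                                                     range = c(-1, 1)))
  class(tab) <- c("occu_modelset", class(tab))
  avg <- model_average(tab)
  expect_equal(unname(avg$coef_occ[["elevation"]]), 0.5)
  expect_equal(avg$importance$importance, 0.5)
})

test_that("suitability prediction is consistent with site-level evaluation", {
  fx <- small_landscape()
  sv <- small_survey(n_sites = 150, n_occasions = 6, seed = 22)
  ms <- all_subsets_selection(sv$history, sv$sites,
                              c("elevation", "bamboo", "forest_age"),
                              det_terms = "lure", n_starts = 1)
  avg <- model_average(ms)
  psi <- predict_suitability(avg, fx$land$stack)
  expect_true(all(psi$values >= 0 & psi$values <= 1, na.rm = TRUE))
  # prediction at surveyed cells equals applying the equation to the rows
  eta <- corridorscape:::avg_linear_predictor(avg, sv$sites)
  expect_equal(psi$values[cbind(sv$sites$row, sv$sites$col)], plogis(eta),
               tolerance = 1e-10)
  # end-to-end recovery of the truth surface
  expect_lt(mean(abs(psi$values - fx$truth_map$values), na.rm = TRUE), 0.1)
})

test_that("partial response curves are monotone for raw terms and consistent", {
  sv <- small_survey(n_sites = 150, n_occasions = 6, seed = 23)
  ms <- all_subsets_selection(sv$history, sv$sites, c("elevation", "bamboo"),
                              det_terms = "lure", n_starts = 1)
  avg <- model_average(ms)
  pr <- partial_response(avg, "elevation", n = 50)
  sgn <- sign(avg$coef_occ[["elevation"]])
  expect_true(all(sign(diff(pr$psi)) == sgn | diff(pr$psi) == 0))
  expect_error(partial_response(avg, "no_such"), "unknown covariate")
  # quadratic averaged model with negative curvature is unimodal
  fitQ <- list(beta = c(`(Intercept)` = 0, x = 0.2, `I(x^2)` = -1.5),
               alpha = c(`(Intercept)` = 0),
               design_info = list(meta = list(`quad(x)` = list(
                 type = "numeric", center = c(0, 1), scale = c(1, 1)))))
  tabQ <- tibble::tibble(model = "quad(x)", occ_terms = list("quad(x)"),
                         K = 4, logLik = -5, AIC = 18, dAIC = 0, weight = 1,
                         cum_weight = 1)
  attr(tabQ, "fits") <- list(`quad(x)` = fitQ)
  attr(tabQ, "occ_pool") <- "quad(x)"
  attr(tabQ, "det_terms") <- character(0)
  attr(tabQ, "site_summary") <- list(x = list(type = "numeric", mean = 0,
                                              range = c(-3, 3)))
  class(tabQ) <- c("occu_modelset", class(tabQ))
  avgQ <- model_average(tabQ)
  prQ <- partial_response(avgQ, "x", n = 101)
  peak <- which.max(prQ$psi)
  expect_true(peak > 1 && peak < 101)
  expect_true(all(diff(prQ$psi[1:peak]) >= -1e-12))
  expect_true(all(diff(prQ$psi[peak:101]) <= 1e-12))
})
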