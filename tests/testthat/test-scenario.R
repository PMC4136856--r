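scenario_fixture <- function() {
  if (is.null(.fixture_env$scen)) {
    fx <- small_landscape()
    sv <- small_survey(n_sites = 150, n_occasions = 6, seed = 51)
    ms <- all_subsets_selection(sv$history, sv$sites,
                                c("elevation", "bamboo", "forest_age"),
                                det_terms = "lure", n_starts = 1)
    avg <- model_average(ms)
    psi <- predict_suitability(avg, fx$land$stack)
    cost <- cost_surface(psi)
    ends <- corridorscape:::corridor_endpoints(sv$sites, sv$history, fx$land,
                                               n_per_side = 5)
    paths <- enumerate_pathways(cost, ends$sources, ends$sinks)
    .fixture_env$scen <- list(fx = fx, sv = sv, avg = avg, psi = psi,
                              cost = cost, paths = paths)
  }
  .fixture_env$scen
}

test_that("tunnel edits strictly increase road distance near the removed segment", {
  s <- scenario_fixture()
  stack <- s$fx$land$stack; features <- s$fx$land$features
  road <- features$roads
  total <- max(corridorscape:::polyline_chainage(road$x, road$y))
  spec <- scenario_spec("tunnel", list(edit_tunnel(1L, total / 2 - 500,
                                                   total / 2 + 500)))
  out <- apply_scenario(stack, features, spec)
  d0 <- stack$layers$dist_road$values
  d1 <- out$stack$layers$dist_road$values
  expect_true(all(d1 - d0 >= -1e-9))        # removal can only increase distance
  expect_gt(max(d1 - d0), 0)                # and does so somewhere
  # near-road cells far (along the road) from the tunnel keep their distance
  mid <- corridorscape:::point_at_chainage(road$x, road$y, total / 2)
  ref <- stack$layers[[1]]
  idx <- expand.grid(row = seq_len(ref$n_rows), col = seq_len(ref$n_cols))
  ctr <- cell_center(ref, idx$row, idx$col)
  far_along <- matrix(abs(ctr$y - mid[2]) > 2500, ref$n_rows, ref$n_cols)
  keep <- far_along & d0 < 1000
  expect_equal(d1[keep], d0[keep])
  # untouched layers bit-identical
  expect_identical(out$stack$layers$elevation$values,
                   stack$layers$elevation$values)
  expect_identical(out$stack$layers$dist_residence_large$values,
                   stack$layers$dist_residence_large$values)
})

test_that("removing all large residences caps the distance layer everywhere", {
  s <- scenario_fixture()
  stack <- s$fx$land$stack; features <- s$fx$land$features
  out <- apply_scenario(stack, features,
                        scenario_spec("reloc", list(edit_remove_residences("large"))))
  expect_equal(sum(out$features$residences$size == "large"), 0)
  ref <- stack$layers[[1]]
  cap <- sqrt((ref$n_rows * ref$cell_size)^2 + (ref$n_cols * ref$cell_size)^2)
  expect_true(all(out$stack$layers$dist_residence_large$values == cap))
  expect_warning(apply_scenario(out$stack, out$features,
                                scenario_spec("again", list(edit_remove_residences("large")))),
                 "no-op")
})

test_that("restoration sets primary forest and bamboo inside the polygon only", {
  s <- scenario_fixture()
  stack <- s$fx$land$stack
  poly <- tibble::tibble(x = c(2000, 6000, 6000, 2000),
                         y = c(2000, 2000, 6000, 6000))
  out <- apply_scenario(stack, s$fx$land$features,
                        scenario_spec("rest", list(edit_restore_forest(poly))))
  ref <- stack$layers[[1]]
  idx <- expand.grid(row = seq_len(ref$n_rows), col = seq_len(ref$n_cols))
  ctr <- cell_center(ref, idx$row, idx$col)
  inside <- matrix(corridorscape:::points_in_polygon(ctr$x, ctr$y, poly$x, poly$y),
                   ref$n_rows, ref$n_cols)
  expect_true(all(out$stack$layers$forest_age$values[inside] == 1))
  expect_true(all(out$stack$layers$bamboo$values[inside] == 2))
  expect_identical(out$stack$layers$forest_age$values[!inside],
                   stack$layers$forest_age$values[!inside])
  expect_identical(out$stack$layers$bamboo$values[!inside],
                   stack$layers$bamboo$values[!inside])
})

test_that("scenario re-costing keeps the baseline column identical to path indices", {
  s <- scenario_fixture()
  cmp <- scenario_costs(list(), s$avg, s$fx$land$stack, s$fx$land$features,
                        s$paths)
  feas <- s$paths[s$paths$role != "infeasible", ]
  expect_equal(unname(cmp$cost_matrix[, "baseline"]), feas$cost_index,
               tolerance = 1e-12)
  # a no-edit scenario column equals baseline exactly
  cmp2 <- scenario_costs(list(copy = scenario_spec("copy")), s$avg,
                         s$fx$land$stack, s$fx$land$features, s$paths)
  expect_equal(cmp2$cost_matrix[, "copy"], cmp2$cost_matrix[, "baseline"])
})

test_that("restoration lowers the cost index of paths it touches", {
  s <- scenario_fixture()
  cfg <- s$fx$land$config
  whole <- tibble::tibble(
    x = c(0, cfg$n_cols * 100, cfg$n_cols * 100, 0),
    y = c(0, 0, cfg$n_rows * 100, cfg$n_rows * 100))
  cmp <- scenario_costs(list(rest = scenario_spec("rest",
                                                  list(edit_restore_forest(whole)))),
                        s$avg, s$fx$land$stack, s$fx$land$features, s$paths)
  # bamboo and primary forest raise psi under the fitted model, so costs drop
  expect_true(all(cmp$cost_matrix[, "rest"] < cmp$cost_matrix[, "baseline"]))
})

test_that("two-way ANOVA decomposes exactly and matches aov on random matrices", {
  withr::with_seed(61, M <- matrix(rnorm(25 * 4, 100, 10), 25, 4,
                                   dimnames = list(paste0("p", 1:25),
                                                   c("a", "b", "c", "d"))))
  tab <- two_way_anova(M)
  expect_equal(tab$df, c(3, 24, 72))
  # SS conservation
  expect_equal(sum(tab$sumsq), sum((M - mean(M))^2), tolerance = 1e-8)
  # reference implementation
  df <- data.frame(y = as.vector(M),
                   path = factor(rep(rownames(M), 4)),
                   scen = factor(rep(colnames(M), each = 25)))
  ref <- summary(stats::aov(y ~ scen + path, data = df))[[1]]
  expect_equal(tab$statistic[tab$term == "scenario"], ref["scen", "F value"],
               tolerance = 1e-8)
  expect_equal(tab$p.value[tab$term == "scenario"], ref["scen", "Pr(>F)"],
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "pathway"], ref["path", "F value"],
               tolerance = 1e-8)
  # constant matrix -> F = 0
  tab0 <- two_way_anova(matrix(5, 4, 3))
  expect_equal(tab0$statistic[1:2], c(NaN, NaN))
  expect_error(two_way_anova(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")
})

test_that("Holm adjustment reproduces the step-down arithmetic and references", {
  expect_equal(holm_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)  # identity for m = 1
  withr::with_seed(62, p <- runif(10))
  expect_equal(holm_adjust(p), stats::p.adjust(p, "holm"), tolerance = 1e-12)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("paired t statistics match t.test and degenerate columns report p = 1", {
  withr::with_seed(63, M <- matrix(rnorm(25 * 3, 100, 8), 25, 3,
                                   dimnames = list(NULL, c("x", "y", "z"))))
  res <- holm_paired_tests(M)
  for (k in seq_len(nrow(res))) {
    ref <- stats::t.test(M[, res$scenario_a[k]], M[, res$scenario_b[k]],
                         paired = TRUE)
    expect_equal(res$t[k], unname(ref$statistic), tolerance = 1e-8)
    expect_equal(res$p.value[k], ref$p.value, tolerance = 1e-8)
  }
  expect_equal(res$p.holm, stats::p.adjust(res$p.value, "holm"),
               tolerance = 1e-12)
  # identical columns: t undefined, adjusted p = 1
  M2 <- cbind(a = M[, 1], b = M[, 1])
  res2 <- holm_paired_tests(M2)
  expect_true(is.na(res2$t))
  expect_equal(res2$p.holm, 1)
  expect_error(holm_paired_tests(M, comparisons = list(c("x", "nope"))),
               "unknown scenario")
})

test_that("the valley fixture reproduces the qualitative scenario ordering", {
  fx <- valley_demo_fixture()
  expect_equal(nrow(fx$paths), 25)
  cmp <- scenario_costs(fx$scenarios, fx$avg, fx$stack, fx$features, fx$paths)
  res <- holm_paired_tests(cmp, comparisons = list(
    c("baseline", "restoration"), c("baseline", "relocation"),
    c("baseline", "tunnel"), c("restoration", "tunnel")))
  get <- function(a, b) res[res$scenario_a == a & res$scenario_b == b, ]
  # restoration and tunnel significantly below baseline
  expect_true(get("baseline", "restoration")$significant)
  expect_gt(get("baseline", "restoration")$mean_diff, 0)
  expect_true(get("baseline", "tunnel")$significant)
  expect_gt(get("baseline", "tunnel")$mean_diff, 0)
  # relocation not significantly different from baseline
  expect_false(get("baseline", "relocation")$significant)
  # tunnel below restoration
  tr <- get("restoration", "tunnel")
  expect_true(tr$significant)
  expect_gt(tr$mean_diff, 0)
  # the ANOVA finds a scenario effect
  an <- two_way_anova(cmp)
  expect_lt(an$p.value[an$term == "scenario"], 0.001)
})
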