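test_that("level-0 perturbations reproduce the base case bit-for-bit", {
  s1 <- scenario1_fixture()
  base <- run_budget_impact(s1)
  cost0 <- perturb_spec(s1, sensitivity_axis("cost", "arm_unit_cost",
                                             levels = 0), 0)
  up0 <- perturb_spec(s1, sensitivity_axis("up", "uptake_trajectory",
                                           levels = 0), 0)
  for (p in list(cost0, up0)) {
    res <- run_budget_impact(p)
    expect_identical(res$rows$incremental, base$rows$incremental)
    expect_identical(res$cumulative, base$cumulative)
  }
  # and the original spec is never mutated
  expect_identical(spec_digest(s1), spec_digest(scenario1_fixture()))
})

test_that("uptake shifts move percentage points, comparator absorbs them", {
  s1 <- scenario1_fixture()
  up <- sensitivity_axis("uptake", "uptake_trajectory", levels = 0.10)
  pert <- perturb_spec(s1, up, 0.10)
  sh <- pert$projected$shares
  expect_equal(sh$share[sh$arm_id == "abma"], c(0.30, 0.40, 0.50, 0.60, 0.70),
               tolerance = 1e-12)
  expect_equal(as.vector(tapply(sh$share, sh$year, sum)), rep(1, 5),
               tolerance = 1e-12)
  # a shift pushing any year outside [0, 1] fails loudly
  expect_error(perturb_spec(s1, up, 0.41), "2028")
  expect_error(perturb_spec(s1, up, -0.21), "2024")
  # shifting exactly to the boundary is allowed
  s_zero <- perturb_spec(s1, up, -0.20)
  sh0 <- s_zero$projected$shares
  expect_equal(sh0$share[sh0$arm_id == "abma" & sh0$year == 2024], 0,
               tolerance = 1e-12)
})

test_that("uptake shift of minus the whole share recreates the comparator-only scenario", {
  s <- tiny_spec(s_proj = c(0.4, 0.4), baseline_new_share = 0)
  pert <- perturb_spec(s, sensitivity_axis("u", "uptake_trajectory",
                                           levels = -0.4), -0.4)
  res <- run_budget_impact(pert)
  expect_equal(res$rows$incremental, c(0, 0), tolerance = 1e-9)
})

test_that("published year-5 uptake sensitivity figures are reproduced", {
  s1 <- scenario1_fixture()
  sp <- one_way_analysis(s1, sensitivity_axis("uptake", "uptake_trajectory",
                                              levels = c(-0.10, 0.10)))
  y5 <- function(lv) {
    r <- sp$entries$result[[which(sp$entries$level == lv)]]
    r$rows$incremental[r$rows$year == 2028]
  }
  expect_rel_equal(y5(0.10), -5270684, 1e-4)
  expect_rel_equal(y5(-0.10), -3764774, 1e-4)
})

test_that("cumulative impact is affine in a uniform uptake shift", {
  for (spec in list(scenario1_fixture(), tiny_spec(c(0.3, 0.5, 0.6)))) {
    ax <- sensitivity_axis("u", "uptake_trajectory",
                           levels = c(-0.10, 0, 0.10))
    sp <- one_way_analysis(spec, ax)
    cum <- spider_series(sp, "cumulative")
    cum <- cum[order(cum$level), ]
    expect_identical(nrow(cum), 3L)
    mid <- (cum$value_qar[1] + cum$value_qar[3]) / 2
    expect_lt(abs(mid - cum$value_qar[2]) / abs(cum$value_qar[2]), 1e-6)
  }
})

test_that("a global cost factor scales every incremental by (1 + f)", {
  for (f in c(-0.25, -0.1, 0.1, 0.25)) {
    spec <- tiny_spec(s_proj = c(0.2, 0.5, 0.7), cost_new = 90000,
                      cost_old = 150000)
    base <- run_budget_impact(spec)
    ax <- sensitivity_axis("all_costs", "arm_unit_cost", levels = f,
                           scenario_scope = "both")
    pert <- run_budget_impact(perturb_spec(spec, ax, f))
    expect_equal(pert$rows$incremental, base$rows$incremental * (1 + f),
                 tolerance = 1e-9)
    # brute force: same factor applied to the cost inputs directly
    brute <- run_budget_impact(tiny_spec(c(0.2, 0.5, 0.7),
                                         90000 * (1 + f), 150000 * (1 + f)))
    expect_equal(pert$cumulative, brute$cumulative, tolerance = 1e-9)
  }
})

test_that("cost axes respect the arm selector and scenario scope", {
  s1 <- scenario1_fixture()
  ax <- sensitivity_axis("abma_price", "arm_unit_cost", levels = 0.10,
                         arm_selector = "abma")
  pert <- perturb_spec(s1, ax, 0.10)
  expect_equal(unit_cost(pert$unit_costs, "abma", 2024),
               unit_cost(s1$unit_costs, "abma", 2024) * 1.1,
               tolerance = 1e-12)
  expect_identical(unit_cost(pert$unit_costs, "cdk_mix", 2024),
                   unit_cost(s1$unit_costs, "cdk_mix", 2024))

  # one-sided scope works when the arm appears in only one trajectory
  ax_proj <- sensitivity_axis("proj_only", "arm_unit_cost", levels = 0.10,
                              arm_selector = "abma",
                              scenario_scope = "projected_only")
  pert2 <- perturb_spec(s1, ax_proj, 0.10)
  expect_equal(unit_cost(pert2$unit_costs, "abma", 2026),
               unit_cost(s1$unit_costs, "abma", 2026) * 1.1,
               tolerance = 1e-12)

  # but is rejected when the arm is shared between both scenarios
  shared <- tiny_spec(s_proj = c(0.5, 0.6), baseline_new_share = 0.1)
  ax_bad <- sensitivity_axis("bad", "arm_unit_cost", levels = 0.10,
                             arm_selector = "new",
                             scenario_scope = "projected_only")
  expect_error(perturb_spec(shared, ax_bad, 0.10), "both scenarios")
  expect_error(perturb_spec(s1, sensitivity_axis("ghost", "arm_unit_cost",
                                                 levels = 0.1,
                                                 arm_selector = "ghost"),
                            0.1), "ghost")
})

test_that("spider series are long, sorted, and anchored at the base case", {
  s1 <- scenario1_fixture()
  sp <- one_way_analysis(s1, list(
    sensitivity_axis("uptake", "uptake_trajectory", levels = c(-0.1, 0.1)),
    sensitivity_axis("abma_price", "arm_unit_cost", levels = 0.25,
                     arm_selector = "abma")))
  cum <- spider_series(sp, "cumulative")
  expect_identical(names(cum), c("axis_id", "level", "year", "value_qar"))
  # each axis gains a base-case row at level 0
  expect_identical(nrow(cum[cum$axis_id == "uptake", ]), 3L)
  expect_identical(nrow(cum[cum$axis_id == "abma_price", ]), 2L)
  base_rows <- cum[cum$level == 0, ]
  expect_equal(unique(base_rows$value_qar), sp$base$cumulative,
               tolerance = 1e-12)
  by_year <- spider_series(sp, "by_year")
  expect_identical(sort(unique(by_year$year)), as.character(2024:2028))
  expect_error(spider_series(sp, "nope"))
  expect_error(one_way_analysis(s1, list()), "at least one")
})
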