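# survival maps, demarcation contrast, zone metrics, protocol sweep

uniform_model <- function() {
  # k1 = 0 so Ec*(n) = 1 for every n; convenient against a uniform field
  fermi_protocol_model(Eco = 1e5, k1 = 0, Ao = 4e4, k2 = 0,
                       pulse_length = 1e-4)
}

test_that("a uniform field at Ec* gives S = 0.5 everywhere", {
  sol <- solve_potential(plate_config(C = 1), h = 0.025)  # E* = 1 uniform
  smap <- survival_map(sol, uniform_model(), n = 10)
  tissue <- !is.na(smap$survival)
  expect_true(all(abs(smap$survival[tissue] - 0.5) < 1e-9))
  # and a zero-field region survives: S ~ 1 (width narrow vs midpoint)
  narrow <- fermi_protocol_model(Eco = 1e5, k1 = 0, Ao = 5e3, k2 = 0,
                                 pulse_length = 1e-4)
  sol0 <- solve_potential(plate_config(C = 1e-9), h = 0.025)
  smap0 <- survival_map(sol0, narrow, n = 10)
  expect_true(all(smap0$survival[!is.na(smap0$survival)] > 1 - 1e-6))
})

test_that("survival map recomposes the two modules' scalar paths", {
  model <- fermi_protocol_model(Eco = 1.5e5, k1 = 0.03, Ao = 4e4,
                                k2 = 0.03, pulse_length = 1e-4)
  sol <- solve_potential(small_cylinder_config(C = 1.5), h = 0.025)
  n <- 50
  smap <- survival_map(sol, model, n = n)
  set.seed(31)
  tissue_idx <- which(sol$mask == 0L)
  for (k in sample(tissue_idx, 10)) {
    # independent scalar path: dimensional survival at E = E* Eco
    expect_equal(smap$survival[k],
                 protocol_survival(sol$field_magnitude[k] * model$Eco,
                                   n, model),
                 tolerance = 1e-9)
  }
  expect_true(all(is.na(smap$survival[sol$mask != 0L])))
  expect_error(survival_map(sol, model, n = 0), ">= 1")
})

test_that("deterministic demarcation equals the S <= 0.5 region node-exactly", {
  model <- truth_model()
  dm_model <- normalize_model(model)
  sol <- solve_potential(small_cylinder_config(C = 1.5), h = 0.025)
  for (n in c(10, 50, 100)) {
    smap <- survival_map(sol, model, n = n)
    det <- deterministic_map(sol, threshold = dm_model$Ec_star(n))
    tissue <- !is.na(det$killed)
    expect_identical(det$killed[tissue], smap$survival[tissue] <= 0.5)
  }
  # threshold above the global maximum kills nothing
  hi <- deterministic_map(sol, threshold = max(sol$field_magnitude) * 1.01)
  expect_identical(sum(hi$killed, na.rm = TRUE), 0L)
  # uniform plate field below threshold: everything killed
  plate <- solve_potential(plate_config(C = 2), h = 0.1)
  all_killed <- deterministic_map(plate, threshold = 1.5)$killed
  expect_true(all(all_killed[!is.na(all_killed)]))
})

test_that("zone areas partition the tissue domain exactly", {
  sol <- solve_potential(small_cylinder_config(C = 1.5), h = 0.025)
  smap <- survival_map(sol, truth_model(), n = 50)
  met <- ablation_metrics(smap, s_kill = 0.05, s_live = 0.95)
  expect_equal(met$kill_area + met$transition_area + met$survive_area,
               met$total_area, tolerance = 1e-12)
  expect_identical(met$total_area, sum(sol$mask == 0L) * sol$h^2)
  # deterministic area sandwiched by the statistical zones
  expect_gte(met$deterministic_area, met$kill_area)
  expect_lte(met$deterministic_area, met$kill_area + met$transition_area)
  # an all-transition map: S = 0.5 everywhere
  plate <- solve_potential(plate_config(C = 1), h = 0.1)
  pm <- survival_map(plate, uniform_model(), n = 5)
  pmet <- ablation_metrics(pm, s_kill = 0.05, s_live = 0.95)
  expect_identical(pmet$kill_area, 0)
  expect_identical(pmet$survive_area, 0)
  expect_identical(pmet$transition_area, pmet$total_area)
  expect_error(ablation_metrics(smap, s_kill = 0.9, s_live = 0.1),
               "s_kill < s_live")
})

test_that("kill area computed from S and from the inverted field agree", {
  model <- truth_model()
  dm <- normalize_model(model)
  sol <- solve_potential(small_cylinder_config(C = 1.5), h = 0.025)
  n <- 50
  smap <- survival_map(sol, model, n = n)
  s_kill <- 0.05
  met <- ablation_metrics(smap, s_kill = s_kill, s_live = 0.95)
  # monotone inverse: S <= s  <=>  E* >= Ec* + A* log((1-s)/s)
  E_at <- dm$Ec_star(n) + dm$A_star(n) * log((1 - s_kill) / s_kill)
  tissue <- sol$mask == 0L
  kill_by_field <- sum(sol$field_magnitude[tissue] >= E_at) * sol$h^2
  expect_equal(met$kill_area, kill_by_field, tolerance = 1e-12)
})

test_that("parametric sweep reproduces the qualitative protocol orderings", {
  cfg <- small_cylinder_config(C = 1)
  model <- truth_model()
  sweep_n <- parametric_sweep(cfg, model,
                              data.frame(n = c(10, 50, 100), C = 1.5),
                              h = 0.025)
  expect_true(all(diff(sweep_n$kill_area) > 0))   # more pulses kill more
  sweep_C <- parametric_sweep(cfg, model,
                              data.frame(n = 50, C = c(0.5, 1.5, 2.5)),
                              h = 0.025)
  expect_true(all(diff(sweep_C$kill_area) > 0))
  expect_true(all(sweep_C$transition_area > 0))   # the transition rim
  # determinism: a repeated protocol gives identical rows
  rep2 <- parametric_sweep(cfg, model,
                           data.frame(n = c(50, 50), C = c(1.5, 1.5)),
                           h = 0.025)
  expect_equal(rep2[1, ], rep2[2, ], ignore_attr = TRUE)
  expect_error(parametric_sweep(cfg, model, data.frame()), "empty")
})

test_that("metrics from the rescaled unit solve match a direct solve", {
  cfg <- small_cylinder_config(C = 1)
  model <- truth_model()
  swept <- parametric_sweep(cfg, model, data.frame(n = 50, C = 1.5),
                            h = 0.025, tol = 1e-10)
  direct_sol <- solve_potential(small_cylinder_config(C = 1.5), h = 0.025,
                                tol = 1e-10)
  direct <- ablation_metrics(survival_map(direct_sol, model, 50))
  for (col in c("kill_area", "transition_area", "survive_area",
                "deterministic_area"))
    expect_equal(swept[[col]], direct[[col]], tolerance = 1e-9)
})

test_that("multi-pulse-length sweeps select the matching model", {
  cfg <- small_cylinder_config(C = 1)
  models <- list(default_illustrative_model(1e-4),
                 default_illustrative_model(1e-3))
  prot <- data.frame(n = 50, C = 1.5, pulse_length = c(1e-4, 1e-3))
  sw <- parametric_sweep(cfg, models, prot, h = 0.025)
  expect_identical(nrow(sw), 2L)
  expect_true(all(sw$transition_area > 0))
  expect_error(
    parametric_sweep(cfg, models, data.frame(n = 5, C = 1,
                                             pulse_length = 5e-5),
                     h = 0.025),
    "no fitted model.*no interpolation")
})
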