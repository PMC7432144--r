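test_that("default factorial design enumerates every flask observation", {
  d <- generate_design(design_config())
  # 10 blends x 3 concentrations x 3 replicates x (5 harvests for day-13
  # addition + 3 for day-17 addition)
  expect_equal(nrow(d), 720)
  expect_true(all(d$harvest_day > d$adding_day))
  expect_true(all(d$harvest_day <= 23))
  expect_setequal(d$harvest_day[d$adding_day == 17], c(19, 21, 23))
  expect_setequal(d$harvest_day[d$adding_day == 13], c(15, 17, 19, 21, 23))
  # blend dose arithmetic: 75:25 at 10 % v/v
  expect_true(any(d$ce_conc == 7.5 & d$cf_conc == 2.5))
  # control blends carry no elicitor at any nominal concentration
  expect_equal(sum(d$ce_conc == 0 & d$cf_conc == 0), 5 * 3 * 3 * 8)
})

test_that("design row count matches the closed-form factor product", {
  set.seed(11)
  for (i in 1:5) {
    n_blend <- sample(2:6, 1)
    fr <- runif(n_blend)
    blends <- data.frame(ce_frac = fr, cf_frac = 1 - fr,
                         control = rep(FALSE, n_blend))
    conc <- sort(sample(seq(1, 12, 0.5), sample(2:4, 1)))
    add <- sort(sample(10:15, sample(1:2, 1)))
    interval <- sample(1:3, 1)
    final <- max(add) + sample(3:8, 1)
    reps <- sample(1:4, 1)
    cfg <- design_config(blends, conc, add, interval, final, reps)
    d <- generate_design(cfg)
    expected <- n_blend * length(conc) * reps *
      sum(vapply(add, function(a)
        length(seq(a + interval, final, by = interval)), numeric(1)))
    expect_equal(nrow(d), expected)
    expect_true(all(d$harvest_day > d$adding_day & d$harvest_day <= final))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(design_config(conc_levels = numeric()), "empty")
  expect_error(design_config(adding_days = c(13, 25)), "final_day")
  bad <- default_blend_levels(); bad$ce_frac[1] <- 0.4
  expect_error(design_config(blend_levels = bad), "sum to 1")
  expect_error(design_config(n_replicates = 0), "n_replicates")
})

test_that("noiseless responses satisfy the mass-balance identities exactly", {
  d <- simulate_experiment(params = surface_params(noise_frac = 0), seed = 1)
  expect_equal(d$total, d$intra * d$dw + d$extra, tolerance = 1e-12)
  expect_equal(d$portion, 100 * d$extra / d$total, tolerance = 1e-12)
  expect_true(all(d$dw > 0))
})

test_that("simulation is deterministic given the seed and clips at zero", {
  p <- surface_params(noise_frac = 0.5)
  d1 <- simulate_experiment(params = p, seed = 42)
  d2 <- simulate_experiment(params = p, seed = 42)
  expect_identical(d1, d2)
  d3 <- simulate_experiment(params = p, seed = 43)
  expect_false(identical(d1$total, d3$total))
  expect_true(all(d1[TABLE_RESPONSES] >= 0))
})

test_that("noise is centred: control-row means track the true baseline", {
  p <- surface_params()
  design <- generate_design(design_config())
  ctrl <- design$ce_conc == 0 & design$cf_conc == 0
  truth <- true_response(p, 0, 0, design$adding_day[ctrl],
                         design$harvest_day[ctrl], "extra")
  # measure the actual noise sd the generator applied
  d0 <- simulate_responses(design, p, seed = 1)
  for (seed in c(101, 202)) {
    d <- simulate_responses(design, p, seed = seed)
    resid <- d$extra[ctrl] - truth
    noise_sd <- stats::sd(d0$extra[ctrl] - truth)
    expect_lt(abs(mean(resid)), 3 * noise_sd / sqrt(sum(ctrl)))
  }
})

test_that("positive-noise identity residual has mean near zero", {
  d <- simulate_experiment(params = surface_params(noise_frac = 0.1), seed = 7)
  resid <- d$total - (d$intra * d$dw + d$extra)
  expect_lt(abs(mean(resid)) / stats::sd(resid), 0.1)
})

test_that("grid oracle finds analytic optima", {
  # single Gaussian bump in the doses at (ce = 4, cf = 5), no interaction
  p <- surface_params(intra = c(ce_opt = 4, cf_opt = 5, rho = 0))
  opt <- true_optimum(p, response = "intra", grid_step = 0.25)
  expect_lte(abs(opt$inputs[["ce_conc"]] - 4), opt$grid_step)
  expect_lte(abs(opt$inputs[["cf_conc"]] - 5), opt$grid_step)
  # dry weight rises monotonically with harvest day: boundary optimum
  opt_dw <- true_optimum(surface_params(), response = "dw", grid_step = 0.5)
  expect_equal(opt_dw$inputs[["harvest_day"]], 23)
})

test_that("grid refinement moves the optimum by at most one coarse step", {
  p <- surface_params(seed = 3)
  coarse <- true_optimum(p, response = "total", grid_step = 0.5)
  fine <- true_optimum(p, response = "total", grid_step = 0.25)
  expect_true(all(abs(coarse$inputs - fine$inputs) <= coarse$grid_step + 1e-9))
  expect_gte(fine$value, coarse$value - 1e-9)
})

test_that("unknown response names are rejected", {
  expect_error(true_optimum(surface_params(), response = "ash"),
               "should be one of")
  expect_error(true_response(surface_params(), 1, 1, 13, 20, "ash"),
               "should be one of")
})
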