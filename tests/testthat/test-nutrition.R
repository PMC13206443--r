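test_that("adequacy caps at 1 and scales linearly below the target", {
  # per-meal target for 50 g daily protein over 3 meals is 50/3 g
  expect_equal(adequacy(50 / 3, 50), 1)
  expect_equal(adequacy(100 / 3, 50), 1)   # twice the target still capped
  expect_equal(adequacy(0, 50), 0)
  expect_equal(adequacy(25 / 3, 50), 0.5)
  expect_error(adequacy(-1, 50), "nutrient")
  expect_error(adequacy(1, 0), "RDA")
})

test_that("aggregate adequacy is the arithmetic mean over nutrients", {
  expect_equal(aggregate_adequacy(rep(1, 5)), 1)
  expect_equal(aggregate_adequacy(c(1, 0)), 0.5)
  a <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  expect_equal(aggregate_adequacy(a), mean(a))
  expect_error(aggregate_adequacy(numeric()), "non-empty")
})

test_that("energy ratios derive from Atwater factors and sum to one", {
  cfg <- nutrition_config()
  # 4p/(4p+4c+9f): 30/40/13.33 g gives the 30/40/30 target split
  n <- c(calories = 500, protein = 30, fat = 40 * 3 / 9,
         carbohydrates = 40, fiber = 0)
  r <- energy_ratios(n, cfg)
  expect_equal(unname(r), c(0.30, 0.40, 0.30), tolerance = 1e-9)
  expect_equal(sum(r), 1)
  only_p <- c(calories = 100, protein = 10, fat = 0, carbohydrates = 0,
              fiber = 0)
  expect_equal(unname(energy_ratios(only_p, cfg)), c(1, 0, 0))
  set.seed(4)
  for (i in 1:20) {
    n <- c(calories = 400, protein = runif(1, 0, 50),
           fat = runif(1, 0, 40), carbohydrates = runif(1, 0, 90),
           fiber = runif(1, 0, 10))
    r <- energy_ratios(n, cfg)
    expect_equal(sum(r), 1, tolerance = 1e-12)
    denom <- 4 * n[["protein"]] + 4 * n[["carbohydrates"]] + 9 * n[["fat"]]
    expect_equal(r[["protein"]], 4 * n[["protein"]] / denom,
                 tolerance = 1e-12)
  }
  expect_error(energy_ratios(c(calories = 1, protein = 0, fat = 0,
                               carbohydrates = 0, fiber = 0), cfg),
               "undefined")
})

test_that("ratio balance is 1 at target and matches direct evaluation", {
  cfg <- nutrition_config()
  at_target <- c(protein = 0.3, carbohydrates = 0.4, fat = 0.3)
  expect_equal(ratio_balance(at_target, cfg), 1)
  skewed <- c(protein = 1, carbohydrates = 0, fat = 0)
  expect_equal(ratio_balance(skewed, cfg), (0.3 + 0.6 + 0.7) / 3)
  third <- c(protein = 1 / 3, carbohydrates = 1 / 3, fat = 1 / 3)
  expect_equal(ratio_balance(third, cfg),
               mean(1 - abs(1 / 3 - c(0.3, 0.4, 0.3))))
})

test_that("energy density penalty is flat below tau and exponential above", {
  cfg <- nutrition_config()   # tau = 1.5, kappa = 1
  expect_equal(energy_density_score(1.5 * 300, 300, cfg)$score, 1)
  expect_equal(energy_density_score(100, 300, cfg)$score, 1)
  at_plus <- energy_density_score((1.5 + 1) * 200, 200, cfg)
  expect_equal(at_plus$score, exp(-1), tolerance = 1e-12)
  # continuity at tau
  eps <- 1e-9
  expect_equal(energy_density_score((1.5 + eps) * 100, 100, cfg)$score, 1,
               tolerance = 1e-6)
  expect_error(energy_density_score(100, 0, cfg), "mass")
})

test_that("composite score is the configured weighted sum", {
  cfg <- nutrition_config()
  expect_equal(composite_score(1, 1, 1, cfg), 1)
  expect_equal(composite_score(1, 0, 0, cfg), 0.5)
  expect_equal(composite_score(0, 1, 0, cfg), 0.3)
  expect_equal(composite_score(0, 0, 1, cfg), 0.2)
  set.seed(8)
  for (i in 1:10) {
    x <- runif(3)
    expect_equal(composite_score(x[1], x[2], x[3], cfg),
                 sum(c(0.5, 0.3, 0.2) * x))
  }
  expect_error(nutrition_config(weights = c(0.5, 0.3, 0.1)), "sum to 1")
})

test_that("breakdown components stay in range and respect invariances", {
  set.seed(21)
  corpus <- generate_corpus(generator_config(corpus_size = 40, seed = 21))
  for (id in corpus_ids(corpus)) {
    b <- nutrition_breakdown(get_recipe(corpus, id))
    expect_true(all(b$a_m >= 0 & b$a_m <= 1))
    expect_true(b$a_abs >= 0 && b$a_abs <= 1)
    expect_true(b$a_ratio >= 0 && b$a_ratio <= 1)
    expect_true(b$a_ed >= 0 && b$a_ed <= 1)
    expect_true(b$s_nutrition >= 0 && b$s_nutrition <= 1)
    expect_gte(b$ed, 0)
  }
  # scaling mass and nutrients together leaves ED and ratios unchanged
  r <- fixture_recipe()
  r2 <- r
  r2$total_mass_g <- r$total_mass_g * 3
  r2$nutrients <- r$nutrients * 3
  b1 <- nutrition_breakdown(r); b2 <- nutrition_breakdown(r2)
  expect_equal(b2$ed, b1$ed)
  expect_equal(b2$ratios, b1$ratios)
})
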