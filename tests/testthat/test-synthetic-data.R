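test_that("scenarios validate their fields", {
  sc <- make_scenario()
  expect_equal(sc$m_species, 31L)
  expect_equal(sc$n_scattered, 69L)
  expect_equal(sc$elevation_range, c(200, 1000))
  expect_equal(sc$true_fixed$alpha, -2.23)
  expect_equal(unname(sc$true_random_sd),
               c(1.32, 1.01, 0.70, 0.40, 0.42))

  tiny <- make_scenario(m_species = 2)
  expect_equal(tiny$m_species, 2)

  expect_error(make_scenario(elevation_range = c(1000, 200)), "increasing")
  expect_error(make_scenario(banana = 1), "Unknown scenario field")
  expect_error(make_scenario(trait_ranges = list(
    sla = c(45, 5.6), seed_mass = c(0.1, 9259),
    wood_density = c(0.35, 0.85), max_height = c(5, 30)
  )), "sla")
})

test_that("the layout reproduces the field design", {
  sc <- make_scenario(seed = 13)
  plots <- gen_topography(sc)
  expect_equal(nrow(plots), 369) # 3 x 100 + 69
  expect_equal(sum(plots$set_id == "scattered"), 69)
  for (s in paste0("set", 1:3)) {
    set <- plots[plots$set_id == s, ]
    expect_equal(nrow(set), 100)
    expect_setequal(unique(set$row), 0:9)
    expect_setequal(unique(set$col), 0:9)
    # 10-m spacing within the hectare
    expect_equal(sort(unique(diff(sort(unique(set$x))))), 10)
  }
  expect_true(all(plots$elevation >= 200 & plots$elevation <= 1000))
  expect_true(all(plots$aspect >= 0 & plots$aspect < 360))
  expect_true(all(plots$slope >= 0))
  expect_identical(plots, gen_topography(sc))
})

test_that("trait fixtures honour the printed ranges exactly", {
  sc <- make_scenario(seed = 17)
  tr <- gen_traits(sc)
  expect_equal(nrow(tr), 31)
  expect_equal(range(tr$sla), c(5.60, 45.05))
  expect_equal(range(tr$seed_mass), c(0.10, 9259.00))
  expect_equal(range(tr$wood_density), c(0.35, 0.85))
  expect_equal(range(tr$max_height), c(5, 30))
  expect_equal(max(tr$max_height) / min(tr$max_height), 6)
  expect_identical(tr, gen_traits(sc))
})

test_that("occurrences are Bernoulli draws from the model", {
  sc <- make_scenario(m_species = 6, seed = 19)
  dat <- simulate_community(sc)
  occ <- as.matrix(dat$occurrence[, -1])
  expect_true(all(occ %in% c(0, 1)))
  truth <- attr(dat$occurrence, "truth")
  expect_equal(truth$fixed$alpha, -2.23)
  expect_equal(dim(truth$random$U), c(6, 4))
})

test_that("an intercept-only scenario reproduces the closed-form prevalence", {
  sc <- make_scenario(
    true_fixed = te_fixed(alpha = -2.23),
    true_random_sd = c(site = 0, intercept = 0, elevation = 0, slope = 0,
                       aspect = 0),
    seed = 23
  )
  plots <- gen_topography(sc)
  traits <- gen_traits(sc)
  draws <- unlist(lapply(1:9, function(k) {
    as.matrix(gen_occurrence(plots, traits, sc, seed = 100 + k)[, -1])
  }))
  expect_gt(length(draws), 1e5)
  expect_lt(abs(mean(draws) - plogis(-2.23)), 0.003)
})

test_that("prevalence rises with the true intercept", {
  base <- list(site = 0.5, intercept = 0.5, elevation = 0.3, slope = 0.2,
               aspect = 0.2)
  prev <- vapply(c(-3, -2, -1), function(a) {
    sc <- make_scenario(m_species = 10,
                        true_fixed = te_fixed(alpha = a),
                        true_random_sd = unlist(base), seed = 29)
    dat <- simulate_community(sc)
    mean(as.matrix(dat$occurrence[, -1]))
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("a strong height-elevation interaction flips occurrence trends", {
  b12 <- numeric(12)
  b12[10] <- -2 # MH x elevation, strongly negative
  sc <- make_scenario(
    true_fixed = te_fixed(alpha = -0.5, beta1 = c(0.2, 0, 0), beta12 = b12),
    true_random_sd = c(site = 0.3, intercept = 0.3, elevation = 0.2,
                       slope = 0.2, aspect = 0.2),
    seed = 37
  )
  plots <- gen_topography(sc)
  traits <- gen_traits(sc)
  occ <- gen_occurrence(plots, traits, sc)
  tall <- traits$species_id[which.max(traits$max_height)]
  short <- traits$species_id[which.min(traits$max_height)]
  slope_of <- function(sp) {
    coef(glm(occ[[sp]] ~ scale(log(plots$elevation)),
             family = binomial))[2]
  }
  expect_lt(slope_of(tall), 0)
  expect_gt(slope_of(short), 0)
})

test_that("communities serialize deterministically", {
  sc <- make_scenario(m_species = 4, n_sets = 1, n_scattered = 10,
                      seed = 41)
  d1 <- file.path(tempdir(), "comm1")
  d2 <- file.path(tempdir(), "comm2")
  write_community(simulate_community(sc), d1)
  write_community(simulate_community(sc), d2)
  for (f in c("plots.csv", "traits.csv", "occurrence.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$alpha, -2.23)
  expect_length(truth$beta12, 12)
})
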