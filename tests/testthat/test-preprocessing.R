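test_that("aspect folding maps compass bearings onto the south-north axis", {
  expect_equal(fold_aspect(0), 0)
  expect_equal(fold_aspect(270), 90)
  expect_equal(fold_aspect(359), 1)
  expect_equal(fold_aspect(180), 180)
  expect_equal(fold_aspect(360), 0) # exact-360 input treated as due north

  # idempotent on [0, 180] and maps [0, 360) onto [0, 180]
  grid <- seq(0, 359.9, by = 0.1)
  folded <- fold_aspect(grid)
  expect_true(all(folded >= 0 & folded <= 180))
  expect_equal(fold_aspect(folded), folded)

  expect_error(fold_aspect(-1), "Aspect")
  expect_error(fold_aspect(c(10, 361), ids = c("pA", "pB")), "pB")
})

test_that("log transform honours the offset policy", {
  lt <- log_transform(c(exp(1), 1))
  expect_equal(lt$values, c(1, 0))
  expect_equal(lt$offset, 0)

  # zeros trigger an offset of half the smallest positive value
  lt0 <- log_transform(c(0, 2, 8))
  expect_equal(lt0$offset, 1)
  expect_equal(lt0$values, log(c(1, 3, 9)))

  expect_error(log_transform(c(0, 1), offset_policy = "none"), "Non-positive")
  expect_error(log_transform(c(-1, 1)), "Negative")
})

test_that("2-SD standardization centres and halves the spread", {
  st <- standardize_2sd(c(1, 3))
  expect_equal(st$values, c(-1, 1) / (2 * sqrt(2)))
  expect_equal(st$center, 2)
  expect_equal(st$scale, 2 * sqrt(2))

  for (seed in 1:5) {
    x <- with_seed(seed, rexp(50))
    st <- standardize_2sd(x)
    expect_equal(mean(st$values), 0, tolerance = 1e-12)
    expect_equal(sd(st$values), 0.5, tolerance = 1e-12)
  }

  expect_error(standardize_2sd(c(5, 5, 5)), "constant")
})

make_raw_tables <- function(seed = 1, n = 12, m = 5) {
  with_seed(seed, list(
    plots = tibble::tibble(
      plot_id = paste0("p", seq_len(n)),
      elevation = runif(n, 200, 1000),
      aspect = runif(n, 0, 360),
      slope = c(0, runif(n - 1, 1, 40)) # a flat plot exercises the offset
    ),
    traits = tibble::tibble(
      species_id = paste0("s", seq_len(m)),
      sla = runif(m, 5.6, 45),
      seed_mass = exp(runif(m, log(0.1), log(9000))),
      wood_density = runif(m, 0.35, 0.85),
      max_height = runif(m, 5, 30)
    )
  ))
}

test_that("build_design produces the 16-term standardized design", {
  raw <- make_raw_tables()
  d <- build_design(raw$plots, raw$traits)

  expect_s3_class(d, "te_design")
  expect_equal(nrow(d$interactions), 12)
  expect_length(d$terms, 16)
  expect_equal(d$terms[1:4], c("Intercept", "Elevation", "Slope", "Aspect"))
  expect_equal(d$interactions$term[1:3],
               c("SLA: Elevation", "SLA: Slope", "SLA: Aspect"))
  expect_equal(d$interactions$term[10:12],
               c("MH: Elevation", "MH: Slope", "MH: Aspect"))

  for (M in list(as.matrix(d$X[, -1]), as.matrix(d$Z[, -1]))) {
    expect_true(all(abs(colMeans(M)) < 1e-10))
    expect_true(all(abs(apply(M, 2, sd) - 0.5) < 1e-10))
  }

  # aspect is the one column that is not log-transformed
  rec <- d$records
  expect_false(rec$log_applied[rec$name == "aspect"])
  expect_true(all(rec$log_applied[rec$name != "aspect"]))
  expect_true(all(rec$scale > 0))
})

test_that("a reduced trait/environment set gives a reduced index", {
  expect_equal(nrow(interaction_index("max_height", "elevation")), 1)
  expect_equal(interaction_index("max_height", "elevation")$term,
               "MH: Elevation")
})

test_that("standardization records round-trip raw values", {
  raw <- make_raw_tables(seed = 3)
  d <- build_design(raw$plots, raw$traits)
  folded <- fold_aspect(raw$plots$aspect)
  raw_cols <- list(
    elevation = raw$plots$elevation, slope = raw$plots$slope,
    aspect = folded, sla = raw$traits$sla,
    seed_mass = raw$traits$seed_mass,
    wood_density = raw$traits$wood_density,
    max_height = raw$traits$max_height
  )
  std_cols <- c(as.list(d$X[, -1]), as.list(d$Z[, -1]))
  for (nm in names(raw_cols)) {
    rec <- d$records[d$records$name == nm, ]
    expect_equal(apply_standardization(raw_cols[[nm]], rec),
                 std_cols[[nm]], tolerance = 1e-12)
    expect_equal(invert_standardization(std_cols[[nm]], rec),
                 raw_cols[[nm]], tolerance = 1e-10)
  }
})

test_that("build_design validates its inputs", {
  raw <- make_raw_tables()
  traits_na <- raw$traits
  traits_na$seed_mass[2] <- NA
  expect_error(build_design(raw$plots, traits_na), "s2")
  expect_error(build_design(raw$plots[, -2], raw$traits), "elevation")
  plots_dup <- raw$plots
  plots_dup$plot_id[2] <- "p1"
  expect_error(build_design(plots_dup, raw$traits), "Duplicate")
})

test_that("a design can be written with its standardization sidecar", {
  raw <- make_raw_tables()
  d <- build_design(raw$plots, raw$traits)
  dir <- file.path(tempdir(), "design_out")
  write_design(d, dir)
  expect_true(file.exists(file.path(dir, "X.csv")))
  expect_true(file.exists(file.path(dir, "Z.csv")))
  rec <- jsonlite::read_json(file.path(dir, "standardization.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(rec), 7)
  expect_equal(rec$scale, d$records$scale)
})
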