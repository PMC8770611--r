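#' Reference fixed effects of the simulation scenario
#'
#' The default truths of the synthetic generator: the point estimates of
#' the reference topographic fit (intercept -2.23; elevation 0.27, slope
#' -0.15, aspect 0.34; and the 12 trait-environment interaction
#' coefficients in trait-major order SLA, SM, SD, MH by elevation, slope,
#' aspect).
#'
#' @return A [te_fixed()] bundle.
#' @export
reference_fixed_effects <- function() {
  te_fixed(
    alpha = -2.23,
    beta1 = c(elevation = 0.27, slope = -0.15, aspect = 0.34),
    beta12 = c(
      0.13, 0.07, -0.02,   # SLA x elevation, slope, aspect
      -0.14, 0.18, 0.29,   # SM
      -0.08, -0.12, 0.04,  # SD
      -0.32, -0.06, -0.18  # MH
    )
  )
}

#' Reference random-effect SDs of the simulation scenario
#'
#' @return Named numeric vector: site intercept SD and species intercept
#'   and environmental-slope SDs.
#' @export
reference_random_sd <- function() {
  c(site = 1.32, intercept = 1.01, elevation = 0.70, slope = 0.40,
    aspect = 0.42)
}

#' Define a simulation scenario
#'
#' A scenario fixes everything the synthetic community generator needs:
#' the field layout (3 one-hectare sets of one hundred 10 m x 10 m plots
#' plus 69 scattered plots), the species pool (31 woody species with
#' trait ranges as observed: SLA 5.60-45.05, seed mass 0.10-9259 mg,
#' wood density 0.35-0.85, maximum height 5-30 m), the elevation range
#' (200-1000 m), and the true model parameters (defaults: the reference
#' fit's point estimates).
#'
#' @param ... Overrides of the default fields (`n_sets`, `n_scattered`,
#'   `m_species`, `true_fixed`, `true_random_sd`, `species_corr`,
#'   `trait_ranges`, `elevation_range`, `seed`). Unknown fields error.
#' @return A list of class `te_scenario`.
#' @examples
#' make_scenario(m_species = 2, seed = 1) # tiny oracle-test scenario
#' @export
make_scenario <- function(...) {
  default <- list(
    n_sets = 3L,
    n_scattered = 69L,
    m_species = 31L,
    true_fixed = reference_fixed_effects(),
    true_random_sd = reference_random_sd(),
    species_corr = NULL, # NULL = independent species random effects
    trait_ranges = list(
      sla = c(5.60, 45.05),
      seed_mass = c(0.10, 9259.00),
      wood_density = c(0.35, 0.85),
      max_height = c(5, 30)
    ),
    elevation_range = c(200, 1000),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(default))
  if (length(bad)) {
    abort(paste("Unknown scenario field(s):", paste(bad, collapse = ", ")))
  }
  sc <- utils::modifyList(default, over)
  if (diff(sc$elevation_range) <= 0) {
    abort("elevation_range must be increasing (min, max).")
  }
  for (tr in names(sc$trait_ranges)) {
    rg <- sc$trait_ranges[[tr]]
    if (length(rg) != 2 || any(rg <= 0) || diff(rg) <= 0) {
      abort(paste0("trait_ranges$", tr,
                   " must be a positive increasing (min, max) pair."))
    }
  }
  if (any(sc$true_random_sd < 0)) abort("Random-effect SDs must be >= 0.")
  stopifnot(sc$m_species >= 1, sc$n_sets >= 0, sc$n_scattered >= 0)
  structure(sc, class = "te_scenario")
}

#' Generate the topographic plot layout
#'
#' Emulates the field design: `n_sets` one-hectare sets of one hundred
#' 10 m x 10 m plots on 10 x 10 grids plus `n_scattered` scattered
#' plots. Each set sits on a smooth hillside: a linear elevation gradient
#' in a random downhill direction plus low-frequency relief, with slope
#' derived from the local gradient and aspect from the downhill
#' direction. Scattered plots are spread over the whole elevation range.
#'
#' @param scenario A [make_scenario()] object.
#' @param seed RNG seed (defaults to the scenario's seed).
#' @return A tibble with `plot_id`, `set_id`, `row`, `col`, `x`, `y`,
#'   `elevation` (m, within the scenario range), `aspect` (compass
#'   degrees in `[0, 360)`), `slope` (degrees >= 0).
#' @export
gen_topography <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "te_scenario"))
  er <- scenario$elevation_range
  with_seed(seed, {
    sets <- purrr::map(seq_len(scenario$n_sets), function(si) {
      # set centres staggered across the mountainside and elevation band
      base_elev <- er[1] + (si - 0.5) / scenario$n_sets * diff(er) * 0.9
      ox <- (si - 1) * 600
      oy <- runif(1, 0, 400)
      g <- tidyr::expand_grid(row = 0:9, col = 0:9)
      x <- ox + g$col * 10
      y <- oy + g$row * 10
      # linear gradient in a random downhill direction + smooth relief
      theta <- runif(1, 0, 2 * pi)
      grad <- runif(1, 0.25, 0.55) # m elevation per m ground
      ph1 <- runif(2, 0, 2 * pi); ph2 <- runif(2, 0, 2 * pi)
      relief <- 6 * sin(2 * pi * x / 70 + ph1[1]) * cos(2 * pi * y / 90 + ph1[2]) +
        4 * sin(2 * pi * (x + y) / 55 + ph2[1])
      elev <- base_elev + grad * (cos(theta) * (x - ox - 45) +
                                    sin(theta) * (y - oy - 45)) + relief
      elev <- pmin(pmax(elev, er[1]), er[2])
      slope_deg <- pmin(pmax(
        atan(grad) * 180 / pi + rnorm(100, 0, 4), 0.5), 45)
      # downhill compass bearing of the gradient, east of north
      downhill <- (atan2(-sin(theta), -cos(theta)) * 180 / pi) %% 360
      aspect <- (downhill + rnorm(100, 0, 25)) %% 360
      tibble(
        plot_id = sprintf("set%d_r%dc%d", si, g$row, g$col),
        set_id = paste0("set", si),
        row = g$row, col = g$col, x = x, y = y,
        elevation = elev, aspect = aspect, slope = slope_deg
      )
    })
    ns <- scenario$n_scattered
    scattered <- tibble(
      plot_id = sprintf("scat_%02d", seq_len(ns)),
      set_id = "scattered",
      row = NA_integer_, col = NA_integer_,
      x = runif(ns, -200, scenario$n_sets * 600 + 300),
      y = runif(ns, -300, 900),
      elevation = runif(ns, er[1], er[2]),
      aspect = runif(ns, 0, 360),
      slope = pmin(pmax(rnorm(ns, 18, 9), 0.5), 45)
    )
    dplyr::bind_rows(sets, if (ns > 0) scattered)
  })
}

#' Generate a species trait table
#'
#' Draws `m_species` species with the four traits log-uniform within the
#' scenario ranges. The range endpoints are pinned (for each trait, one
#' species takes the minimum and another the maximum), so fixture
#' extremes match the scenario exactly -- e.g. the tallest species is 30 m,
#' six times the shortest (5 m). This is a fixture policy, not an
#' estimate of any real community's trait distribution.
#'
#' @inheritParams gen_topography
#' @return A tibble with `species_id`, `sla`, `seed_mass`,
#'   `wood_density`, `max_height`.
#' @export
gen_traits <- function(scenario, seed = scenario$seed + 1L) {
  stopifnot(inherits(scenario, "te_scenario"))
  m <- scenario$m_species
  with_seed(seed, {
    draw <- function(rg) {
      v <- exp(runif(m, log(rg[1]), log(rg[2])))
      if (m >= 2) {
        at <- sample(m, 2)
        v[at[1]] <- rg[1]
        v[at[2]] <- rg[2]
      }
      v
    }
    tibble(
      species_id = sprintf("sp%02d", seq_len(m)),
      sla = draw(scenario$trait_ranges$sla),
      seed_mass = draw(scenario$trait_ranges$seed_mass),
      wood_density = draw(scenario$trait_ranges$wood_density),
      max_height = draw(scenario$trait_ranges$max_height)
    )
  })
}

#' Simulate occurrences from the trait-environment model
#'
#' Standardizes the supplied plots and traits exactly as [build_design()]
#' does, draws species random effects from the covariance assembled from
#' the scenario's SDs (independent components unless `species_corr` is
#' set), site effects from the site SD, and occurrence indicators
#' `y_ij ~ Bernoulli(plogis(eta_ij))` from the model's linear predictor
#' at the scenario's true fixed effects.
#'
#' @param plots Plot table (the plots to simulate on; standardization is
#'   over exactly these plots).
#' @param traits Trait table.
#' @inheritParams gen_topography
#' @return A wide occurrence tibble (`plot_id` plus one 0/1 column per
#'   species) with attribute `truth`: the true fixed effects, the drawn
#'   random effects, and the design used.
#' @export
gen_occurrence <- function(plots, traits, scenario,
                           seed = scenario$seed + 2L) {
  stopifnot(inherits(scenario, "te_scenario"))
  design <- build_design(plots, traits)
  X <- as.matrix(design$X[, -1])
  Z <- as.matrix(design$Z[, -1])
  n <- nrow(X); m <- nrow(Z)
  sds <- scenario$true_random_sd
  s <- 1 + ncol(X)
  sd_vec <- c(sds["intercept"], sds[colnames(X)])
  R <- if (is.null(scenario$species_corr)) diag(s) else scenario$species_corr
  stopifnot(nrow(R) == s, ncol(R) == s)
  Sigma <- diag(sd_vec) %*% R %*% diag(sd_vec)
  with_seed(seed, {
    # diagonal factor when effects are independent (allows zero SDs)
    L <- if (is.null(scenario$species_corr)) diag(sd_vec, s) else t(chol(Sigma))
    U <- t(L %*% matrix(rnorm(s * m), s, m)) # m x s
    cvec <- rnorm(n, 0, sds["site"])
    eta <- linear_predictor(
      scenario$true_fixed, X, Z,
      random = list(a = U[, 1], b = U[, -1, drop = FALSE], c = cvec)
    )
    Y <- matrix(rbinom(n * m, 1, stats::plogis(eta)), n, m)
    colnames(Y) <- design$Z$species_id
    occ <- dplyr::bind_cols(tibble(plot_id = design$X$plot_id),
                            tibble::as_tibble(Y))
    attr(occ, "truth") <- list(
      fixed = scenario$true_fixed,
      random = list(U = U, c = cvec),
      Sigma = Sigma, sigma_site = unname(sds["site"]),
      design = design, seed = seed
    )
    occ
  })
}

#' Simulate a full synthetic community
#'
#' Convenience wrapper: topography, traits and occurrences from one
#' scenario, with seeds derived from the scenario seed so the whole
#' community is reproducible byte-for-byte.
#'
#' @inheritParams gen_topography
#' @return A list with `plots`, `traits`, `occurrence` (with its `truth`
#'   attribute) and the `scenario`.
#' @export
simulate_community <- function(scenario, seed = scenario$seed) {
  plots <- gen_topography(scenario, seed = seed)
  traits <- gen_traits(scenario, seed = seed + 1L)
  occ <- gen_occurrence(plots, traits, scenario, seed = seed + 2L)
  list(plots = plots, traits = traits, occurrence = occ,
       scenario = scenario)
}

#' Write a simulated community to CSV plus a JSON truth sidecar
#'
#' @param community A [simulate_community()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(community$plots, file.path(dir, "plots.csv"))
  readr::write_csv(community$traits, file.path(dir, "traits.csv"))
  readr::write_csv(community$occurrence, file.path(dir, "occurrence.csv"))
  truth <- attr(community$occurrence, "truth")
  jsonlite::write_json(
    list(
      alpha = truth$fixed$alpha,
      beta1 = truth$fixed$beta1,
      beta12 = truth$fixed$beta12,
      random_sd = as.list(community$scenario$true_random_sd),
      seed = community$scenario$seed
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
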