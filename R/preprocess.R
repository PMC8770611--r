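#' Fold compass aspect onto a north-south axis
#'
#' Converts a compass aspect in degrees (0-360, clockwise from north) to
#' degrees of south-north orientation: 0 is due north and 180 due south,
#' with east- and west-facing slopes folded onto each other. Values above
#' 180 are converted by subtracting 360 and multiplying by -1, so the
#' folded value measures "southness" regardless of east/west exposure.
#'
#' An input of exactly 360 is treated as 0 before folding.
#'
#' @param degrees Numeric vector of aspects in `[0, 360]`.
#' @param ids Optional vector of plot identifiers used in error messages.
#' @return Numeric vector in `[0, 180]`.
#' @examples
#' fold_aspect(c(0, 90, 180, 270, 359))
#' @export
fold_aspect <- function(degrees, ids = NULL) {
  if (!is.numeric(degrees)) abort("`degrees` must be numeric.")
  bad <- !is.finite(degrees) | degrees < 0 | degrees > 360
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad) else ids[bad]
    abort(paste0(
      "Aspect values outside [0, 360] for plot(s): ",
      paste(utils::head(who, 5), collapse = ", "),
      ". Aspect must be a compass bearing in degrees."
    ))
  }
  degrees[degrees == 360] <- 0
  ifelse(degrees <= 180, degrees, (degrees - 360) * -1)
}

#' Log-transform a covariate with an explicit offset policy
#'
#' Skewed covariates enter the model on the natural-log scale. Zeros are
#' plausible for some variables (a perfectly flat plot has slope 0), so a
#' recorded offset keeps the transform defined and invertible: under the
#' default `"half_min_positive"` policy, if any zero is present the offset
#' is half the smallest positive observed value; otherwise it is 0.
#'
#' @param x Numeric vector, non-negative under the default policy.
#' @param offset_policy `"half_min_positive"` or `"none"` (error on any
#'   non-positive value).
#' @return List with `values` (log-transformed) and `offset` (the value
#'   added before taking logs).
#' @export
log_transform <- function(x, offset_policy = c("half_min_positive", "none")) {
  offset_policy <- match.arg(offset_policy)
  if (any(!is.finite(x))) abort("Non-finite values in covariate to log-transform.")
  if (any(x < 0)) abort("Negative values cannot be log-transformed.")
  offset <- 0
  if (any(x == 0)) {
    if (offset_policy == "none") {
      abort("Non-positive values under the zero-offset log policy.")
    }
    pos <- x[x > 0]
    if (length(pos) == 0) abort("All-zero covariate cannot be log-transformed.")
    offset <- min(pos) / 2
  }
  list(values = log(x + offset), offset = offset)
}

#' Centre and scale by twice the standard deviation
#'
#' Centres a covariate at its mean and divides by twice its sample
#' standard deviation, so that standardized columns have SD 0.5 and a
#' one-unit change spans two SDs of the raw variable. On this scale the
#' magnitudes of coefficients of continuous predictors are comparable
#' with those of binary ones, and the model intercept is the prevalence
#' at mean trait and mean environmental conditions.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return List with `values` (standardized vector), `center` (mean) and
#'   `scale` (twice the sample SD).
#' @examples
#' standardize_2sd(c(1, 3))$values
#' @export
standardize_2sd <- function(x) {
  if (any(!is.finite(x))) abort("Non-finite values in covariate to standardize.")
  if (length(x) < 2) abort("Need at least 2 values to standardize.")
  s <- stats::sd(x)
  if (s == 0) abort("Degenerate input: covariate is constant, scale would be 0.")
  list(values = (x - mean(x)) / (2 * s), center = mean(x), scale = 2 * s)
}

# One covariate through the full convention: optional log, then 2-SD scaling.
# Returns the standardized values plus a one-row record sufficient to redo
# or invert the transform exactly.
standardize_covariate <- function(x, name, log_apply = TRUE,
                                  offset_policy = "half_min_positive") {
  offset <- 0
  if (log_apply) {
    lt <- log_transform(x, offset_policy)
    x <- lt$values
    offset <- lt$offset
  }
  st <- standardize_2sd(x)
  list(
    values = st$values,
    record = tibble(
      name = name, log_applied = log_apply, offset = offset,
      center = st$center, scale = st$scale
    )
  )
}

#' Apply or invert a recorded standardization
#'
#' `apply_standardization()` replays a recorded transform (optional
#' offset + log, then 2-SD centring/scaling) on raw values;
#' `invert_standardization()` maps standardized values back to the raw
#' scale. Applying then inverting recovers the input to numerical
#' tolerance, so a fitted model is reproducible bit-for-bit from raw
#' inputs plus its records.
#'
#' @param x Numeric vector (raw for apply, standardized for invert).
#' @param record A one-row record as produced by [build_design()] (fields
#'   `name`, `log_applied`, `offset`, `center`, `scale`).
#' @return Numeric vector.
#' @export
apply_standardization <- function(x, record) {
  stopifnot(nrow(record) == 1)
  if (record$log_applied) x <- log(x + record$offset)
  (x - record$center) / record$scale
}

#' @rdname apply_standardization
#' @export
invert_standardization <- function(x, record) {
  stopifnot(nrow(record) == 1)
  x <- x * record$scale + record$center
  if (record$log_applied) x <- exp(x) - record$offset
  x
}

# Canonical variable orderings; interaction order is trait-major so the
# fixed-effect reporting order is Intercept, 3 environment main effects,
# then SLA:Elevation ... MH:Aspect.
te_environments <- function() c("elevation", "slope", "aspect")
te_traits <- function() c("sla", "seed_mass", "wood_density", "max_height")
te_trait_labels <- function() {
  c(sla = "SLA", seed_mass = "SM", wood_density = "SD", max_height = "MH")
}
te_env_labels <- function() {
  c(elevation = "Elevation", slope = "Slope", aspect = "Aspect")
}

#' Interaction index of trait-environment pairs
#'
#' The fixed documented ordering of the trait-by-environment interaction
#' terms: traits SLA, SM (seed mass), SD (stem wood density), MH (maximum
#' height) crossed with environments elevation, slope, aspect, trait-major.
#'
#' @param traits,environments Character vectors of variable names; the
#'   defaults give the full 12-pair index.
#' @return A tibble with columns `term`, `trait`, `environment`.
#' @export
interaction_index <- function(traits = te_traits(),
                              environments = te_environments()) {
  tl <- te_trait_labels()
  el <- te_env_labels()
  tidyr::expand_grid(trait = traits, environment = environments) %>%
    mutate(term = paste0(
      ifelse(.data$trait %in% names(tl), tl[.data$trait], .data$trait), ": ",
      ifelse(.data$environment %in% names(el), el[.data$environment],
             .data$environment)
    )) %>%
    select("term", "trait", "environment")
}

#' Build the standardized design used by the trait-environment model
#'
#' Applies the full preprocessing convention to a plot table and a species
#' trait table: aspect is folded to a 0-180 south-north orientation, every
#' other variable is natural-log transformed (skewed raw distributions),
#' and all columns are centred and divided by twice their SD. Environments
#' are standardized over the plots supplied here, so a subsampled dataset
#' re-standardizes on its own plots; traits are standardized over the
#' modelled species.
#'
#' @param plots Data frame with columns `plot_id`, `elevation` (m),
#'   `aspect` (compass degrees), `slope` (degrees).
#' @param traits Data frame with columns `species_id`, `sla`, `seed_mass`,
#'   `wood_density`, `max_height`.
#' @return An object of class `te_design`: a list with
#'   \describe{
#'     \item{X}{tibble of `plot_id` plus 3 standardized environment columns;}
#'     \item{Z}{tibble of `species_id` plus 4 standardized trait columns;}
#'     \item{records}{tibble of standardization records, one per column;}
#'     \item{interactions}{the 12-row trait-environment interaction index;}
#'     \item{terms}{the 16 fixed-effect term labels in reporting order.}
#'   }
#' @examples
#' plots <- tibble::tibble(plot_id = paste0("p", 1:6),
#'   elevation = c(300, 450, 600, 750, 900, 350),
#'   aspect = c(10, 200, 350, 90, 180, 270), slope = c(5, 10, 20, 30, 15, 8))
#' traits <- tibble::tibble(species_id = c("s1", "s2", "s3"),
#'   sla = c(6, 20, 45), seed_mass = c(0.1, 10, 9000),
#'   wood_density = c(0.35, 0.6, 0.85), max_height = c(5, 15, 30))
#' d <- build_design(plots, traits)
#' d$terms
#' @export
build_design <- function(plots, traits) {
  need_p <- c("plot_id", te_environments())
  need_t <- c("species_id", te_traits())
  miss <- setdiff(need_p, names(plots))
  if (length(miss)) abort(paste("Plot table missing column(s):", paste(miss, collapse = ", ")))
  miss <- setdiff(need_t, names(traits))
  if (length(miss)) abort(paste("Trait table missing column(s):", paste(miss, collapse = ", ")))
  na_t <- te_traits()[purrr::map_lgl(te_traits(), ~ anyNA(traits[[.x]]))]
  if (length(na_t)) {
    bad_sp <- traits$species_id[rowSums(is.na(traits[te_traits()])) > 0]
    abort(paste(
      "Missing trait value(s) for modelled species:",
      paste(bad_sp, collapse = ", ")
    ))
  }
  if (anyNA(plots[need_p])) abort("Missing values in plot table.")
  if (anyNA(traits$species_id) || anyNA(plots$plot_id)) abort("Missing ids.")
  if (anyDuplicated(plots$plot_id)) abort("Duplicate plot ids in plot table.")
  if (anyDuplicated(traits$species_id)) abort("Duplicate species ids in trait table.")

  folded <- fold_aspect(plots$aspect, ids = plots$plot_id)

  std <- list(
    elevation = standardize_covariate(plots$elevation, "elevation", TRUE),
    slope     = standardize_covariate(plots$slope, "slope", TRUE),
    # aspect is already an orientation score; it is the one untransformed
    # variable
    aspect    = standardize_covariate(folded, "aspect", FALSE),
    sla          = standardize_covariate(traits$sla, "sla", TRUE),
    seed_mass    = standardize_covariate(traits$seed_mass, "seed_mass", TRUE),
    wood_density = standardize_covariate(traits$wood_density, "wood_density", TRUE),
    max_height   = standardize_covariate(traits$max_height, "max_height", TRUE)
  )

  X <- tibble(
    plot_id = plots$plot_id,
    elevation = std$elevation$values,
    slope = std$slope$values,
    aspect = std$aspect$values
  )
  Z <- tibble(
    species_id = traits$species_id,
    sla = std$sla$values,
    seed_mass = std$seed_mass$values,
    wood_density = std$wood_density$values,
    max_height = std$max_height$values
  )
  ii <- interaction_index()
  out <- list(
    X = X, Z = Z,
    records = purrr::list_rbind(purrr::map(std, "record")),
    interactions = ii,
    terms = c("Intercept", unname(te_env_labels()), ii$term)
  )
  class(out) <- "te_design"
  out
}

#' @export
print.te_design <- function(x, ...) {
  cat("<te_design> ", nrow(x$X), " plots x ", nrow(x$Z), " species; ",
      length(x$terms), " fixed-effect terms (",
      nrow(x$interactions), " trait-environment interactions)\n", sep = "")
  invisible(x)
}

#' Write a standardized design to disk
#'
#' Writes `X.csv` and `Z.csv` (standardized design tables) plus a
#' `standardization.json` sidecar of the transformation records, so any
#' fit can be reproduced exactly from the raw tables.
#'
#' @param design A `te_design` from [build_design()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir) {
  stopifnot(inherits(design, "te_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(design$X, file.path(dir, "X.csv"))
  readr::write_csv(design$Z, file.path(dir, "Z.csv"))
  jsonlite::write_json(design$records, file.path(dir, "standardization.json"),
                       digits = NA)
  invisible(dir)
}
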