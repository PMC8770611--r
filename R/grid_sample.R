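#' Partition a 10 x 10 plot set into a 3 x 3 sampling grid
#'
#' A side of 10 plots is split into contiguous bands of 4/3/3 rows
#' (columns), giving cell sizes 16, 12, 12, 12, 9, 9, 12, 9, 9 for the
#' default layout. The partition is a design choice: contiguous and as
#' near-equal as a 10-by-10 layout allows.
#'
#' @param n_side Number of rows (or columns) on one side of the set.
#' @param n_bands Number of grid bands along that side.
#' @return Integer vector mapping index `0:(n_side-1)` to band `1:n_bands`.
#' @keywords internal
grid_bands <- function(n_side = 10, n_bands = 3) {
  base <- n_side %/% n_bands
  extra <- n_side %% n_bands
  sizes <- rep(base, n_bands) + c(rep(1, extra), rep(0, n_bands - extra))
  rep(seq_len(n_bands), times = sizes)
}

#' Grid-subsample plots from one plot set
#'
#' Lays a `grid_rows` x `grid_cols` grid over a 10 x 10 plot set and draws
#' `k` plots without replacement from each cell, thinning the 100
#' contiguous plots to limit spatial autocorrelation while retaining
#' coverage of the whole hectare.
#'
#' @param plots Data frame of one set's plots, with `plot_id`, `row`,
#'   `col` (0-9 grid indices).
#' @param grid_rows,grid_cols Grid dimensions (default 3 x 3).
#' @param k Plots to draw per cell (default 3).
#' @param seed Integer RNG seed; the draw is deterministic given the seed.
#' @return Character vector of `grid_rows * grid_cols * k` plot ids.
#' @export
subsample_plot_set <- function(plots, grid_rows = 3, grid_cols = 3, k = 3,
                               seed = 1L) {
  stopifnot(all(c("plot_id", "row", "col") %in% names(plots)))
  if (anyDuplicated(plots$plot_id)) abort("Duplicate plot ids within a set.")
  rb <- grid_bands(max(plots$row) + 1, grid_rows)
  cb <- grid_bands(max(plots$col) + 1, grid_cols)
  cell <- paste0("r", rb[plots$row + 1], "c", cb[plots$col + 1])
  by_cell <- split(plots$plot_id, cell)
  if (length(by_cell) != grid_rows * grid_cols) {
    abort("Empty grid cell(s); every cell must contain plots.")
  }
  short <- names(by_cell)[lengths(by_cell) < k]
  if (length(short)) {
    abort(paste0("Cannot draw ", k, " plots from cell(s) ",
                 paste(short, collapse = ", "), " with fewer plots."))
  }
  with_seed(seed, {
    # fixed cell order so the draw depends only on the seed
    unlist(lapply(by_cell[sort(names(by_cell))], sample, size = k),
           use.names = FALSE)
  })
}

#' Assemble one modelling dataset of 150 plots
#'
#' Draws 27 plots (3 per cell of a 3 x 3 grid) from each plot set and
#' unions them with all scattered plots: with the default field layout of
#' 3 sets plus 69 scattered plots this yields 27 x 3 + 69 = 150 plots.
#'
#' @param plots Data frame of all plots with `plot_id`, `set_id` (the
#'   scattered plots carry `set_id = "scattered"`), and `row`/`col`
#'   indices within sets.
#' @param seed Integer RNG seed.
#' @param replicate_id Integer label stored with the dataset.
#' @inheritParams subsample_plot_set
#' @return A tibble with columns `replicate_id`, `plot_id`, `seed`.
#' @export
assemble_modelling_dataset <- function(plots, seed = 1L, replicate_id = 1L,
                                       grid_rows = 3, grid_cols = 3, k = 3) {
  stopifnot(all(c("plot_id", "set_id") %in% names(plots)))
  if (anyDuplicated(plots$plot_id)) {
    dup <- plots$plot_id[duplicated(plots$plot_id)]
    abort(paste("Duplicate plot id(s) across inputs:",
                paste(unique(dup), collapse = ", ")))
  }
  set_ids <- sort(setdiff(unique(plots$set_id), "scattered"))
  picked <- character(0)
  for (i in seq_along(set_ids)) {
    set_plots <- plots[plots$set_id == set_ids[i], ]
    picked <- c(picked, subsample_plot_set(
      set_plots, grid_rows, grid_cols, k,
      # one derived seed per set so sets are sampled independently
      seed = seed * 13L + i
    ))
  }
  scattered <- plots$plot_id[plots$set_id == "scattered"]
  tibble(
    replicate_id = as.integer(replicate_id),
    plot_id = c(picked, scattered),
    seed = as.integer(seed)
  )
}

#' Generate replicate grid-sampled datasets
#'
#' Repeats the grid-sampling strategy `n_replicates` times (default 10)
#' with seeds derived as `base_seed + replicate index`, yielding
#' replicate modelling datasets whose plot selections differ only in the
#' within-cell random draws.
#'
#' @inheritParams assemble_modelling_dataset
#' @param n_replicates Number of replicate datasets.
#' @param base_seed Integer; replicate `r` uses seed `base_seed + r`.
#' @return A tibble with columns `replicate_id`, `plot_id`, `seed`
#'   (long format, one row per selected plot per replicate).
#' @examples
#' sc <- make_scenario(seed = 7)
#' plots <- gen_topography(sc)
#' reps <- generate_replicates(plots, n_replicates = 2, base_seed = 7)
#' table(reps$replicate_id)
#' @export
generate_replicates <- function(plots, n_replicates = 10, base_seed = 1L,
                                grid_rows = 3, grid_cols = 3, k = 3) {
  stopifnot(n_replicates >= 1)
  purrr::map(seq_len(n_replicates), function(r) {
    assemble_modelling_dataset(
      plots, seed = base_seed + r, replicate_id = r,
      grid_rows = grid_rows, grid_cols = grid_cols, k = k
    )
  }) %>% purrr::list_rbind()
}

#' Write replicate plot selections to JSON
#'
#' @param replicates Tibble from [generate_replicates()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(replicates, path) {
  out <- replicates %>%
    group_by(.data$replicate_id) %>%
    summarise(seed = .data$seed[1], plot_ids = list(.data$plot_id),
              .groups = "drop")
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
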