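#' Write and read benchmark bundles
#'
#' A bundle directory holds plain-text artifacts only: `design.csv` (one row
#' per treatment), `grid.csv` (the missingness mask), `observations.csv`,
#' `truth.json` (generating parameters and error scales) and `manifest.json`
#' (preset, seeds, package version). `read_bundle()` restores a `gp_bundle`
#' that round-trips through [design_bookkeeping()], [joint_loglik()] and the
#' fitting functions.
#'
#' @param bundle A `gp_bundle` from [make_benchmark()].
#' @param dir Directory path (created if needed).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` the
#'   restored bundle.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "gp_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$design$treatments, file.path(dir, "design.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$design$grid, file.path(dir, "grid.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(
    list(
      variant = truth$variant,
      params = lapply(truth$params, as.list),
      error_params = as.list(truth$error_params),
      sharing = as.list(truth$sharing),
      C_i_max = bundle$scaling$C_i_max, R_0 = bundle$scaling$R_0,
      design_config = unclass(bundle$design$config),
      design_seed = bundle$design$seed
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- structure(
    list(
      variant = tj$variant,
      params = lapply(tj$params, unlist),
      error_params = unlist(tj$error_params),
      sharing = unlist(tj$sharing)
    ),
    class = "gp_truth"
  )
  cfg <- tj$design_config
  cfg$endpoint_targets <- if (!is.null(cfg$endpoint_targets)) unlist(cfg$endpoint_targets)
  class(cfg) <- "gp_design_config"
  design <- structure(
    list(
      treatments = tibble::as_tibble(
        utils::read.csv(file.path(dir, "design.csv"), stringsAsFactors = FALSE)
      ),
      grid = tibble::as_tibble(
        utils::read.csv(file.path(dir, "grid.csv"), stringsAsFactors = FALSE)
      ),
      config = cfg, seed = tj$design_seed
    ),
    class = "gp_design"
  )
  structure(
    list(
      design = design,
      observations = tibble::as_tibble(
        utils::read.csv(file.path(dir, "observations.csv"), stringsAsFactors = FALSE)
      ),
      scaling = scaling_context(tj$C_i_max, tj$R_0),
      truth = truth,
      manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                     simplifyVector = TRUE)
    ),
    class = "gp_bundle"
  )
}

#' Export a trajectory as tidy CSV
#'
#' Long format: `treatment_id`, `time`, `variable`, `value`.
#'
#' @param trajectory A `gp_trajectory` from [simulate_guts()].
#' @param path Output CSV path.
#' @export
write_trajectory <- function(trajectory, path) {
  tid <- attr(trajectory, "treatment_id") %||% NA_character_
  long <- tidyr::pivot_longer(tibble::as_tibble(trajectory), -"time",
                              names_to = "variable", values_to = "value")
  long <- dplyr::mutate(long, treatment_id = tid, .before = 1)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
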