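#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end analysis uses. Unknown
#' keys are rejected. Defaults reproduce the study-style conditions: the
#' six-category palette, exclusive segmentation for proportions, the dyadic
#' box ladder, a 100x100 rook row-standardized Moran lattice, an 8x8
#' normalized diversity grid, selection thresholds 5.0/5.0/1.2, Kaiser
#' retention, 8 clusters, participant-by-image factor observations.
#'
#' @param ... Overrides of the default keys, e.g.
#'   `pipeline_config(cluster_k = 6, seed = 42)`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    palette = default_palette(),
    segmentation_mode = "exclusive",
    precedence = default_precedence(),
    box_scales = default_box_scales(),
    moran_lattice = c(100L, 100L),
    weights_scheme = "rook",
    row_standardized = TRUE,
    diversity_grid = c(8L, 8L),
    diversity_normalized = TRUE,
    select_mean_min = 5.0,
    select_median_min = 5.0,
    select_sd_max = 1.2,
    retention = "kaiser",
    fixed_k = NULL,
    cluster_k = 8L,
    observation_mode = "participant_by_image",
    score_method = "regression",
    n_images = 42L,
    n_participants = 58L,
    n_raters = 23L,
    n_candidates = 150L,
    image_size = c(128L, 128L),
    image_layout = "blobs",
    write_masks = FALSE,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  stopifnot(inherits(cfg$palette, "color_palette"),
            cfg$segmentation_mode %in% c("exclusive", "non_exclusive"),
            cfg$weights_scheme %in% c("rook", "queen"),
            cfg$retention %in% c("kaiser", "fixed_k"),
            cfg$observation_mode %in% c("participant_by_image", "image_mean"),
            cfg$score_method %in% c("regression", "bartlett"),
            cfg$image_layout %in% c("blocks", "blobs", "fractal_per_color"),
            cfg$select_sd_max > 0, cfg$cluster_k >= 1 || identical(cfg$cluster_k, "auto"))
  class(cfg) <- "pipeline_config"
  cfg
}

metrics_config_from <- function(cfg) {
  metrics_config(box_scales = cfg$box_scales,
                 moran_lattice = cfg$moran_lattice,
                 weights_scheme = cfg$weights_scheme,
                 row_standardized = cfg$row_standardized,
                 diversity_grid = cfg$diversity_grid,
                 diversity_normalized = cfg$diversity_normalized)
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, input file
#' checksums, and per-stage row counts as JSON next to the outputs, so a
#' run can be audited and reproduced.
#'
#' @param out_dir Output directory.
#' @param config A `pipeline_config`.
#' @param inputs Character vector of input file paths (checksummed).
#' @param counts Named list/vector of per-stage row counts.
#' @param warnings Character vector of warnings gathered during the run.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(out_dir, config, inputs = character(),
                           counts = list(), warnings = character()) {
  cfg <- unclass(config)
  cfg$palette <- as.data.frame(unclass(cfg$palette))
  manifest <- list(
    package = "chromascape",
    version = as.character(utils::packageVersion("chromascape")),
    config = cfg,
    input_checksums = if (length(inputs)) {
      stats::setNames(as.list(tools::md5sum(inputs)), basename(inputs))
    } else list(),
    row_counts = counts,
    warnings = warnings
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a full synthetic study bundle on disk
#'
#' Writes `n_images` landscape PNGs, a long-format healing-rating CSV for
#' the candidate pool, and a long-format semantic-differential CSV with
#' planted factor structure, plus ground-truth tables and a manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the written paths.
#' @export
cmd_simulate <- function(out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)

  colors <- config$palette$name
  img_ids <- sprintf("img%03d", seq_len(config$n_images))
  image_paths <- character(0)
  with_local_seed(config$seed, {
    fracs <- lapply(seq_len(config$n_images), function(i) {
      raw <- stats::runif(length(colors), 0.2, 1)
      stats::setNames(0.85 * raw / sum(raw), colors)
    })
  })
  for (i in seq_len(config$n_images)) {
    scene <- gen_landscape_image(fracs[[i]], layout = config$image_layout,
                                 size = config$image_size,
                                 seed = config$seed + i)
    p <- file.path(out_dir, "images", paste0(img_ids[i], ".png"))
    write_image_png(scene$image, p)
    image_paths <- c(image_paths, p)
  }

  heal <- gen_healing_ratings(n_images = config$n_candidates,
                              n_raters = config$n_raters,
                              seed = config$seed + 10000L)
  heal_long <- do.call(rbind, lapply(names(heal$ratings), function(id) {
    data.frame(image_id = id, rater = seq_along(heal$ratings[[id]]),
               rating = heal$ratings[[id]], stringsAsFactors = FALSE)
  }))
  heal_path <- file.path(out_dir, "healing_ratings.csv")
  write_table(heal_long, heal_path)

  sd_sim <- gen_sd_ratings(n_participants = config$n_participants,
                           n_images = config$n_images,
                           seed = config$seed + 20000L)
  sd_long <- sd_ratings_to_long(sd_sim$ratings)
  sd_path <- file.path(out_dir, "sd_ratings.csv")
  write_table(sd_long, sd_path)

  truth_path <- file.path(out_dir, "planted_healing.csv")
  write_table(heal$planted, truth_path)

  write_manifest(out_dir, config,
                 inputs = character(),
                 counts = list(images = config$n_images,
                               healing_rows = nrow(heal_long),
                               sd_rows = nrow(sd_long)))
  invisible(list(images = image_paths, healing = heal_path, sd = sd_path,
                 planted = truth_path))
}

#' Convert a semantic-differential array to/from long format
#'
#' Long format has columns `participant`, `image_id`, `item`, `score` --
#' the on-disk CSV layout.
#'
#' @param sd_array Array `participants x items x images` with dimnames.
#' @return `sd_ratings_to_long`: a data frame; `sd_ratings_from_long`: an
#'   array.
#' @export
sd_ratings_to_long <- function(sd_array) {
  d <- dim(sd_array)
  dn <- dimnames(sd_array)
  data.frame(
    participant = rep(dn[[1L]], times = d[2L] * d[3L]),
    image_id = rep(dn[[3L]], each = d[1L] * d[2L]),
    item = rep(rep(dn[[2L]], each = d[1L]), times = d[3L]),
    score = as.integer(sd_array),
    stringsAsFactors = FALSE
  )
}

#' @param sd_long Data frame with columns `participant`, `image_id`,
#'   `item`, `score`.
#' @rdname sd_ratings_to_long
#' @export
sd_ratings_from_long <- function(sd_long) {
  stopifnot(all(c("participant", "image_id", "item", "score") %in% names(sd_long)))
  parts <- unique(sd_long$participant)
  items <- unique(sd_long$item)
  imgs <- unique(sd_long$image_id)
  arr <- array(NA_integer_, dim = c(length(parts), length(items), length(imgs)),
               dimnames = list(parts, items, imgs))
  arr[cbind(match(sd_long$participant, parts),
            match(sd_long$item, items),
            match(sd_long$image_id, imgs))] <- sd_long$score
  if (anyNA(arr)) stop("incomplete participant x item x image design in long data")
  arr
}

#' Segment a set of images and tabulate their color composition
#'
#' @param image_paths Character vector of image files.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for the composition CSV and (when
#'   `config$write_masks`) per-color mask PNGs.
#' @return Data frame: `image_id`, `unclassified_fraction`, and one
#'   proportion column per palette color.
#' @export
cmd_segment <- function(image_paths, config = pipeline_config(), out_dir = NULL) {
  stopifnot(length(image_paths) >= 1L)
  rows <- list()
  failed <- character(0)
  for (p in image_paths) {
    id <- tools::file_path_sans_ext(basename(p))
    seg <- tryCatch(
      segment_image(load_image(p), config$palette,
                    mode = config$segmentation_mode,
                    precedence = config$precedence),
      error = function(e) {
        message("skipping unreadable image ", p, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(seg)) {
      failed <- c(failed, p)
      next
    }
    if (!is.null(out_dir) && isTRUE(config$write_masks)) {
      mask_dir <- file.path(out_dir, "masks", id)
      dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(seg$masks)) {
        write_mask_png(seg$masks[[nm]], file.path(mask_dir, paste0(nm, ".png")))
      }
    }
    rows[[id]] <- data.frame(image_id = id,
                             unclassified_fraction = seg$unclassified_fraction,
                             as.list(seg$proportions),
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("all images failed to segment")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(out, file.path(out_dir, "composition.csv"))
  }
  out
}

#' Compute the color-metric table for a set of images
#'
#' @inheritParams cmd_segment
#' @return Tidy data frame, one row per (image, color): `image_id`,
#'   `color`, `D`, `r_squared`, `H_color`, `C`, `unclassified_fraction`.
#' @export
cmd_metrics <- function(image_paths, config = pipeline_config(), out_dir = NULL) {
  stopifnot(length(image_paths) >= 1L)
  mc <- metrics_config_from(config)
  rows <- lapply(image_paths, function(p) {
    id <- tools::file_path_sans_ext(basename(p))
    seg <- segment_image(load_image(p), config$palette,
                         mode = config$segmentation_mode,
                         precedence = config$precedence)
    suppressWarnings(compute_color_metrics(seg, mc, image_id = id))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(out, file.path(out_dir, "metrics.csv"))
  }
  out
}

#' Run the psychometric analysis and metric-factor integration
#'
#' Selects consensus samples from the healing ratings, factor-analyzes the
#' semantic-differential ratings (principal-axis extraction, varimax
#' rotation, loading screens), scores and clusters the images, and
#' correlates the color metrics with the factor scores. Writes the
#' selection list, loading table, cluster profile table, and correlation
#' table as CSVs when `out_dir` is given.
#'
#' @param metrics Tidy metrics table from [cmd_metrics()].
#' @param sd_long Long-format semantic-differential ratings.
#' @param healing_long Long-format healing ratings (`image_id`, `rating`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `selected`, `summaries`, `solution`, `screen`,
#'   `image_scores`, `clusters`, `correlations`.
#' @export
cmd_analyze <- function(metrics, sd_long, healing_long,
                        config = pipeline_config(), out_dir = NULL) {
  summaries <- summarize_healing_ratings(healing_long)
  selected <- select_samples(summaries,
                             mean_min = config$select_mean_min,
                             median_min = config$select_median_min,
                             sd_max = config$select_sd_max)

  sd_arr <- sd_ratings_from_long(sd_long)
  sd_images <- dimnames(sd_arr)[[3L]]
  metric_images <- unique(metrics$image_id)
  if (!setequal(sd_images, metric_images)) {
    stop("image ids differ between metrics and SD ratings; offending ids: ",
         paste(union(setdiff(sd_images, metric_images),
                     setdiff(metric_images, sd_images)), collapse = ", "))
  }

  corr <- item_correlation_matrix(sd_arr, config$observation_mode)
  sol <- principal_axis_factor(corr, retention = config$retention,
                               k = config$fixed_k)
  if (sol$k >= 2L) sol <- varimax_rotate(sol)
  screen <- if (sol$k >= 1L) screen_loadings(sol) else NULL

  obs <- sd_observations(sd_arr, config$observation_mode)
  scores <- factor_scores(obs, sol, method = config$score_method)
  image_scores <- image_factor_scores(scores, attr(obs, "image_ids"))

  clusters <- ward_cluster(image_scores, k = config$cluster_k)

  mw <- metrics_wide(metrics)
  correlations <- suppressWarnings(correlate_metrics_factors(mw, image_scores))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(data.frame(image_id = selected, stringsAsFactors = FALSE),
                file.path(out_dir, "selected_samples.csv"))
    write_table(summaries, file.path(out_dir, "healing_summaries.csv"))
    write_table(loading_table(sol), file.path(out_dir, "factor_loadings.csv"))
    profile_df <- data.frame(cluster = rownames(clusters$profile),
                             clusters$profile, check.names = FALSE,
                             stringsAsFactors = FALSE)
    write_table(profile_df, file.path(out_dir, "cluster_profiles.csv"))
    write_table(data.frame(image_id = names(clusters$assignments),
                           cluster = unname(clusters$assignments),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "cluster_assignments.csv"))
    write_table(as.data.frame(correlations),
                file.path(out_dir, "metric_factor_correlations.csv"))
    write_table(format_correlation_table(correlations),
                file.path(out_dir, "metric_factor_correlations_wide.csv"))
  }

  list(selected = selected, summaries = summaries, solution = sol,
       screen = screen, image_scores = image_scores, clusters = clusters,
       correlations = correlations)
}

#' Factor loading table in journal layout
#'
#' Items by factors, with a communality column and eigenvalue /
#' contribution-rate / cumulative-contribution footer rows.
#'
#' @param solution A `factor_solution`.
#' @param digits Decimal places. Default 3.
#' @return Data frame of formatted strings.
#' @export
loading_table <- function(solution, digits = 3L) {
  stopifnot(inherits(solution, "factor_solution"))
  if (solution$k < 1L) {
    return(data.frame(item = character(0)))
  }
  f <- function(x) formatC(x, digits = digits, format = "f")
  body <- data.frame(item = rownames(solution$loadings),
                     apply(solution$loadings, 2L, f),
                     communality = f(solution$communalities),
                     stringsAsFactors = FALSE, check.names = FALSE)
  footer <- data.frame(
    item = c("Eigenvalue", "Contribution Rate (%)", "Cumulative Contribution (%)"),
    rbind(f(solution$eigenvalues),
          f(solution$contribution_rate_pct),
          f(solution$cumulative_pct)),
    communality = c("", "", ""),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(footer) <- names(body)
  rbind(body, footer)
}

#' Run the full pipeline on a fresh synthetic bundle
#'
#' Simulate, segment, compute metrics, and analyze, writing every output
#' table under `out_dir`. Identical `config` (including seed) yields
#' byte-identical CSVs.
#'
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, the [cmd_analyze()] result list.
#' @export
run_all <- function(out_dir, config = pipeline_config()) {
  sim <- cmd_simulate(out_dir, config)
  cmd_segment(sim$images, config, out_dir = out_dir)
  metrics <- cmd_metrics(sim$images, config, out_dir = out_dir)
  sd_long <- utils::read.csv(sim$sd, stringsAsFactors = FALSE)
  healing_long <- utils::read.csv(sim$healing, stringsAsFactors = FALSE)
  res <- cmd_analyze(metrics, sd_long, healing_long, config, out_dir = out_dir)
  invisible(res)
}
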