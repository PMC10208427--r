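#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].  A config
#' is fully serializable to JSON; every run echoes its config verbatim into
#' the output directory, and one master seed deterministically derives all
#' stage seeds, so repeated runs are byte-identical.
#'
#' @param samples a named list of inputs: each element either a path to a
#'   label image (`list(path = ..., group = ...)`) or synthetic parameters
#'   (`list(synth = "cvtn"|"hex"|"random", n_seeds = , iterations = ,
#'   group = )`).
#' @param pixel_size micrometers per pixel (required).
#' @param gap_fraction_max montage QC threshold.
#' @param smooth_window,prominence border-metric parameters (um).
#' @param exclusion_depth contact-graph exclusion border (edges).
#' @param orbit_subset orbits for the GDD.
#' @param n_ref_cells reference-set size.
#' @param scale_params list passed to [build_cvtn_scale()] (`n_seeds`,
#'   `n_iter`, `stride`, `replicates`, `noise_amplitude`); NULL skips the
#'   CVTn scale stage.
#' @param rng_seed master seed.
#' @param out_dir output directory.
#' @return a validated `epi_run_config` list.
#' @export
run_config <- function(samples, pixel_size = NULL, gap_fraction_max = 0.08,
                       smooth_window = 1, prominence = 0.5,
                       exclusion_depth = 4, orbit_subset = 0:72,
                       n_ref_cells = 196, scale_params = NULL,
                       rng_seed = 1L, out_dir = tempfile("epitess_run_")) {
  missing_keys <- character(0)
  if (is.null(pixel_size)) missing_keys <- c(missing_keys, "pixel_size")
  if (missing(samples) || !length(samples)) missing_keys <- c(missing_keys, "samples")
  if (length(missing_keys))
    .stop_invalid("config schema error; missing required field(s): ",
                  paste(missing_keys, collapse = ", "))
  if (is.null(names(samples)) || any(names(samples) == ""))
    .stop_invalid("config schema error: every sample needs a name")
  structure(list(samples = samples, pixel_size = pixel_size,
                 gap_fraction_max = gap_fraction_max,
                 smooth_window = smooth_window, prominence = prominence,
                 exclusion_depth = exclusion_depth,
                 orbit_subset = orbit_subset, n_ref_cells = n_ref_cells,
                 scale_params = scale_params, rng_seed = rng_seed,
                 out_dir = out_dir), class = "epi_run_config")
}

#' @rdname run_config
#' @param path JSON file written by [write_run_config()].
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  j$samples <- lapply(j$samples, function(s) s)
  do.call(run_config, j)
}

#' @rdname run_config
#' @param cfg an `epi_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

pipeline_log <- function(con, ...) {
  msg <- sprintf("[%s] %s", "epitess", paste0(...))
  writeLines(msg, con)
  message(msg)
}

resolve_sample_image <- function(spec, cfg, name) {
  if (!is.null(spec$path)) return(read_label_image(spec$path, cfg$pixel_size))
  if (is.null(spec$synth)) .stop_invalid("sample ", name,
                                         ": needs $path or $synth")
  n <- if (!is.null(spec$n_seeds)) spec$n_seeds else 150
  it <- if (!is.null(spec$iterations)) spec$iterations else 30
  res <- if (!is.null(spec$resolution_px)) spec$resolution_px else 512
  sd <- derive_seed(cfg$rng_seed, paste0("sample-", name))
  dom <- epi_domain(mode = "bounded")
  tess <- switch(spec$synth,
    hex = hexagonal_lattice(max(4, 2 * round(sqrt(n) / 2)),
                            max(3, round(sqrt(n))), dom),
    random = voronoi_tessellate(generate_seeds(n, sd, dom)),
    cvtn = {
      p <- lloyd_path(generate_seeds(n, sd, dom), n_iter = it,
                      noise_amplitude = if (!is.null(spec$noise)) spec$noise else 0.15,
                      rng_seed = derive_seed(sd, "noise"),
                      record_stride = max(1L, it))
      p$diagrams[[length(p$diagrams)]]
    },
    .stop_invalid("unknown synth kind: ", spec$synth))
  if (!is.null(spec$wavy_amplitude) && spec$wavy_amplitude > 0) {
    w <- synthesize_wavy(tess, spec$wavy_amplitude,
                         if (!is.null(spec$wavy_peaks)) spec$wavy_peaks else 2,
                         rng_seed = derive_seed(sd, "wavy"),
                         resolution_px = res, pixel_size = cfg$pixel_size)
    w$label_image
  } else rasterize(tess, res, res, cfg$pixel_size)
}

#' Run the full analysis pipeline
#'
#' For every configured sample: read or synthesize the label image, extract
#' cells, apply montage QC, compute polygon/area statistics and border
#' interdigitation metrics, build the contact graph, and place the sample's
#' GDD triplet against the reference set (plus, optionally, the CVTn scale
#' with randomization significance).  With two or more groups a MANOVA over
#' the triplets is run.  Writes `cells.csv`, `polygon_distribution.csv`,
#' `borders.csv`, `gdd_triplets.csv`, `qc_report.json`, `manova.json` (when
#' applicable), `run.log` and a verbatim config echo into `cfg$out_dir`.
#'
#' @param cfg an [run_config()].
#' @param strict if TRUE, QC montage rejection raises an error (nonzero exit
#'   in scripted use); otherwise rejected samples are reported and skipped.
#' @return invisibly, a list with per-sample results and paths of the report
#'   files.
#' @export
run_pipeline <- function(cfg, strict = FALSE) {
  stopifnot(inherits(cfg, "epi_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con))
  ver <- as.character(packageVersion("epitess"))
  pipeline_log(con, "epitess ", ver, " pipeline start, master seed ",
               cfg$rng_seed)
  write_run_config(cfg, file.path(cfg$out_dir, "config.json"))

  refs <- build_reference_set(cfg$n_ref_cells,
                              derive_seed(cfg$rng_seed, "reference-set"))
  scale <- NULL
  if (!is.null(cfg$scale_params)) {
    pipeline_log(con, "building CVTn scale")
    scale <- do.call(build_cvtn_scale, c(list(refs = refs,
      rng_seed = derive_seed(cfg$rng_seed, "cvtn-scale"),
      orbit_subset = cfg$orbit_subset), cfg$scale_params))
  }

  all_cells <- list(); all_pd <- list(); all_borders <- list()
  triplets <- list(); qc_reports <- list()
  for (name in names(cfg$samples)) {
    pipeline_log(con, "sample ", name)
    spec <- cfg$samples[[name]]
    img <- resolve_sample_image(spec, cfg, name)
    cells <- extract_cells(img)
    qc <- qc_filter(cells, cfg$gap_fraction_max)
    qc_reports[[name]] <- qc$report
    if (!qc$report$montage_pass) {
      msg <- sprintf("sample %s rejected: gap fraction %.3f > %.3f", name,
                     qc$report$gap_fraction, qc$report$gap_fraction_max)
      if (strict) { pipeline_log(con, msg); stop(msg, call. = FALSE) }
      pipeline_log(con, msg, " (skipped)")
      next
    }
    cells <- qc$cells
    df <- cells$cells
    df$sample <- name
    all_cells[[name]] <- df
    pd <- polygon_distribution(cells)
    all_pd[[name]] <- data.frame(sample = name,
                                 n = as.integer(names(pd$freq)),
                                 freq = unname(pd$freq),
                                 balance_deviation = pd$balance_deviation)
    bdf <- analyze_borders(cells, cfg$smooth_window, cfg$prominence)
    if (nrow(bdf)) bdf$sample <- name
    all_borders[[name]] <- bdf
    g <- build_contact_graph(cells, cfg$exclusion_depth)
    tr <- tryCatch(gdd_triplet(g, refs, cfg$orbit_subset, sample_id = name,
                               group = if (!is.null(spec$group)) spec$group else name),
                   error = function(e) {
                     pipeline_log(con, "sample ", name, ": ", conditionMessage(e))
                     NULL
                   })
    if (!is.null(tr)) triplets[[name]] <- tr
  }

  trip_df <- do.call(rbind, lapply(triplets, function(tr)
    data.frame(sample = tr$sample_id, group = tr$group,
               d_hex = tr$triplet[1], d_random = tr$triplet[2],
               d_voronoi5 = tr$triplet[3])))
  if (!is.null(trip_df) && !is.null(scale)) {
    trip_df$closest_iteration <- vapply(triplets, function(tr)
      closest_cvtn(tr, scale), 0L)[trip_df$sample]
    trip_df$p_offpath <- vapply(trip_df$sample, function(nm) {
      randomization_significance(triplets[[nm]], scale,
        n_draws = 1000,
        rng_seed = derive_seed(cfg$rng_seed, paste0("rand-", nm)))$p
    }, 0)
  }

  man <- NULL
  if (!is.null(trip_df) && length(unique(trip_df$group)) >= 2 &&
      all(table(trip_df$group) >= 4)) {
    man <- manova_groups(trip_df)
    jsonlite::write_json(unclass(man), file.path(cfg$out_dir, "manova.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  write_report_csv <- function(df, fname) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    path <- file.path(cfg$out_dir, fname)
    con2 <- file(path, open = "wt")
    writeLines(sprintf("# epitess %s", ver), con2)
    write.csv(df, con2, row.names = FALSE)
    close(con2)
  }
  write_report_csv(do.call(rbind, all_cells), "cells.csv")
  write_report_csv(do.call(rbind, all_pd), "polygon_distribution.csv")
  write_report_csv(do.call(rbind, all_borders), "borders.csv")
  write_report_csv(trip_df, "gdd_triplets.csv")
  jsonlite::write_json(lapply(qc_reports, unclass),
                       file.path(cfg$out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  pipeline_log(con, "pipeline done")
  invisible(list(cells = all_cells, polygon_distributions = all_pd,
                 borders = all_borders, triplets = triplets,
                 gdd_table = trip_df, manova = man, qc = qc_reports,
                 refs = refs, scale = scale, out_dir = cfg$out_dir))
}
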