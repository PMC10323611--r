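#' Integer percentage with round-half-up
#'
#' `100 * k / n` rounded half-up to an integer percent, matching how counts
#' are reported in summary tables (e.g. 30 of 45 -> 67%).
#'
#' @param k Successes (0 <= k <= n).
#' @param n Total (> 0).
#' @return Integer percentage.
#' @examples
#' proportion_summary(30, 45)  # 67
#' proportion_summary(16, 45)  # 36
#' @export
proportion_summary <- function(k, n) {
  stopifnot(length(k) == length(n))
  if (any(n <= 0)) stop("n must be > 0")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  as.integer(floor(100 * k / n + 0.5))
}

#' Dataset-level nerve size summary
#'
#' Given per-class mean nerve cross-sectional areas and image counts,
#' computes the count-weighted mean nerve area, expresses it in pixels, and
#' relates it to the imaging system's resolution area. Both outputs are
#' rounded half-up to integers, as printed in dataset summaries.
#'
#' @param areas_mm2 Per-class mean nerve areas (mm^2).
#' @param counts Per-class image counts.
#' @param pixel_area_mm2 Area of one pixel (default 0.01 mm^2, i.e. 100 um
#'   pitch).
#' @param resolution_area_mm2 Effective resolution area (default 0.04 mm^2).
#' @return List with `mean_area_mm2`, `mean_pixels_per_nerve`,
#'   `nerve_to_resolution_ratio`, `n_images`.
#' @examples
#' dataset_summary(c(6.5, 9.6, 5.7), c(45, 47, 43))
#' @export
dataset_summary <- function(areas_mm2, counts, pixel_area_mm2 = 0.01,
                            resolution_area_mm2 = 0.04) {
  stopifnot(length(areas_mm2) == length(counts),
            all(areas_mm2 > 0), all(counts > 0),
            pixel_area_mm2 > 0, resolution_area_mm2 > 0)
  rhu <- function(x) as.integer(floor(x + 0.5))
  mean_area <- sum(areas_mm2 * counts) / sum(counts)
  list(
    mean_area_mm2 = mean_area,
    mean_pixels_per_nerve = rhu(mean_area / pixel_area_mm2),
    nerve_to_resolution_ratio = rhu(mean_area / resolution_area_mm2),
    n_images = as.integer(sum(counts))
  )
}

#' Pipeline configuration
#'
#' Assembles the configuration of a full analysis run. Every source of
#' randomness has an explicit seed so that a fixed configuration always
#' reproduces the same report.
#'
#' @param simulate Logical: render a synthetic phantom (`TRUE`) or read a
#'   stack from `stack_path` (`FALSE`).
#' @param stack_path,nerve_mask_path,analysis_mask_path Input paths used
#'   when `simulate = FALSE` (stack written by [write_stack()], masks by
#'   [write_mask()]).
#' @param layout Phantom geometry for simulate mode (a [phantom_layout()]).
#' @param noise_sd Phantom noise level (simulate mode).
#' @param seed_simulate,seed_vca,seed_reference Stage seeds.
#' @param nmf An [nmf_params()] object.
#' @param pairing,min_count Options of [pearson_matrix()].
#' @param top_n_leaves Leaves analysed by [per_leaf_pcc()].
#' @param entropy_base Logarithm base for [fingerprint_entropy()].
#' @param log_level One of "debug", "info", "warn".
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = TRUE, stack_path = NULL,
                            nerve_mask_path = NULL, analysis_mask_path = NULL,
                            layout = phantom_layout(),
                            noise_sd = 0.5, seed_simulate = 1L,
                            seed_vca = 1L, seed_reference = 1L,
                            nmf = nmf_params(), pairing = "both_present",
                            min_count = 10, top_n_leaves = 6,
                            entropy_base = exp(1), log_level = "info") {
  if (!simulate && is.null(stack_path)) {
    stop("configuration error: simulate is disabled and no stack_path is given")
  }
  structure(
    list(simulate = simulate, stack_path = stack_path,
         nerve_mask_path = nerve_mask_path,
         analysis_mask_path = analysis_mask_path, layout = layout,
         noise_sd = noise_sd,
         seed_simulate = as.integer(seed_simulate),
         seed_vca = as.integer(seed_vca),
         seed_reference = as.integer(seed_reference),
         nmf = nmf, pairing = pairing, min_count = min_count,
         top_n_leaves = top_n_leaves, entropy_base = entropy_base,
         log_level = log_level),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path (`.yaml`/`.yml` or `.json`). Fields mirror the
#'   arguments of [pipeline_config()]; `nmf` may be a nested mapping of
#'   [nmf_params()] arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$nmf)) raw$nmf <- do.call(nmf_params, raw$nmf)
  do.call(pipeline_config, raw)
}

plog <- function(config, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[config$log_level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

#' Run the full spectral-analysis pipeline
#'
#' Executes simulate (or load) -> unmix (NMF + NNLS and VCA comparators) ->
#' coefficient model -> co-occurrence statistics (nerve vs reference) ->
#' mixture clustering and fingerprints -> report. All intermediate
#' artifacts are persisted under `out_dir` (component spectra CSV,
#' coefficient maps TIFF, metric matrices CSV, Newick tree, fingerprints
#' CSV, run report JSON). The run is a pure function of the configuration:
#' re-running with the same config reproduces the same report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The run report (named list), invisibly; also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("msotmix_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "configure"
  report <- list()
  tryCatch({
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(
      unclass(config), cfg_path,
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
    )
    config_hash <- unname(tools::md5sum(cfg_path))

    stage <- "simulate"
    if (config$simulate) {
      plog(config, "info", "rendering synthetic phantom (seed %d, noise sd %g)",
           config$seed_simulate, config$noise_sd)
      scene <- render_phantom(layout = config$layout,
                              noise_sd = config$noise_sd,
                              seed = config$seed_simulate)
      write_stack(scene, file.path(out_dir, "stack.tif"))
      write_mask(scene$nerve_mask, file.path(out_dir, "nerve_mask.tif"))
      stack <- scene$stack
      nerve_mask <- scene$nerve_mask
      analysis_mask <- scene$analysis_mask
      true_library <- scene$endmembers
      wavelengths <- scene$wavelengths
    } else {
      plog(config, "info", "reading stack from %s", config$stack_path)
      inp <- read_stack(config$stack_path)
      stack <- inp$stack
      wavelengths <- inp$wavelengths
      nerve_mask <- if (!is.null(config$nerve_mask_path)) {
        read_mask(config$nerve_mask_path)
      } else {
        stop("configuration error: nerve_mask_path is required when simulate is disabled")
      }
      analysis_mask <- if (!is.null(config$analysis_mask_path)) {
        read_mask(config$analysis_mask_path)
      } else {
        matrix(TRUE, dim(stack)[1], dim(stack)[2])
      }
      scene <- NULL
      true_library <- NULL
    }
    S <- spectra_matrix(stack, mask = analysis_mask, wavelengths = wavelengths)
    backmap <- attr(S, "backmap")

    stage <- "unmix"
    plog(config, "info", "NMF unmixing %d spectra (K = %d)", nrow(S), config$nmf$k)
    fit <- nmf_unmix(S, config$nmf)
    utils::write.csv(
      data.frame(component = rownames(fit$H), fit$H, check.names = FALSE),
      file.path(out_dir, "components.csv"), row.names = FALSE
    )
    write_coefficient_maps(fit$W, backmap, dim(stack)[1:2],
                           file.path(out_dir, "coefficients.tif"))
    rel <- list(nmf = fit$relative_error)
    if (!is.null(true_library)) {
      plog(config, "info", "comparators: NNLS (true library) and VCA")
      W_nnls <- nnls_unmix(S, true_library)
      rel$nnls <- relative_error(S, W_nnls, true_library)
      vca <- vca_endmembers(S, config$nmf$k, seed = config$seed_vca)
      rel$vca <- relative_error(S, vca$W, vca$H)
    }

    stage <- "model"
    presence <- binarize_presence(fit$W, config$nmf$eps_zero)
    std <- standardize_coefficients(fit$W, presence)

    stage <- "stats"
    nerve_rows <- which(nerve_mask[backmap])
    ref_rows <- NULL
    if (length(nerve_rows) >= 1) {
      cent <- colMeans(backmap[nerve_rows, , drop = FALSE])
      spread <- apply(backmap[nerve_rows, , drop = FALSE], 2, stats::sd)
      loc <- list(mu_lat = cent[["col"]], mu_ax = cent[["row"]],
                  sd_lat = max(spread[["col"]], 1), sd_ax = max(spread[["row"]], 1))
      refs <- sample_reference_pixels(loc, n = length(nerve_rows),
                                      nerve_mask = nerve_mask,
                                      analysis_mask = analysis_mask,
                                      seed = config$seed_reference)
      utils::write.csv(as.data.frame(refs$coords),
                       file.path(out_dir, "reference_pixels.csv"),
                       row.names = FALSE)
      key <- backmap[, 1] + dim(stack)[1] * (backmap[, 2] - 1)
      ref_rows <- match(refs$coords[, 1] + dim(stack)[1] * (refs$coords[, 2] - 1), key)
      ref_rows <- ref_rows[!is.na(ref_rows)]
    }
    subset_metrics <- function(rows) {
      pr <- list(m = presence$m[rows, , drop = FALSE],
                 p = colMeans(presence$m[rows, , drop = FALSE]),
                 eps_zero = presence$eps_zero)
      class(pr) <- "presence_matrix"
      list(
        dice = dice_matrix(pr),
        pcc = pearson_matrix(std$std[rows, , drop = FALSE], pr,
                             pairing = config$pairing,
                             min_count = config$min_count)
      )
    }
    met_nerve <- subset_metrics(nerve_rows)
    write_matrix_csv <- function(M, name) {
      utils::write.csv(as.data.frame(M), file.path(out_dir, name))
    }
    write_matrix_csv(met_nerve$dice, "dice_nerve.csv")
    write_matrix_csv(met_nerve$pcc, "pcc_nerve.csv")
    if (!is.null(ref_rows) && length(ref_rows) >= 1) {
      met_ref <- subset_metrics(ref_rows)
      write_matrix_csv(met_ref$dice, "dice_reference.csv")
      write_matrix_csv(met_ref$pcc, "pcc_reference.csv")
      write_matrix_csv(contrast_difference(met_nerve$dice, met_ref$dice),
                       "dice_difference.csv")
      write_matrix_csv(contrast_difference(met_nerve$pcc, met_ref$pcc),
                       "pcc_difference.csv")
    }

    stage <- "cluster"
    classes <- enumerate_classes(presence, S)
    tree <- ward_tree(classes)
    if (nrow(classes$classes) > 1) {
      tree_newick(tree, file.path(out_dir, "tree.nwk"))
    }
    fp_rows <- unique(c(nerve_rows, ref_rows))
    fp <- fingerprint(fp_rows, classes, tree, label = "nerve+reference")
    utils::write.csv(
      data.frame(pattern = names(fp), proportion = as.numeric(fp)),
      file.path(out_dir, "fingerprint_nerve_reference.csv"), row.names = FALSE
    )
    entropy <- fingerprint_entropy(fp, base = config$entropy_base)

    stage <- "report"
    report <- list(
      config_hash = config_hash,
      package_version = as.character(utils::packageVersion("msotmix")),
      n_spectra = nrow(S),
      n_wavelengths = ncol(S),
      relative_error_pct = lapply(rel, function(x) 100 * x),
      objective_final = fit$objective[length(fit$objective)],
      objective_monotone = all(diff(fit$objective) <= 1e-8 * abs(fit$objective[1])),
      n_mixture_classes = nrow(classes$classes),
      null_class_pixels = classes$null_count,
      fingerprint_entropy = entropy,
      entropy_base = config$entropy_base,
      seeds = list(simulate = config$seed_simulate, vca = config$seed_vca,
                   reference = config$seed_reference)
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    plog(config, "info", "report written to %s", file.path(out_dir, "report.json"))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(report)
}
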