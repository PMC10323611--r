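#' Location statistics of nerve centroids
#'
#' Reference (surrounding-tissue) spectra are drawn from a bivariate normal
#' law `N((mu_lat, mu_ax), diag(sd_lat^2, sd_ax^2))` fitted to the centroid
#' positions of a nerve class across images, so that the reference samples
#' share the depth regime and anatomical environment of the nerve. Each
#' nerve class is fitted independently.
#'
#' @param centroids Two-column matrix or data.frame of (lateral, axial)
#'   centroid coordinates in pixels, one row per image.
#' @param class Optional factor/character vector grouping the rows by nerve
#'   class; statistics are computed per class.
#' @return data.frame with columns `class`, `n`, `mu_lat`, `mu_ax`,
#'   `sd_lat`, `sd_ax` (population standard deviations).
#' @examples
#' estimate_location_stats(cbind(c(1, 3, 5), c(2, 4, 6)))
#' @export
estimate_location_stats <- function(centroids, class = NULL) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1) stop("need at least one centroid")
  stopifnot(ncol(centroids) == 2)
  if (is.null(class)) class <- rep("all", nrow(centroids))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- lapply(split(seq_len(nrow(centroids)), class), function(idx) {
    data.frame(
      n = length(idx),
      mu_lat = mean(centroids[idx, 1]), mu_ax = mean(centroids[idx, 2]),
      sd_lat = pop_sd(centroids[idx, 1]), sd_ax = pop_sd(centroids[idx, 2])
    )
  })
  cbind(data.frame(class = names(out)), do.call(rbind, out), row.names = NULL)
}

#' Sample reference pixel locations
#'
#' Draws pixel coordinates from the bivariate normal location law of a nerve
#' class, rounds them to the nearest pixel, and rejects (and redraws) any
#' draw that falls outside the image or analysis mask or inside the nerve
#' mask, so reference samples always represent the nerve's surroundings.
#' Sampling is a pure function of `(stats, masks, n, seed)`.
#'
#' @param stats One row of [estimate_location_stats()] output (or any list
#'   with `mu_lat`, `mu_ax`, `sd_lat`, `sd_ax`).
#' @param n Number of accepted samples required (a sensible default is the
#'   nerve ROI's pixel count, giving balanced nerve/reference sets).
#' @param nerve_mask,analysis_mask Logical matrices of common shape; samples
#'   must lie inside `analysis_mask` and outside `nerve_mask`.
#' @param seed Integer RNG seed.
#' @param max_draw_factor Abort with an error after `max_draw_factor * n`
#'   total draws (default 1000).
#' @return List of class `"reference_samples"` with `coords` (n x 2 matrix
#'   of row/col pixel indices), `rejected` (number of rejected draws),
#'   `stats`, `seed`, `n`.
#' @export
sample_reference_pixels <- function(stats, n, nerve_mask, analysis_mask,
                                    seed = 1L, max_draw_factor = 1000) {
  stopifnot(n >= 1, identical(dim(nerve_mask), dim(analysis_mask)))
  ok_mask <- analysis_mask & !nerve_mask
  if (!any(ok_mask)) stop("acceptance region is empty: analysis mask minus nerve mask has no pixels")
  nr <- nrow(ok_mask); nc <- ncol(ok_mask)
  coords <- matrix(NA_integer_, 0, 2)
  rejected <- 0L
  drawn <- 0L
  cap <- max_draw_factor * n
  with_seed(seed, {
    while (nrow(coords) < n) {
      m <- min(max(2L * (n - nrow(coords)), 32L), cap - drawn)
      if (m <= 0) {
        stop(sprintf(
          "rejection cap exceeded (%d draws) before %d samples were accepted; acceptance region too small for the location law",
          cap, n
        ))
      }
      lat <- round(stats::rnorm(m, stats$mu_lat, stats$sd_lat))
      ax <- round(stats::rnorm(m, stats$mu_ax, stats$sd_ax))
      drawn <- drawn + m
      ok <- ax >= 1 & ax <= nr & lat >= 1 & lat <= nc
      ok[ok] <- ok_mask[cbind(ax[ok], lat[ok])]
      rejected <- rejected + sum(!ok)
      coords <- rbind(coords, cbind(ax[ok], lat[ok]))
    }
  })
  coords <- coords[seq_len(n), , drop = FALSE]
  colnames(coords) <- c("row", "col")
  structure(list(coords = coords, rejected = rejected, stats = stats,
                 seed = seed, n = n),
            class = "reference_samples")
}
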