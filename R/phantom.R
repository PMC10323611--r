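# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Layered tissue-phantom layout
#'
#' Describes the geometry of a synthetic cross-sectional arm phantom:
#' horizontal tissue layers (epidermis, dermis, subcutaneous fat, muscle)
#' stacked from the skin surface downward, plus embedded structures (a nerve
#' ellipse with fascicle sub-disks and blood-vessel disks). Row 0 is the skin
#' surface, rows run with axial depth and columns laterally; pixel centres
#' are at (index + 0.5) * `pixel_mm`.
#'
#' Tissue recipes are non-negative mixture weights over the chromophores of
#' [endmember_library()]; a vessel's recipe is derived from its oxygenation
#' fraction (oxy- vs deoxyhemoglobin split of a fixed blood weight).
#'
#' @param nrow,ncol Image size in pixels (axial x lateral).
#' @param pixel_mm Pixel pitch in mm (default 0.1, i.e. 100 um resolution).
#' @param layer_depths_mm Named numeric vector of the lower boundary (mm) of
#'   the epidermis, dermis and fat layers; everything below is muscle.
#' @param nerve List with `center_mm` (lateral, axial), `radii_mm`
#'   (lateral, axial) and `fascicles` (data.frame lateral_mm, axial_mm,
#'   radius_mm, relative to image origin).
#' @param vessels data.frame with columns `lateral_mm`, `axial_mm`,
#'   `radius_mm`, `so2` (oxygenation fraction in \[0,1\]).
#' @param recipes Named list of named non-negative weight vectors over
#'   chromophore names, one per tissue label.
#' @return A list of class `"phantom_layout"`.
#' @export
phantom_layout <- function(nrow = 200, ncol = 200, pixel_mm = 0.1,
                           layer_depths_mm = c(epidermis = 0.2, dermis = 1.5,
                                               fat = 4.5),
                           nerve = list(
                             center_mm = c(lateral = 10, axial = 7),
                             radii_mm = c(lateral = 2.5, axial = 1.5),
                             fascicles = data.frame(
                               lateral_mm = c(9.0, 10.4, 11.2, 9.6, 10.8),
                               axial_mm   = c(6.6, 6.4, 7.2, 7.5, 7.8),
                               radius_mm  = rep(0.35, 5)
                             )
                           ),
                           vessels = data.frame(
                             lateral_mm = c(14.5, 6.2, 4.0, 16.5),
                             axial_mm   = c(6.8, 7.4, 1.0, 1.1),
                             radius_mm  = c(0.55, 0.45, 0.30, 0.25),
                             so2        = c(0.95, 0.60, 0.90, 0.65)
                           ),
                           recipes = NULL) {
  stopifnot(nrow >= 1, ncol >= 1, pixel_mm > 0)
  stopifnot(all(diff(layer_depths_mm) > 0))
  if (is.null(recipes)) {
    recipes <- list(
      epidermis = c(melanin = 1.2, water = 0.5),
      dermis    = c(collagen = 0.9, water = 0.5, oxyhemoglobin = 0.25,
                    deoxyhemoglobin = 0.10),
      fat       = c(lipid = 1.5, water = 0.2),
      muscle    = c(oxyhemoglobin = 0.8, deoxyhemoglobin = 0.3, water = 0.5,
                    collagen = 0.2),
      nerve     = c(lipid = 0.5, water = 0.4, collagen = 0.5,
                    oxyhemoglobin = 0.3, deoxyhemoglobin = 0.1),
      fascicle  = c(lipid = 0.9, collagen = 0.3, water = 0.3)
    )
  }
  if (any(unlist(recipes) < 0)) stop("mixture weights must be >= 0")
  # structures must lie inside the image
  fov_lat <- ncol * pixel_mm
  fov_ax <- nrow * pixel_mm
  inside <- function(lat, ax, r_lat, r_ax = r_lat) {
    all(lat - r_lat >= 0, lat + r_lat <= fov_lat,
        ax - r_ax >= 0, ax + r_ax <= fov_ax)
  }
  if (!inside(nerve$center_mm[["lateral"]], nerve$center_mm[["axial"]],
              nerve$radii_mm[["lateral"]], nerve$radii_mm[["axial"]])) {
    stop("nerve ellipse does not lie inside the image")
  }
  if (nrow(vessels) > 0 &&
      !all(mapply(inside, vessels$lateral_mm, vessels$axial_mm,
                  vessels$radius_mm))) {
    stop("a vessel disk does not lie inside the image")
  }
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         pixel_mm = pixel_mm, layer_depths_mm = layer_depths_mm,
         nerve = nerve, vessels = vessels, recipes = recipes),
    class = "phantom_layout"
  )
}

#' Depth-dependent fluence (spectral coloring) model
#'
#' One-dimensional Beer-Lambert attenuation of the excitation light with a
#' per-wavelength effective attenuation coefficient. The default coefficient
#' has a bump across the lipid absorption band (900-940 nm) and towards the
#' water peak, so that structures below the subcutaneous fat show the
#' characteristic dip of their spectra in the lipid-peak region, plus a
#' mildly decreasing blood/melanin background. The transmitted fraction at
#' depth d is `exp(-mu(lambda) * max(0, d - reference_depth_mm))`, which is
#' 1 at the reference depth and non-increasing with depth at every
#' wavelength.
#'
#' @param grid Wavelength grid in nm.
#' @param mu Optional per-wavelength effective attenuation coefficient
#'   (1/mm, >= 0); defaults to the closed form above.
#' @param reference_depth_mm Depth at which the transmitted fraction is 1.
#' @return A list of class `"fluence_model"` with fields `wavelengths`,
#'   `mu`, `reference_depth_mm`.
#' @export
fluence_model <- function(grid = wavelength_grid(), mu = NULL,
                          reference_depth_mm = 0) {
  assert_grid(grid)
  w <- as.numeric(grid)
  if (is.null(mu)) {
    mu <- 0.04 +
      0.05 * exp(-(w - 700) / 150) +
      0.13 * exp(-(w - 925)^2 / (2 * 30^2)) +
      0.08 * exp(-(w - 975)^2 / (2 * 45^2))
  }
  stopifnot(length(mu) == length(w), all(mu >= 0))
  structure(list(wavelengths = w, mu = as.numeric(mu),
                 reference_depth_mm = reference_depth_mm),
            class = "fluence_model")
}

#' Transmitted light fraction at depth
#'
#' @param fluence A [fluence_model()].
#' @param depth_mm Vector of depths in mm.
#' @return Matrix `length(depth_mm)` x `length(wavelengths)` of transmitted
#'   fractions in (0, 1].
#' @export
transmitted_fraction <- function(fluence, depth_mm) {
  stopifnot(inherits(fluence, "fluence_model"))
  d <- pmax(0, depth_mm - fluence$reference_depth_mm)
  exp(-outer(d, fluence$mu))
}

#' Render a multispectral tissue phantom
#'
#' Builds a synthetic multispectral optoacoustic scene with known ground
#' truth. Per pixel, the clean spectrum is the transmitted light fraction at
#' the pixel's depth times the recipe mixture of chromophore absorption
#' spectra; additive Gaussian noise clipped at zero keeps the stack
#' non-negative. The same `(layout, library, fluence, noise_sd, seed)`
#' always renders a bit-identical scene.
#'
#' @param layout A [phantom_layout()].
#' @param library Endmember matrix from [endmember_library()].
#' @param fluence A [fluence_model()] on the same grid.
#' @param noise_sd Standard deviation of the additive noise (same arbitrary
#'   units as the spectra); >= 0.
#' @param seed Integer RNG seed for the noise.
#' @return A list of class `"msot_scene"` with fields:
#'   `stack` (nrow x ncol x L array of spectra), `wavelengths`, `pixel_mm`,
#'   `endmembers` (the library), `abundances` (nrow x ncol x K true weights),
#'   `labels` (tissue label matrix), `nerve_mask`, `analysis_mask` (logical
#'   matrices), `fluence`, `noise_sd`, `seed`.
#' @export
render_phantom <- function(layout = phantom_layout(),
                           library = endmember_library(),
                           fluence = fluence_model(),
                           noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(layout, "phantom_layout"), noise_sd >= 0)
  w <- attr(library, "wavelengths")
  stopifnot(identical(as.numeric(w), fluence$wavelengths))
  chroms <- rownames(library)
  known <- unique(unlist(lapply(layout$recipes, names)))
  bad <- setdiff(known, chroms)
  if (length(bad)) {
    stop("recipe references unknown chromophore(s): ", paste(bad, collapse = ", "))
  }

  nr <- layout$nrow; nc <- layout$ncol
  px <- layout$pixel_mm
  depth <- (seq_len(nr) - 0.5) * px   # axial depth of each pixel row, mm
  lat <- (seq_len(nc) - 0.5) * px

  # label map: layers first, then structures drawn on top
  lb <- layout$layer_depths_mm
  labels <- matrix("muscle", nr, nc)
  labels[depth <= lb[["fat"]], ] <- "fat"
  labels[depth <= lb[["dermis"]], ] <- "dermis"
  labels[depth <= lb[["epidermis"]], ] <- "epidermis"

  DD <- matrix(depth, nr, nc)
  LL <- matrix(lat, nr, nc, byrow = TRUE)

  nv <- layout$nerve
  nerve_mask <- ((LL - nv$center_mm[["lateral"]]) / nv$radii_mm[["lateral"]])^2 +
    ((DD - nv$center_mm[["axial"]]) / nv$radii_mm[["axial"]])^2 <= 1
  labels[nerve_mask] <- "nerve"
  fs <- nv$fascicles
  if (!is.null(fs) && nrow(fs) > 0) {
    for (i in seq_len(nrow(fs))) {
      disk <- (LL - fs$lateral_mm[i])^2 + (DD - fs$axial_mm[i])^2 <=
        fs$radius_mm[i]^2
      labels[disk & nerve_mask] <- "fascicle"
    }
  }
  recipes <- layout$recipes
  vs <- layout$vessels
  if (!is.null(vs) && nrow(vs) > 0) {
    for (i in seq_len(nrow(vs))) {
      so2 <- vs$so2[i]
      stopifnot(so2 >= 0, so2 <= 1)
      lab <- sprintf("vessel_%d", i)
      recipes[[lab]] <- c(oxyhemoglobin = 2.5 * so2,
                          deoxyhemoglobin = 2.5 * (1 - so2),
                          water = 0.3)
      disk <- (LL - vs$lateral_mm[i])^2 + (DD - vs$axial_mm[i])^2 <=
        vs$radius_mm[i]^2
      labels[disk] <- lab
    }
  }

  # ground-truth abundances per pixel (chromophore weights)
  K <- length(chroms); L <- length(w)
  A <- array(0, dim = c(nr, nc, K), dimnames = list(NULL, NULL, chroms))
  for (lab in unique(as.vector(labels))) {
    rec <- recipes[[lab]]
    sel <- labels == lab
    for (ch in names(rec)) A[, , ch][sel] <- rec[[ch]]
  }

  # clean spectra: transmitted fraction (per row, wavelength) x mixture
  Tf <- transmitted_fraction(fluence, depth)          # nr x L
  Amat <- matrix(A, nrow = nr * nc, ncol = K)         # pixel-major (col-major rows)
  clean <- Amat %*% library                           # (nr*nc) x L
  rowidx <- rep.int(seq_len(nr), nc)
  clean <- clean * Tf[rowidx, , drop = FALSE]

  S <- with_seed(seed, {
    if (noise_sd > 0) {
      pmax(0, clean + matrix(stats::rnorm(length(clean), sd = noise_sd),
                             nrow(clean), ncol(clean)))
    } else {
      clean
    }
  })
  stack <- array(S, dim = c(nr, nc, L), dimnames = list(NULL, NULL, w))

  structure(
    list(stack = stack, wavelengths = as.numeric(w), pixel_mm = px,
         endmembers = library, abundances = A, labels = labels,
         nerve_mask = nerve_mask,
         analysis_mask = matrix(TRUE, nr, nc),
         fluence = fluence, noise_sd = noise_sd, seed = seed),
    class = "msot_scene"
  )
}

#' @export
print.msot_scene <- function(x, ...) {
  cat(sprintf(
    "msot scene: %d x %d px (%.2g mm), %d wavelengths, noise sd %g, seed %s\n",
    dim(x$stack)[1], dim(x$stack)[2], x$pixel_mm, dim(x$stack)[3],
    x$noise_sd, format(x$seed)
  ))
  invisible(x)
}

#' Extract the pixel-spectra matrix from a scene or stack
#'
#' Arranges the masked pixel spectra as a non-negative N x L matrix (one row
#' per pixel, one column per wavelength), the input format of the unmixing
#' routines. A back-map from matrix row to image (row, col) is kept as an
#' attribute so coefficient maps can be folded back into image geometry.
#'
#' @param x An `"msot_scene"` or a 3D array (rows x cols x wavelengths).
#' @param mask Logical matrix selecting pixels; defaults to the scene's
#'   analysis mask (or all pixels for a bare array).
#' @param wavelengths Wavelengths for a bare array input.
#' @return Numeric matrix with attributes `wavelengths` and `backmap`
#'   (two-column matrix of image row/col per matrix row).
#' @export
spectra_matrix <- function(x, mask = NULL, wavelengths = NULL) {
  if (inherits(x, "msot_scene")) {
    stack <- x$stack
    if (is.null(mask)) mask <- x$analysis_mask
    wavelengths <- x$wavelengths
  } else {
    stack <- x
    stopifnot(length(dim(stack)) == 3)
    if (is.null(mask)) mask <- matrix(TRUE, dim(stack)[1], dim(stack)[2])
    if (is.null(wavelengths)) wavelengths <- seq_len(dim(stack)[3])
  }
  stopifnot(identical(dim(mask), dim(stack)[1:2]))
  idx <- which(mask)
  L <- dim(stack)[3]
  S <- matrix(stack, ncol = L)[idx, , drop = FALSE]
  colnames(S) <- wavelengths
  attr(S, "wavelengths") <- as.numeric(wavelengths)
  attr(S, "backmap") <- cbind(row = ((idx - 1) %% dim(stack)[1]) + 1,
                              col = ((idx - 1) %/% dim(stack)[1]) + 1)
  S
}
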