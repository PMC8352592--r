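#' Specification of a banded-nucleus image phantom
#'
#' Geometry and optics for a synthetic confocal z-stack emulating a
#' histone-fluorescence image of a polytene nucleus: an ellipsoidal nucleus
#' containing a cylinder-like "chromosome" of stacked bands of white, gray
#' and black chromatin, and one spherical nucleolar void.  Class intensities
#' increase with condensation (histone density); the imaging model is a
#' Gaussian in-plane PSF followed by Poisson shot noise and Gaussian read
#' noise.
#'
#' @param shape Voxel dimensions `c(z, y, x)`.
#' @param voxel_size Micrometres per voxel per axis `c(z, y, x)`.
#' @param class_fractions Target volume fractions of the chromatin classes,
#'   named `white`, `gray`, `black`; must sum to 1.
#' @param class_intensity Mean 8-bit intensity per region, named
#'   `background`, `nucleolus`, `white`, `gray`, `black`; chromatin classes
#'   must be ordered `background < white < gray < black` and all values must
#'   lie in \[0, 255\].  Defaults put each chromatin class at the centre of
#'   the corresponding intensity bin of [class_scheme()].
#' @param psf_sigma Gaussian PSF sigma in voxels (in-plane); 0 disables blur.
#' @param photon_gain Photons per intensity unit for Poisson shot noise;
#'   0 disables shot noise.
#' @param read_sd Gaussian read-noise SD in intensity units; 0 disables.
#' @param n_bands Number of chromatin bands stacked along the chromosome.
#' @param seed Integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(z = 9, y = 96, x = 96),
                         voxel_size = c(z = 0.5, y = 0.1, x = 0.1),
                         class_fractions = c(white = 0.52, gray = 0.43,
                                             black = 0.05),
                         class_intensity = c(background = 30, nucleolus = 40,
                                             white = 116, gray = 186,
                                             black = 245),
                         psf_sigma = 1, photon_gain = 1, read_sd = 2,
                         n_bands = 12, seed = 1L) {
  check_that(length(shape) == 3 && all(shape >= 1), "shape",
             "must be three positive extents (z, y, x)")
  check_that(length(voxel_size) == 3 && all(voxel_size > 0), "voxel_size",
             "must be three positive sizes")
  check_that(length(class_fractions) == 3 &&
               setequal(names(class_fractions), c("white", "gray", "black")),
             "class_fractions", "must be named white/gray/black")
  check_that(all(class_fractions >= 0) &&
               abs(sum(class_fractions) - 1) < 1e-9,
             "class_fractions", "must be >= 0 and sum to 1")
  check_that(setequal(names(class_intensity),
                      c("background", "nucleolus", "white", "gray", "black")),
             "class_intensity",
             "must be named background/nucleolus/white/gray/black")
  ci <- class_intensity
  check_that(all(ci >= 0 & ci <= 255), "class_intensity",
             "must lie within the 8-bit range")
  check_that(ci[["background"]] < ci[["white"]] &&
               ci[["white"]] < ci[["gray"]] && ci[["gray"]] < ci[["black"]],
             "class_intensity",
             "must be ordered background < white < gray < black")
  check_that(psf_sigma >= 0, "psf_sigma", "must be >= 0")
  check_that(photon_gain >= 0, "photon_gain", "must be >= 0")
  check_that(read_sd >= 0, "read_sd", "must be >= 0")
  check_that(n_bands >= 3, "n_bands", "need at least one band per class")
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 class_fractions = class_fractions[c("white", "gray", "black")],
                 class_intensity = ci, psf_sigma = psf_sigma,
                 photon_gain = photon_gain, read_sd = read_sd,
                 n_bands = as.integer(n_bands), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Interleaved band-class sequence: class c with m_c bands sits at positions
# (j - 1/2)/m_c, j = 1..m_c; sorting all positions spreads same-class bands
# evenly along the chromosome axis.
band_class_sequence <- function(fractions, n_bands) {
  m <- floor(fractions * n_bands)
  m[fractions > 0 & m == 0] <- 1
  while (sum(m) > n_bands) m[which.max(m)] <- m[which.max(m)] - 1
  rem <- fractions * n_bands - m
  while (sum(m) < n_bands) {
    i <- which.max(rem)
    m[i] <- m[i] + 1
    rem[i] <- -Inf
  }
  pos <- unlist(lapply(seq_along(m), function(i) {
    if (m[i] == 0) return(numeric(0))
    setNames((seq_len(m[i]) - 0.5) / m[i], rep(names(m)[i], m[i]))
  }))
  names(sort(pos))
}

# Largest-remainder integer quotas summing exactly to `total`.
integer_quotas <- function(weights, total) {
  q <- floor(weights / sum(weights) * total)
  rem <- weights / sum(weights) * total - q
  short <- total - sum(q)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    q[add] <- q[add] + 1
  }
  q
}

#' Render a banded-nucleus phantom z-stack
#'
#' Builds the ground-truth label map (voxel class counts match the target
#' volume fractions to within one voxel), paints it with the class mean
#' intensities, applies the Gaussian PSF per slice, and adds Poisson shot
#' noise and Gaussian read noise.  Fully reproducible from the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `image` (numeric 3D array `y` x `x` x `z`, 8-bit range,
#'   rounded), `labels` (integer array of the same shape: 0 background,
#'   1 nucleolus, 2 white, 3 gray, 4 black), `spec`, and `ground_truth`
#'   (realized chromatin volume fractions).
#' @export
render_nucleus_phantom <- function(spec) {
  check_that(inherits(spec, "phantom_spec"), "spec", "must be a phantom_spec")
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]

  zc <- (seq_len(nz) - (nz + 1) / 2) / max(nz / 2, 1)
  yc <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  xc <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  Y <- array(rep(yc, times = nx * nz), dim = c(ny, nx, nz))
  X <- array(rep(rep(xc, each = ny), times = nz), dim = c(ny, nx, nz))
  Z <- array(rep(zc, each = ny * nx), dim = c(ny, nx, nz))

  nucleus <- (X / 0.92)^2 + (Y / 0.92)^2 + (Z / 0.95)^2 <= 1
  # chromosome: in-plane cylinder along the y axis, radius 0.45 of the x extent
  chromosome <- nucleus & (X^2 + (Z / 0.9)^2 <= 0.45^2)
  # spherical nucleolar void off to one side, outside the chromosome
  nucleolus <- nucleus & !chromosome &
    ((X - 0.62)^2 + Y^2 + Z^2 <= 0.22^2)

  labels <- array(0L, dim = c(ny, nx, nz))
  labels[nucleolus] <- 1L

  idx <- which(chromosome)
  n_chr <- length(idx)
  check_that(n_chr > spec$n_bands, "shape",
             "too small: chromosome region has fewer voxels than bands")
  # order chromatin voxels along the chromosome axis, then stack bands
  ord <- idx[order(Y[idx], Z[idx], X[idx])]
  seq_classes <- band_class_sequence(spec$class_fractions, spec$n_bands)
  class_counts <- integer_quotas(spec$class_fractions, n_chr)
  band_quota <- unlist(lapply(c("white", "gray", "black"), function(cl) {
    nb <- sum(seq_classes == cl)
    if (nb == 0) return(NULL)
    setNames(integer_quotas(rep(1, nb), class_counts[[cl]]), rep(cl, nb))
  }))
  # walk bands in axis order, drawing each band's quota from its class
  taken <- c(white = 0L, gray = 0L, black = 0L)
  offset <- 0L
  code <- c(white = 2L, gray = 3L, black = 4L)
  per_class_used <- c(white = 0L, gray = 0L, black = 0L)
  for (cl in seq_classes) {
    k <- per_class_used[[cl]] + 1L
    q <- band_quota[which(names(band_quota) == cl)[k]]
    per_class_used[[cl]] <- k
    if (q > 0) labels[ord[offset + seq_len(q)]] <- code[[cl]]
    offset <- offset + q
  }

  ci <- spec$class_intensity
  img <- array(ci[["background"]], dim = c(ny, nx, nz))
  img[labels == 1L] <- ci[["nucleolus"]]
  img[labels == 2L] <- ci[["white"]]
  img[labels == 3L] <- ci[["gray"]]
  img[labels == 4L] <- ci[["black"]]

  if (spec$psf_sigma > 0)
    for (z in seq_len(nz))
      img[, , z] <- EBImage::gblur(img[, , z], sigma = spec$psf_sigma)

  if (spec$photon_gain > 0 || spec$read_sd > 0) {
    img <- with_seed(spec$seed, {
      out <- img
      if (spec$photon_gain > 0)
        out <- array(rpois(length(out), lambda = pmax(out, 0) * spec$photon_gain),
                     dim = dim(out)) / spec$photon_gain
      if (spec$read_sd > 0)
        out <- out + array(rnorm(length(out), 0, spec$read_sd), dim = dim(out))
      out
    })
  }
  img <- round(pmin(pmax(img, 0), 255))

  chrom_counts <- c(white = sum(labels == 2L), gray = sum(labels == 3L),
                    black = sum(labels == 4L))
  list(image = img, labels = labels, spec = spec,
       ground_truth = chrom_counts / sum(chrom_counts))
}
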