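#' Specification of a synthetic layered-retina phantom
#'
#' The phantom emulates the data regime of macular OCT volumes with fluid
#' lesions: a wavy retina band (REA, retinal edema area) bounded by two
#' smooth sinusoidal surfaces, an ellipsoidal subretinal-fluid (SRF) blob
#' inside the band, a pigment-epithelial-detachment (PED) bump deforming the
#' lower boundary, and multiplicative gamma-distributed speckle. Default
#' class fractions follow the approximate composition of clinical fluid
#' volumes: REA ~61%, SRF ~0.7%, PED ~0.03% of all voxels.
#'
#' @param shape integer triple (slices D, rows H, columns W); minimum
#'   (8, 16, 16). Rows are depth within a B-scan.
#' @param class_fractions named target voxel fractions for rea, srf, ped.
#' @param intensity_means base brightness (0-255) for background, rea, srf,
#'   ped. Defaults are stylized, well-separated levels.
#' @param speckle_looks gamma-speckle looks parameter L (mean 1, variance
#'   1/L); `Inf` disables noise.
#' @param boundary_waviness sinusoidal amplitude of the band boundaries, in
#'   voxels.
#' @param seed RNG seed; identical specs give bit-identical phantoms.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16L, 64L, 64L),
                         class_fractions = c(rea = 0.61, srf = 0.007, ped = 0.0003),
                         intensity_means = c(background = 30, rea = 110,
                                             srf = 190, ped = 240),
                         speckle_looks = 16,
                         boundary_waviness = 2,
                         seed = 1L) {
  if (length(shape) != 3L || any(shape < c(8L, 16L, 16L)))
    stop_validation("shape must be (D,H,W) with D >= 8, H >= 16, W >= 16")
  if (any(class_fractions < 0) || sum(class_fractions) >= 1)
    stop_validation("class fractions must be non-negative and sum to < 1")
  if (!(is.infinite(speckle_looks) || speckle_looks > 0))
    stop_validation("speckle_looks must be positive or Inf")
  structure(list(shape = as.integer(shape),
                 class_fractions = class_fractions,
                 intensity_means = intensity_means,
                 speckle_looks = speckle_looks,
                 boundary_waviness = boundary_waviness,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic OCT-like phantom volume with gold-standard mask
#'
#' See [phantom_spec()] for the model. Classes are coded 0 = background,
#' 1 = REA, 2 = SRF, 3 = PED. The SRF ellipsoid lies strictly inside the
#' band; PED voxels hang below (and touch) the lower band boundary. A class
#' whose target volume is below one voxel for the requested shape is emitted
#' empty with a warning.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom`: `volume` (0-255 quantized), `mask`
#'   (integer array), `realized_fractions`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  D <- spec$shape[1]; H <- spec$shape[2]; W <- spec$shape[3]
  N <- D * H * W
  fr <- spec$class_fractions

  with_seed(spec$seed, {
    ## coordinate fields, column-major flatten (d fastest)
    dmat <- rep(seq_len(D), times = H * W)
    hmat <- rep(rep(seq_len(H), each = D), times = W)
    wmat <- rep(seq_len(W), each = D * H)

    ## retina band: thickness sized to the REA target, centred vertically,
    ## wavy boundaries varying smoothly across column and slice
    thick <- fr[["rea"]] * H
    ph <- runif(4, 0, 2 * pi)
    A <- spec$boundary_waviness
    top_surface <- function(d, w)
      (H - thick) / 2 + A * sin(2 * pi * w / W + ph[1]) +
        0.5 * A * sin(2 * pi * d / D + ph[2])
    bot_surface <- function(d, w)
      top_surface(d, w) + thick +
        0.3 * A * sin(2 * pi * w / W * 2 + ph[3])
    top <- top_surface(dmat, wmat)
    bot <- bot_surface(dmat, wmat)
    mask <- integer(N)
    band <- hmat > top & hmat <= bot
    mask[band] <- 1L

    ## SRF: one ellipsoid strictly inside the band
    v_srf <- fr[["srf"]] * N
    if (v_srf >= 1) {
      q_z <- max(D / H, 0.25); q_w <- max(W / H, 0.5)
      r <- (3 * v_srf / (4 * pi * q_z * q_w))^(1 / 3)
      rh <- min(r, 0.33 * thick)
      rz <- max(q_z * r, 1); rw <- max(q_w * r, 1)
      ## rescale rz*rw to preserve volume if rh was clamped
      scale <- v_srf / (4 / 3 * pi * rz * rh * rw)
      rz <- rz * sqrt(scale); rw <- rw * sqrt(scale)
      cd <- D / 2 + runif(1, -0.1, 0.1) * D
      cw <- W / 2 + runif(1, -0.15, 0.15) * W
      chh <- top_surface(cd, cw) + thick / 2
      ell <- ((dmat - cd) / rz)^2 + ((hmat - chh) / rh)^2 + ((wmat - cw) / rw)^2 <= 1
      mask[ell & band] <- 2L
    } else {
      warning("phantom: SRF target below one voxel for this shape; class emitted empty")
    }

    ## PED: half-ellipsoid bump hanging below the lower boundary
    v_ped <- fr[["ped"]] * N
    if (v_ped >= 1) {
      rp <- (3 * v_ped / (2 * pi))^(1 / 3)
      rpz <- max(rp, 1); rpw <- max(rp, 1); hp <- max(rp, 1)
      cd <- D / 2 + runif(1, -0.2, 0.2) * D
      cw <- W / 2 + runif(1, -0.25, 0.25) * W
      bump <- pmax(0, 1 - ((dmat - cd) / rpz)^2 - ((wmat - cw) / rpw)^2)
      depth <- hp * sqrt(bump)
      ped <- hmat > bot & hmat <= bot + depth
      mask[ped] <- 3L
    } else {
      warning("phantom: PED target below one voxel for this shape; class emitted empty")
    }

    ## intensities + multiplicative gamma speckle, quantized to 8 bit
    mu <- spec$intensity_means[c("background", "rea", "srf", "ped")]
    vol <- as.numeric(mu[mask + 1L])
    if (is.finite(spec$speckle_looks)) {
      L <- spec$speckle_looks
      vol <- vol * rgamma(N, shape = L, rate = L)
    }
    vol <- pmin(pmax(round(vol), 0), 255)

    dim(vol) <- c(D, H, W)
    mask_arr <- array(mask, c(D, H, W))
    realized <- c(rea = mean(mask == 1L), srf = mean(mask == 2L),
                  ped = mean(mask == 3L), background = mean(mask == 0L))
    structure(list(volume = vol, mask = mask_arr,
                   realized_fractions = realized, spec = spec),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s voxels, speckle looks = %s, seed = %d\n",
              paste(x$spec$shape, collapse = "x"),
              format(x$spec$speckle_looks), x$spec$seed))
  cat("realized fractions:",
      paste(sprintf("%s %.4f", names(x$realized_fractions), x$realized_fractions),
            collapse = ", "), "\n")
  invisible(x)
}
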