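#' Render a dendrite's session as a two-channel image stack
#'
#' Draws one dendrite at one session as a small 3D two-channel stack: the
#' shaft as a bright band in the red channel, each present spine as a
#' Gaussian blob in both channels, plus a uniform background level. Blob
#' amplitudes are calibrated so the mean pixel value over each ROI mask
#' equals the simulated raw ROI intensity, making the stack a round-trip
#' oracle for [extract_roi_intensities()]. ROI masks (per-spine spine and
#' shaft masks and one background mask) are returned as linear voxel
#' indices into the `dim_yxz`-shaped arrays.
#'
#' @param dataset A `spine_dataset`.
#' @param dendrite_id Dendrite to render.
#' @param session Session label.
#' @param dim_yxz Stack dimensions (rows, columns, slices); default
#'   `c(256, 256, 16)`.
#' @return A list: `green`, `red` (3D arrays), `masks` (named list of
#'   voxel-index vectors: `spine_<id>`, `shaft_<id>`, `background`),
#'   `dendrite_id`, `session`.
#' @export
render_session_stack <- function(dataset, dendrite_id, session,
                                 dim_yxz = c(256, 256, 16)) {
  stopifnot(inherits(dataset, "spine_dataset"))
  if (!dendrite_id %in% dataset$dendrites$dendrite_id) {
    abort(paste0("unknown dendrite '", dendrite_id, "'"))
  }
  if (!session %in% dataset$sessions$session) {
    abort(paste0("unknown session '", session, "'"))
  }
  bg <- dataset$config$background_level
  rows <- dataset$intensities %>%
    filter(.data$session == .env$session, .data$present) %>%
    inner_join(dataset$spines %>%
                 filter(.data$dendrite_id == .env$dendrite_id) %>%
                 select("spine_id"),
               by = "spine_id")

  ny <- dim_yxz[1]; nx <- dim_yxz[2]; nz <- dim_yxz[3]
  green <- array(bg, dim = dim_yxz)
  red <- array(bg, dim = dim_yxz)
  masks <- list()

  n <- nrow(rows)
  if (n > 0) {
    xs <- round(seq(16, nx - 16, length.out = max(n, 2)))[seq_len(n)]
    y_spine <- ny %/% 2L - 8L
    y_shaft <- ny %/% 2L
    z0 <- nz %/% 2L

    ball <- function(cy, cx, cz, r_xy = 3L, r_z = 1L) {
      ys <- max(1, cy - r_xy):min(ny, cy + r_xy)
      xs_ <- max(1, cx - r_xy):min(nx, cx + r_xy)
      zs <- max(1, cz - r_z):min(nz, cz + r_z)
      g <- expand.grid(y = ys, x = xs_, z = zs)
      keep <- ((g$y - cy) / r_xy)^2 + ((g$x - cx) / r_xy)^2 +
        ((g$z - cz) / max(r_z, 1))^2 <= 1
      g <- g[keep, ]
      list(
        idx = g$y + (g$x - 1L) * ny + (g$z - 1L) * ny * nx,
        profile = exp(-((g$y - cy)^2 + (g$x - cx)^2) / (2 * 1.5^2) -
                        (g$z - cz)^2 / (2 * 0.8^2))
      )
    }
    box <- function(cy, cx, half_x = 3L, half_y = 1L, cz = z0, r_z = 1L) {
      ys <- max(1, cy - half_y):min(ny, cy + half_y)
      xs_ <- max(1, cx - half_x):min(nx, cx + half_x)
      zs <- max(1, cz - r_z):min(nz, cz + r_z)
      g <- expand.grid(y = ys, x = xs_, z = zs)
      g$y + (g$x - 1L) * ny + (g$z - 1L) * ny * nx
    }

    for (i in seq_len(n)) {
      b <- ball(y_spine, xs[i], z0)
      # scale the Gaussian profile so the ROI-mask mean equals the
      # background-subtracted raw value
      add_blob <- function(arr, target) {
        amp <- (target - bg) / mean(b$profile)
        arr[b$idx] <- bg + amp * b$profile
        arr
      }
      green <- add_blob(green, rows$green_spine[i])
      red <- add_blob(red, rows$red_spine[i])
      sh <- box(y_shaft, xs[i])
      red[sh] <- rows$red_shaft[i]
      masks[[paste0("spine_", rows$spine_id[i])]] <- b$idx
      masks[[paste0("shaft_", rows$spine_id[i])]] <- sh
    }
  }
  masks$background <- as.vector(outer(
    1:8, (1:8 - 1L) * ny, `+`
  )) # top-left 8x8 box on slice 1

  list(green = green, red = red, masks = masks,
       dendrite_id = dendrite_id, session = session)
}

#' Mean ROI intensities from a rendered stack
#'
#' Computes the mean pixel value of each ROI mask in both channels.
#'
#' @param stack A list with `green` and `red` arrays (e.g. from
#'   [render_session_stack()]).
#' @param masks Named list of voxel-index vectors.
#' @return Tibble with `roi`, `green`, `red`, `n_pixels`.
#' @export
extract_roi_intensities <- function(stack, masks) {
  n_total <- length(stack$green)
  purrr::imap_dfr(masks, function(idx, name) {
    if (length(idx) == 0L) abort(paste0("empty mask '", name, "'"))
    if (any(idx < 1L | idx > n_total)) {
      abort(paste0("mask '", name, "' outside stack bounds"))
    }
    tibble(roi = name,
           green = mean(stack$green[idx]),
           red = mean(stack$red[idx]),
           n_pixels = length(idx))
  })
}

#' Write a rendered stack as multi-page TIFF with a JSON mask sidecar
#'
#' Pages are interleaved (green, red) per slice; pixel values are scaled
#' to \[0, 1\] by the joint maximum (recorded in the sidecar). Masks are
#' stored as 1-based voxel indices.
#'
#' @param stack Output of [render_session_stack()].
#' @param path Output TIFF path; the sidecar is written as
#'   `<path>.masks.json`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("write_stack_tiff() requires the 'tiff' package")
  }
  mx <- max(stack$green, stack$red)
  nz <- dim(stack$green)[3]
  pages <- vector("list", 2L * nz)
  for (z in seq_len(nz)) {
    pages[[2L * z - 1L]] <- stack$green[, , z] / mx
    pages[[2L * z]] <- stack$red[, , z] / mx
  }
  tiff::writeTIFF(pages, path)
  jsonlite::write_json(
    list(dendrite_id = stack$dendrite_id, session = stack$session,
         dim_yxz = dim(stack$green), intensity_scale = mx,
         channel_order = c("green", "red"), masks = stack$masks),
    paste0(path, ".masks.json"), auto_unbox = TRUE
  )
  invisible(path)
}
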