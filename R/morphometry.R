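#' Grayscale micrograph container
#'
#' A micrograph is a 2-D matrix of grayscale intensities plus the physical
#' pixel size in nanometres per pixel, the calibration every downstream
#' length and area is expressed in.
#'
#' @param pixels Numeric matrix of finite intensities (rows = image rows).
#' @param pixel_size Nanometres per pixel (> 0).
#' @return A list of class `micrograph` with elements `pixels` and
#'   `pixel_size`.
#' @export
micrograph <- function(pixels, pixel_size = 1) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  structure(
    list(pixels = pixels, pixel_size = pixel_size),
    class = "micrograph"
  )
}

#' Read a grayscale micrograph from PNG or TIFF
#'
#' Multi-channel images are averaged to grayscale.
#'
#' @param path PNG or TIFF file path.
#' @param pixel_size Nanometres per pixel.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size = 1) {
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  # EBImage stores x-by-y; transpose to row-by-column
  micrograph(t(px), pixel_size = pixel_size)
}

check_micrograph <- function(img) {
  if (!inherits(img, "micrograph")) img <- micrograph(img)
  img
}

#' Binarize a micrograph
#'
#' Separates fibers from background by thresholding: `"otsu"` picks the
#' level maximising between-class variance, `"fixed"` uses the supplied
#' `level`. Foreground is everything strictly above the level. The method
#' and level used are recorded as attributes for provenance.
#'
#' @param img A [micrograph()] or plain intensity matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param level Threshold intensity for `method = "fixed"`.
#' @return A logical matrix (TRUE = foreground) with attributes `method`
#'   and `level`.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  img <- check_micrograph(img)
  px <- img$pixels
  if (method == "otsu") {
    rng <- range(px)
    if (diff(rng) == 0) {
      stop("constant image: Otsu threshold undefined", call. = FALSE)
    }
    norm <- (px - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(t(norm)))
    level <- rng[1] + th * diff(rng)
  } else if (is.null(level)) {
    stop("`level` required for method = \"fixed\"", call. = FALSE)
  }
  mask <- px > level
  attr(mask, "method") <- method
  attr(mask, "level") <- level
  mask
}

#' Label connected components and measure them
#'
#' Labels the connected foreground components of a binary mask (4- or
#' 8-connectivity) and measures each one: pixel count, area in nm^2
#' (pixels times `pixel_size`^2), and major-axis length in nm (the extent
#' of the component along its principal axis, plus one pixel width, times
#' `pixel_size`). Labels are contiguous 1..n in order of first appearance.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_size Nanometres per pixel.
#' @param connectivity 8 (default, diagonal neighbours connect) or 4.
#' @return An object of class `segmentation_result`: list with `label_map`
#'   (integer matrix, 0 = background), `n_components`, a `components`
#'   tibble (`label`, `n_pixels`, `area_nm2`, `length_nm`), and
#'   `pixel_size`. Supports `tidy()` and `glance()`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:3, 2:3] <- TRUE; m[6:7, 5:8] <- TRUE
#' label_components(m, pixel_size = 10)$n_components
#' @export
label_components <- function(mask, pixel_size = 1, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  mask <- mask > 0
  measure_label_map(label_mask(mask, connectivity), pixel_size)
}

# connected-component labeling via igraph on the pixel-adjacency graph;
# labels assigned in order of first appearance (column-major)
label_mask <- function(mask, connectivity) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) {
    return(lab)
  }
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  }
  r <- (fg - 1L) %% nr + 1L
  cc <- (fg - 1L) %/% nr + 1L
  edges <- integer(0)
  for (s in shifts) {
    r2 <- r + s[1]
    c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- id[j] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(id[fg[ok]][hit], id[j][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  # relabel in order of first appearance
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[fg] <- relab[memb]
  lab
}

# extent (pixels) of a pixel cloud along its principal axis, plus one
# pixel of width so a single pixel has extent 1
major_axis_extent <- function(rows, cols) {
  if (length(rows) == 1) {
    return(1)
  }
  m <- cbind(rows, cols)
  m <- sweep(m, 2, colMeans(m))
  ev <- eigen(stats::cov(m), symmetric = TRUE)$vectors[, 1]
  proj <- m %*% ev
  diff(range(proj)) + 1
}

#' Canny edge detection
#'
#' Classic Canny pipeline: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantised gradient direction, and
#' two-level hysteresis (weak edges survive only when 8-connected to a
#' strong edge). Thresholds are quantiles of the nonzero gradient
#' magnitudes.
#'
#' @param img A [micrograph()] or intensity matrix.
#' @param sigma Gaussian smoothing radius in pixels.
#' @param low,high Hysteresis thresholds as quantiles of the nonzero
#'   gradient magnitude (defaults 0.5 and 0.8).
#' @return A logical edge map matrix.
#' @export
canny_edges <- function(img, sigma = 1, low = 0.5, high = 0.8) {
  img <- check_micrograph(img)
  px <- img$pixels
  sm <- t(EBImage::imageData(
    EBImage::gblur(EBImage::Image(t(px)), sigma = sigma)
  ))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- t(EBImage::imageData(
    EBImage::filter2(EBImage::Image(t(sm)), t(kx), boundary = "replicate")
  ))
  gy <- t(EBImage::imageData(
    EBImage::filter2(EBImage::Image(t(sm)), kx, boundary = "replicate")
  ))
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) {
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  ang <- atan2(gy, gx)
  # quantise direction to 0, 45, 90, 135 degrees
  sector <- (round(ang / (pi / 4)) %% 4) + 1
  nr <- nrow(mag)
  nc <- ncol(mag)
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  nms <- matrix(FALSE, nr, nc)
  ri <- 2:(nr - 1)
  ci <- 2:(nc - 1)
  for (s in 1:4) {
    dr <- off[[s]][1]
    dc <- off[[s]][2]
    m0 <- mag[ri, ci]
    sel <- sector[ri, ci] == s &
      m0 >= mag[ri + dr, ci + dc] & m0 >= mag[ri - dr, ci - dc]
    nms[ri, ci] <- nms[ri, ci] | sel
  }
  nzmag <- mag[mag > 0]
  th_hi <- stats::quantile(nzmag, high, names = FALSE)
  th_lo <- stats::quantile(nzmag, low, names = FALSE)
  strong <- nms & mag >= th_hi
  weak <- nms & mag >= th_lo
  if (!any(strong)) {
    return(strong)
  }
  lab <- label_mask(weak, connectivity = 8)
  keep <- unique(lab[strong])
  weak & matrix(lab %in% keep, nr, nc)
}

#' Compare a binary mask against Canny edges
#'
#' Extracts the boundary of the mask (foreground pixels with a background
#' 4-neighbour) and reports the fraction of boundary pixels that have a
#' Canny edge pixel within `tol_px` pixels (Chebyshev distance). A blank
#' edge map gives an overlap of 0 with `undefined = TRUE`.
#'
#' @inheritParams canny_edges
#' @param mask Logical foreground mask, same dimensions as the image.
#' @param tol_px Matching tolerance in pixels (default 1).
#' @return A list with `edge_map`, `boundary` (logical matrices),
#'   `overlap_fraction`, `n_boundary`, `n_edges`, and `undefined`.
#' @export
canny_compare <- function(img, mask, sigma = 1, low = 0.5, high = 0.8,
                          tol_px = 1) {
  img <- check_micrograph(img)
  mask <- mask > 0
  edges <- canny_edges(img, sigma = sigma, low = low, high = high)
  boundary <- mask_boundary(mask)
  nb <- sum(boundary)
  ne <- sum(edges)
  if (nb == 0 || ne == 0) {
    return(list(
      edge_map = edges, boundary = boundary, overlap_fraction = 0,
      n_boundary = nb, n_edges = ne, undefined = TRUE
    ))
  }
  near <- dilate_mask(edges, tol_px)
  list(
    edge_map = edges, boundary = boundary,
    overlap_fraction = sum(boundary & near) / nb,
    n_boundary = nb, n_edges = ne, undefined = FALSE
  )
}

mask_boundary <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  inner <- core &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  core & !inner
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) {
    return(mask)
  }
  out <- mask
  nr <- nrow(mask)
  nc <- ncol(mask)
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr == 0 && dc == 0) next
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      rd <- max(1, 1 - dr):min(nr, nr - dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      cd <- max(1, 1 - dc):min(nc, nc - dc)
      out[rd, cd] <- out[rd, cd] | mask[rs, cs]
    }
  }
  out
}

#' Morphometry summary of a segmentation
#'
#' Mean and standard deviation of the per-component major-axis lengths
#' (nm) and areas (nm^2), plus a histogram of lengths. The default
#' standard deviation convention is the population one (divide by n);
#' `sd_type = "sample"` divides by n - 1.
#'
#' @param seg A `segmentation_result` from [label_components()].
#' @param n_bins Number of histogram bins.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A list of class `morphometry_summary`: `stats` (one-row tibble
#'   with `mean_length`, `sd_length`, `mean_area`, `sd_area`,
#'   `n_components`) and `histogram` (tibble `bin_mid`, `count` over
#'   lengths).
#' @export
morphometry_summary <- function(seg, n_bins = 10,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(seg, "segmentation_result"))
  comp <- seg$components
  if (nrow(comp) == 0) {
    stop("empty segmentation: nothing to summarise", call. = FALSE)
  }
  sdev <- function(x) {
    if (sd_type == "population") {
      sqrt(mean((x - mean(x))^2))
    } else {
      stats::sd(x)
    }
  }
  br <- seq(min(comp$length_nm), max(comp$length_nm), length.out = n_bins + 1)
  if (br[1] == br[n_bins + 1]) br <- br[1] + c(-0.5, 0.5)
  h <- graphics::hist(comp$length_nm, breaks = br, plot = FALSE)
  structure(
    list(
      stats = tibble::tibble(
        mean_length = mean(comp$length_nm),
        sd_length = sdev(comp$length_nm),
        mean_area = mean(comp$area_nm2),
        sd_area = sdev(comp$area_nm2),
        n_components = nrow(comp)
      ),
      histogram = tibble::tibble(bin_mid = h$mids, count = h$counts),
      sd_type = sd_type
    ),
    class = "morphometry_summary"
  )
}

#' Synthetic fiber-network phantom with ground truth
#'
#' Renders a synthetic micrograph emulating the fiber-and-microsphere
#' morphology of proteinoid-actin composites: thick random-walk fiber
#' strokes and filled discs (microspheres) on a darker background, with
#' optional Gaussian intensity noise. Objects are placed so they never
#' touch (a 2-pixel clearance), and the exact ground-truth segmentation is
#' returned alongside the image, so the full binarize-label-measure
#' pipeline can be validated against known truth.
#'
#' @param n_fibers,n_spheres Number of fiber strokes and discs.
#' @param width,height Image size in pixels.
#' @param pixel_size Nanometres per pixel.
#' @param fiber_steps Number of random-walk steps per fiber.
#' @param step_px Walk step length in pixels.
#' @param fiber_halfwidth Stroke half-width in pixels (stamped disc
#'   radius).
#' @param sphere_radius Disc radius in pixels.
#' @param fg,bg Foreground and background intensities.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units).
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @param max_tries Placement attempts per object before a placement error
#'   is raised.
#' @return A list with `image` (a [micrograph()]) and `truth` (a
#'   `segmentation_result`).
#' @examples
#' ph <- generate_phantom(n_fibers = 3, width = 128, height = 128, seed = 1)
#' ph$truth$n_components
#' @export
generate_phantom <- function(n_fibers = 50, n_spheres = 0, width = 512,
                             height = 512, pixel_size = 20,
                             fiber_steps = 40, step_px = 3,
                             fiber_halfwidth = 2, sphere_radius = 12,
                             fg = 1, bg = 0, noise_sd = 0, seed = 1,
                             max_tries = 400) {
  withr_seed(seed, {
    lab <- matrix(0L, height, width)
    occupied <- matrix(FALSE, height, width)
    k <- 0L
    stamp <- function(rows, cols, radius) {
      # pixels within `radius` of any of the given centres
      offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
      offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
      r <- rep(round(rows), each = nrow(offs)) + offs$dr
      c <- rep(round(cols), each = nrow(offs)) + offs$dc
      ok <- r >= 1 & r <= height & c >= 1 & c <= width
      unique((c[ok] - 1L) * height + r[ok])
    }
    place <- function(pix) {
      # reject if the object (dilated by 2 px) touches anything placed
      clear <- matrix(FALSE, height, width)
      clear[pix] <- TRUE
      clear <- dilate_mask(clear, 2)
      if (any(clear & occupied)) {
        return(FALSE)
      }
      k <<- k + 1L
      lab[pix] <<- k
      occupied <<- occupied | clear
      TRUE
    }
    for (i in seq_len(n_fibers)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- stats::runif(1, 1, height)
        c0 <- stats::runif(1, 1, width)
        ang <- stats::runif(1, 0, 2 * pi)
        rows <- numeric(fiber_steps)
        cols <- numeric(fiber_steps)
        for (s in seq_len(fiber_steps)) {
          rows[s] <- r0
          cols[s] <- c0
          ang <- ang + stats::rnorm(1, 0, 0.3)
          r0 <- min(max(r0 + step_px * sin(ang), 1), height)
          c0 <- min(max(c0 + step_px * cos(ang), 1), width)
        }
        if (place(stamp(rows, cols, fiber_halfwidth))) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place fiber ", i, " after ", max_tries,
          " attempts: geometry overcrowded",
          call. = FALSE
        )
      }
    }
    for (i in seq_len(n_spheres)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- stats::runif(1, sphere_radius + 1, height - sphere_radius)
        c0 <- stats::runif(1, sphere_radius + 1, width - sphere_radius)
        if (place(stamp(r0, c0, sphere_radius))) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place sphere ", i, " after ", max_tries,
          " attempts: geometry overcrowded",
          call. = FALSE
        )
      }
    }
    px <- matrix(bg, height, width)
    px[lab > 0] <- fg
    if (noise_sd > 0) {
      px <- px + matrix(
        stats::rnorm(length(px), 0, noise_sd), height, width
      )
    }
    # ground truth measured from the painted label map
    truth <- measure_label_map(lab, pixel_size)
    list(image = micrograph(px, pixel_size = pixel_size), truth = truth)
  })
}

measure_label_map <- function(lab, pixel_size) {
  n <- max(lab)
  comps <- if (n == 0) {
    tibble::tibble(
      label = integer(0), n_pixels = integer(0),
      area_nm2 = numeric(0), length_nm = numeric(0)
    )
  } else {
    idx <- which(lab > 0)
    labs <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    purrr::map_dfr(seq_len(n), function(k) {
      sel <- labs == k
      tibble::tibble(
        label = k,
        n_pixels = sum(sel),
        area_nm2 = sum(sel) * pixel_size^2,
        length_nm = major_axis_extent(rows[sel], cols[sel]) * pixel_size
      )
    })
  }
  structure(
    list(
      label_map = lab, n_components = n, components = comps,
      pixel_size = pixel_size
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d components, pixel size %g nm\n",
    x$n_components, x$pixel_size
  ))
  invisible(x)
}
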