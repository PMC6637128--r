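#' Otsu threshold
#'
#' Classic histogram threshold maximizing the between-class variance; used to
#' separate dark (myelin-poor tumor) from bright (myelinated brain) pixels by
#' intensity alone. Invariant to global intensity scaling.
#'
#' @param x numeric values.
#' @param n_bins histogram bins (default 256).
#' @return list with `threshold`, class means `mu0` (below) and `mu1`
#'   (above), and `separability` (between-class over total variance).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0)
    return(list(threshold = rng[1], mu0 = rng[1], mu1 = rng[1],
                separability = 0))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  between <- (mu_tot * w0 - mu_cum)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  thr <- edges[k + 1]
  tot_var <- sum(p * (mids - mu_tot)^2)
  list(threshold = thr,
       mu0 = if (any(x <= thr)) mean(x[x <= thr]) else NA_real_,
       mu1 = if (any(x > thr)) mean(x[x > thr]) else NA_real_,
       separability = if (tot_var > 0) between[k] / tot_var else 0)
}

# connected components by iterative min-label propagation (4-connectivity);
# masks here are small en-face images, so simplicity beats asymptotics
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  repeat {
    nb <- lab
    nb[-1, ] <- pmin(nb[-1, ], ifelse(lab[-nrow(lab), ] > 0,
                                      lab[-nrow(lab), ], Inf))
    nb[-nrow(lab), ] <- pmin(nb[-nrow(lab), ],
                             ifelse(lab[-1, ] > 0, lab[-1, ], Inf))
    nb[, -1] <- pmin(nb[, -1], ifelse(lab[, -ncol(lab)] > 0,
                                      lab[, -ncol(lab)], Inf))
    nb[, -ncol(lab)] <- pmin(nb[, -ncol(lab)],
                             ifelse(lab[, -1] > 0, lab[, -1], Inf))
    nb[!mask] <- 0
    nb[is.infinite(nb)] <- 0
    if (identical(nb, lab)) break
    lab <- nb
  }
  # compact label ids
  ids <- sort(unique(lab[lab > 0]))
  matrix(match(lab, c(0L, ids)) - 1L, nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  bg <- label_components(!mask)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_ids <- border_ids[border_ids > 0]
  mask | (bg > 0 & !(bg %in% border_ids))
}

#' Segment tumor from an en-face slab
#'
#' Tumor lacks myelinated structures and appears dark, so an Otsu threshold
#' on a linear-intensity en-face slab separates it from bright brain: tumor
#' is the below-threshold class, small components are removed and holes
#' filled. If the dark class is not convincingly darker than the bright class
#' (mean ratio above `dark_ratio_max`) the slab is treated as tumor-free and
#' an empty mask returned with a warning.
#'
#' @param slab 2-D matrix (x by y) of linear intensity averaged over a depth
#'   window below the flattened surface.
#' @param pixel_pitch_um lateral pitch of the slab (scalar or length 2).
#' @param min_component_area_um2 components smaller than this are dropped.
#' @param dark_ratio_max no-tumor heuristic threshold on mu_dark/mu_bright.
#' @return logical matrix (TRUE = tumor) with attributes `threshold` and
#'   `pixel_pitch_um`.
#' @export
segment_tumor <- function(slab, pixel_pitch_um, min_component_area_um2 = 900,
                          dark_ratio_max = 0.5) {
  stopifnot(is.matrix(slab), all(slab >= 0))
  pitch <- rep(as.numeric(pixel_pitch_um), length.out = 2)
  ot <- otsu_threshold(as.numeric(slab))
  empty <- matrix(FALSE, nrow(slab), ncol(slab))
  attr(empty, "threshold") <- ot$threshold
  attr(empty, "pixel_pitch_um") <- pitch
  if (!is.finite(ot$mu0) || !is.finite(ot$mu1) ||
      ot$mu0 >= dark_ratio_max * ot$mu1) {
    warning("no tumor-like dark class found; returning empty mask")
    return(empty)
  }
  mask <- slab <= ot$threshold
  lab <- label_components(mask)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0]) * prod(pitch)
    keep <- which(areas >= min_component_area_um2)
    mask <- lab %in% keep & mask
    dim(mask) <- dim(slab)
  }
  if (any(mask)) mask <- fill_holes(mask)
  attr(mask, "threshold") <- ot$threshold
  attr(mask, "pixel_pitch_um") <- pitch
  mask
}

#' Extract the tumor margin curve
#'
#' Sub-pixel boundary of the largest tumor component, traced with a marching
#' contour at level 0.5 in micron coordinates. Components that touch the
#' image border (e.g. a half-plane tumor) yield an open polyline along the
#' true tissue margin only; the image frame itself is never part of the
#' contour.
#'
#' @param mask logical tumor mask from [segment_tumor()].
#' @param pixel_pitch_um lateral pitch (scalar or length 2); defaults to the
#'   mask's attribute.
#' @return matrix of ordered boundary points, columns `x_um`, `y_um`, class
#'   `margin_curve`.
#' @export
extract_margin_curve <- function(mask, pixel_pitch_um = NULL) {
  if (!any(mask)) stop("empty mask has no margin")
  if (is.null(pixel_pitch_um)) pixel_pitch_um <- attr(mask, "pixel_pitch_um")
  pitch <- rep(as.numeric(pixel_pitch_um), length.out = 2)
  lab <- label_components(mask)
  big <- which.max(tabulate(lab[lab > 0]))
  comp <- (lab == big) * 1.0
  # 3x3 box smoothing (replicated borders) before contouring: the 0.5 level
  # of the smoothed field tracks the region edge with sub-pixel accuracy and
  # removes the marching-squares staircase bias on curved margins, while
  # straight edges keep their exact position by symmetry
  nr <- nrow(comp); nc <- ncol(comp)
  acc <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1), nc)
    acc <- acc + comp[ri, cj]
  }
  sm <- acc / 9
  xs <- (seq_len(nrow(mask)) - 0.5) * pitch[1]
  ys <- (seq_len(ncol(mask)) - 0.5) * pitch[2]
  cl <- grDevices::contourLines(xs, ys, sm, levels = 0.5)
  if (!length(cl)) stop("no contour found")
  cl <- cl[[which.max(vapply(cl, function(l) length(l$x), numeric(1)))]]
  pts <- cbind(x_um = cl$x, y_um = cl$y)
  if (nrow(pts) < 2) stop("margin degenerates to fewer than two points")
  structure(pts, class = c("margin_curve", class(pts)))
}

# minimum distance from each point to a polyline given by ordered vertices
polyline_distance <- function(pts, poly) {
  n <- nrow(pts)
  dmin <- rep(Inf, n)
  for (s in seq_len(nrow(poly) - 1)) {
    q1 <- poly[s, ]; q2 <- poly[s + 1, ]
    v <- q2 - q1
    L2 <- sum(v^2)
    if (L2 == 0) {
      dd <- sqrt((pts[, 1] - q1[1])^2 + (pts[, 2] - q1[2])^2)
    } else {
      t <- ((pts[, 1] - q1[1]) * v[1] + (pts[, 2] - q1[2]) * v[2]) / L2
      t <- pmin(pmax(t, 0), 1)
      dd <- sqrt((pts[, 1] - (q1[1] + t * v[1]))^2 +
                 (pts[, 2] - (q1[2] + t * v[2]))^2)
    }
    dmin <- pmin(dmin, dd)
  }
  dmin
}

#' Margin localization error
#'
#' Symmetric point-to-curve distances between an estimated and a true margin:
#' distances from every estimated point to the truth polyline and from every
#' truth point to the estimated polyline are pooled, penalizing both over-
#' and under-segmentation.
#'
#' @param estimated,truth two-column matrices of ordered boundary points in
#'   microns (e.g. [extract_margin_curve()] output).
#' @return list with `mean_abs_error_um` and `p95_error_um`.
#' @export
margin_error <- function(estimated, truth) {
  estimated <- unclass(estimated); truth <- unclass(truth)
  if (is.null(dim(estimated)) || is.null(dim(truth)) ||
      nrow(estimated) < 2 || nrow(truth) < 2)
    stop("margin curves must contain at least two points")
  d1 <- polyline_distance(estimated[, 1:2, drop = FALSE],
                          truth[, 1:2, drop = FALSE])
  d2 <- polyline_distance(truth[, 1:2, drop = FALSE],
                          estimated[, 1:2, drop = FALSE])
  d <- c(d1, d2)
  list(mean_abs_error_um = mean(d),
       p95_error_um = unname(stats::quantile(d, 0.95)))
}

#' Cortical layer intensity profile
#'
#' Depth profile of the lateral mean of a flattened volume, with per-band
#' statistics and the adjacent-band contrast-to-noise ratio
#' CNR = |mu1 - mu2| / sqrt((sigma1^2 + sigma2^2) / 2). Band edges can be
#' supplied in microns (depth from the top of the flattened volume) or
#' detected automatically from the local minima of the smoothed profile.
#'
#' @param volume flattened linear-scale [intensity_volume()].
#' @param band_edges_um strictly increasing vector of at least 3 band edges;
#'   band b covers `[edge_b, edge_{b+1})`. `NULL` detects interior edges at
#'   the profile's local minima and brackets them with the depth range.
#' @return object of class `layer_profile`.
#' @export
layer_profile <- function(volume, band_edges_um = NULL) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (volume$log_scaled) stop("layer statistics require linear scale")
  v <- volume$values
  nz <- dim(v)[1]
  depth <- (seq_len(nz) - 1) * volume$axial_pitch_um
  prof <- apply(v, 1, mean)
  if (is.null(band_edges_um)) {
    sm <- stats::filter(prof, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- prof[is.na(sm)]
    interior <- 3:(nz - 2)
    is_min <- vapply(interior, function(i)
      sm[i] < sm[i - 1] && sm[i] <= sm[i + 1], logical(1))
    band_edges_um <- c(0, depth[interior[is_min]],
                       max(depth) + volume$axial_pitch_um)
  }
  edges <- sort(unique(band_edges_um))
  if (length(edges) < 3) stop("fewer than 2 resolvable bands")
  bands <- lapply(seq_len(length(edges) - 1), function(b) {
    sel <- depth >= edges[b] & depth < edges[b + 1]
    vals <- as.numeric(v[sel, , , drop = FALSE])
    c(mu = mean(vals), sigma = stats::sd(vals))
  })
  stats_df <- do.call(rbind, bands)
  stats_df <- data.frame(band = seq_len(nrow(stats_df)),
                         z_min_um = edges[-length(edges)],
                         z_max_um = edges[-1],
                         mu = stats_df[, "mu"], sigma = stats_df[, "sigma"])
  dmu <- abs(diff(stats_df$mu))
  denom <- sqrt((stats_df$sigma[-nrow(stats_df)]^2 +
                   stats_df$sigma[-1]^2) / 2)
  cnr <- ifelse(dmu == 0, 0, dmu / denom)
  structure(list(depth_um = depth, profile = prof,
                 band_edges_um = edges, bands = stats_df,
                 cnr = cnr),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat("layer_profile:", nrow(x$bands), "bands; adjacent-band CNR:",
      paste(signif(x$cnr, 3), collapse = ", "), "\n")
  invisible(x)
}
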