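#' Least-squares cross-validated bandwidth for a bivariate normal kernel
#'
#' Selects the isotropic smoothing parameter h (km) minimising the
#' least-squares cross-validation (LSCV) estimate of integrated squared
#' error for a fixed bivariate normal kernel,
#' \deqn{LSCV(h) = \int \hat f^2 - \frac{2}{n}\sum_i \hat f_{-i}(x_i),}
#' evaluated in closed form from pairwise squared distances and minimised
#' by golden-section search over `[0.05, 2]` times the bivariate normal
#' reference bandwidth. If the minimiser collapses onto the lower bound
#' (duplicate-heavy data drive h towards 0) it is clamped there with a
#' warning.
#'
#' @param xy Projected point coordinates in km (tibble/matrix with two
#'   columns); at least 10 distinct points.
#' @param search Numeric length-2 multiplier range around the reference
#'   bandwidth.
#' @param n_trace Number of points in the reported criterion trace.
#' @return List of class `lscv_bandwidth`: `h` (km), `h_ref` (reference
#'   bandwidth), and `trace` tibble (`h`, `criterion`).
#' @export
lscv_bandwidth <- function(xy, search = c(0.05, 2), n_trace = 40) {
  xy <- as_xy_matrix(xy)
  if (nrow(unique(round(xy, 9))) < 10) {
    stop_bad_input("need at least 10 distinct points for LSCV")
  }
  n <- nrow(xy)
  # bivariate normal reference bandwidth (isotropic): sigma * n^(-1/6)
  sigma <- sqrt(mean(c(var(xy[, 1]), var(xy[, 2]))))
  h_ref <- sigma * n^(-1 / 6)
  d2 <- as.vector(stats::dist(xy))^2   # pairwise i<j squared distances

  crit <- function(h) {
    # int f^2 = 1/(4 pi n^2 h^2) * [n + 2 sum_{i<j} exp(-d2/(4h^2))]
    # sum_i f_{-i}(x_i) = 2/( (n-1) 2 pi h^2 ) * sum_{i<j} exp(-d2/(2h^2))
    s4 <- sum(exp(-d2 / (4 * h^2)))
    s2 <- sum(exp(-d2 / (2 * h^2)))
    (n + 2 * s4) / (4 * pi * n^2 * h^2) - 2 / (pi * n * (n - 1) * h^2) * s2
  }
  lo <- search[1] * h_ref; hi <- search[2] * h_ref
  opt <- stats::optimize(crit, interval = c(lo, hi), tol = 1e-4 * h_ref)
  h <- opt$minimum
  if (h <= lo * 1.02 && crit(lo) <= crit(lo * 1.05)) {
    warning("LSCV criterion decreasing towards h -> 0; clamping to the lower search bound")
    h <- lo
  }
  hs <- exp(seq(log(lo), log(hi), length.out = n_trace))
  structure(
    list(h = h, h_ref = h_ref,
         trace = tibble(h = hs, criterion = vapply(hs, crit, numeric(1)))),
    class = "lscv_bandwidth"
  )
}

as_xy_matrix <- function(xy) {
  if (is.data.frame(xy)) xy <- cbind(xy$x %||% xy[[1]], xy$y %||% xy[[2]])
  m <- as.matrix(xy)
  stopifnot(ncol(m) == 2, is.numeric(m))
  m
}

#' Fixed-kernel utilization distribution on a grid
#'
#' Bivariate normal kernel density estimate on a regular grid in the local
#' projected frame, normalised to unit mass over the grid. The grid extends
#' `margin` (default 3.5 h) beyond the data range so the truncated mass is
#' negligible; an error is raised if the mass deficit before normalisation
#' exceeds 1e-3.
#'
#' @param xy Projected points, km.
#' @param h Isotropic bandwidth, km (e.g. from [lscv_bandwidth()]).
#' @param cell_km Grid cell side, km (default 1).
#' @param margin Margin beyond the data range, km; default `3.5 * h`.
#' @return Object of class `ud_grid`: list with `x`, `y` (cell-centre
#'   coordinates), `z` (density per km^2, `length(x)` x `length(y)`),
#'   `cell_km`, `h`, `n_points`.
#' @export
kde_ud <- function(xy, h, cell_km = 1, margin = NULL) {
  xy <- as_xy_matrix(xy)
  if (nrow(xy) == 0) stop_bad_input("no points supplied to kde_ud")
  if (h <= 0) stop_bad_input("bandwidth h must be positive")
  margin <- margin %||% (3.5 * h)
  gx <- grid_axis(range(xy[, 1]), margin, cell_km)
  gy <- grid_axis(range(xy[, 2]), margin, cell_km)
  # separable Gaussian kernel: z = Kx %*% t(Ky) / (2 pi h^2 n)
  Kx <- exp(-outer(gx, xy[, 1], "-")^2 / (2 * h^2))
  Ky <- exp(-outer(gy, xy[, 2], "-")^2 / (2 * h^2))
  z <- (Kx %*% t(Ky)) / (2 * pi * h^2 * nrow(xy))
  mass <- sum(z) * cell_km^2
  if (mass < 1 - 1e-3) {
    stop_bad_input(sprintf("grid truncates %.4f of the kernel mass; enlarge margin", 1 - mass))
  }
  z <- z / mass
  structure(list(x = gx, y = gy, z = z, cell_km = cell_km, h = h,
                 n_points = nrow(xy)),
            class = "ud_grid")
}

grid_axis <- function(r, margin, cell) {
  lo <- floor((r[1] - margin) / cell) * cell
  hi <- ceiling((r[2] + margin) / cell) * cell
  seq(lo + cell / 2, hi - cell / 2 + 1e-9, by = cell)
}

#' Probability contour of a utilization distribution
#'
#' The p% contour is the smallest set of grid cells, taken in order of
#' descending density, whose total mass reaches p/100; its reported mass
#' therefore lies in `[p/100, p/100 + one cell's mass]`.
#'
#' @param ud A [kde_ud()] grid.
#' @param level Probability level in percent, strictly between 0 and 100.
#' @return List with `level`, `mass` (attained), `area_km2`, `threshold`
#'   (density cut), `cells` (tibble `x`, `y`, `density` of member cells),
#'   and `outline` (list of x/y paths from [grDevices::contourLines()] at
#'   the threshold, for plotting).
#' @export
probability_contour <- function(ud, level) {
  stopifnot(inherits(ud, "ud_grid"))
  if (level <= 0 || level >= 100) stop_bad_input("level must be in (0, 100)")
  cell_mass <- as.vector(ud$z) * ud$cell_km^2
  ord <- order(cell_mass, decreasing = TRUE)
  cum <- cumsum(cell_mass[ord])
  k <- which(cum >= level / 100)[1]
  sel <- ord[seq_len(k)]
  idx <- arrayInd(sel, dim(ud$z))
  thr <- as.vector(ud$z)[ord[k]]
  outline <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = thr)
  list(level = level, mass = cum[k], area_km2 = k * ud$cell_km^2,
       threshold = thr,
       cells = tibble(x = ud$x[idx[, 1]], y = ud$y[idx[, 2]],
                      density = as.vector(ud$z)[sel]),
       outline = outline)
}

#' Areas and masses of several probability contours
#'
#' @param ud A [kde_ud()] grid.
#' @param levels Percent levels, default `c(25, 50, 75, 95)`.
#' @return Tibble `level`, `mass`, `area_km2`; areas are non-decreasing in
#'   level and the cell sets are nested.
#' @export
probability_contours <- function(ud, levels = c(25, 50, 75, 95)) {
  purrr::map_dfr(sort(levels), function(l) {
    pc <- probability_contour(ud, l)
    tibble(level = l, mass = pc$mass, area_km2 = pc$area_km2)
  })
}

#' Central-tendency points of a distribution of locations
#'
#' Two summaries used for mapping seasonal centres: the geometric mean of
#' the locations (computed on strictly positive coordinates after a false
#' origin shift, then shifted back) and the density-weighted centre of mass
#' of the cells in the 95% probability contour.
#'
#' @param xy Projected points, km.
#' @param ud A [kde_ud()] grid of the same points.
#' @param level Contour level for the centre of mass (default 95).
#' @param false_origin Offset (km) added to both axes before the geometric
#'   mean so coordinates are positive; increased automatically if needed.
#' @return Tibble with rows `geometric_mean` and `center_of_mass`, columns
#'   `which`, `x`, `y`.
#' @export
central_points <- function(xy, ud, level = 95, false_origin = 1000) {
  xy <- as_xy_matrix(xy)
  shift <- false_origin
  while (any(xy + shift <= 0)) shift <- shift * 2
  gm <- exp(colMeans(log(xy + shift))) - shift
  pc <- probability_contour(ud, level)
  w <- pc$cells$density / sum(pc$cells$density)
  com <- c(sum(w * pc$cells$x), sum(w * pc$cells$y))
  tibble(which = c("geometric_mean", "center_of_mass"),
         x = c(gm[1], com[1]), y = c(gm[2], com[2]))
}

#' Estuary-occupancy polygon from pre-migration fixes
#'
#' Concave (alpha-shape) hull of the projected pre-change-point locations,
#' with a convex-hull fallback when the alpha shape does not close into a
#' single ring. The summary reports the hull area, the alongshore span
#' (east-west extent) and the maximum offshore (northward) extent.
#'
#' @param xy Projected points, km (>= 3 non-collinear).
#' @param alpha_km Radius of the alpha disc, km; `Inf` gives the convex
#'   hull.
#' @return Object of class `estuary_polygon`: list with `ring` (closed
#'   tibble of `x`, `y`), `area_km2`, `alongshore_km`, `offshore_km`,
#'   `method` ("alpha" or "convex").
#' @export
estuary_polygon <- function(xy, alpha_km = 15) {
  xy <- unique(as_xy_matrix(xy))
  if (nrow(xy) < 3) stop_bad_input("need at least 3 distinct points")
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2) {
    stop_bad_input("points are (nearly) collinear")
  }
  ring <- NULL
  method <- "alpha"
  if (is.finite(alpha_km)) {
    ring <- tryCatch(alpha_shape_ring(xy, alpha_km), error = function(e) NULL)
  }
  if (is.null(ring)) {
    if (is.finite(alpha_km)) {
      warning("alpha shape did not close into a single ring; falling back to the convex hull")
    }
    method <- "convex"
    idx <- grDevices::chull(xy)
    ring <- xy[c(idx, idx[1]), , drop = FALSE]
  }
  if (polygon_area(ring) < 1e-9) stop_bad_input("points are (nearly) collinear")
  structure(
    list(ring = tibble(x = ring[, 1], y = ring[, 2]),
         area_km2 = polygon_area(ring),
         alongshore_km = diff(range(xy[, 1])),
         offshore_km = max(xy[, 2]),
         method = method),
    class = "estuary_polygon"
  )
}

polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])) / 2
}

# Alpha-shape boundary: an edge (i, j) with |ij| <= 2r is on the boundary
# when at least one of the two radius-r discs through i and j contains no
# other point. Returns a closed ring matrix or errors if the boundary
# edges do not chain into one simple cycle.
alpha_shape_ring <- function(xy, r) {
  n <- nrow(xy)
  dmat <- as.matrix(stats::dist(xy))
  edges <- which(upper.tri(dmat) & dmat <= 2 * r & dmat > 0, arr.ind = TRUE)
  keep <- apply(edges, 1, function(e) {
    i <- e[1]; j <- e[2]
    p <- xy[i, ]; q <- xy[j, ]
    mid <- (p + q) / 2
    d <- sqrt(sum((q - p)^2))
    off <- sqrt(max(r^2 - (d / 2)^2, 0))
    nrm <- c(-(q - p)[2], (q - p)[1]) / d
    for (s in c(1, -1)) {
      ctr <- mid + s * off * nrm
      d2 <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2
      d2[c(i, j)] <- Inf
      if (min(d2) >= r^2 - 1e-9) return(TRUE)
    }
    FALSE
  })
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) < 3) stop("too few boundary edges")
  # every boundary vertex must have degree exactly 2 for a simple ring
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  verts <- which(deg > 0)
  if (any(deg[verts] != 2)) stop("boundary is not a simple cycle")
  adj <- lapply(seq_len(n), function(i) {
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
  })
  start <- verts[1]
  path <- c(start, adj[[start]][1])
  while (path[length(path)] != start) {
    cur <- path[length(path)]; prev <- path[length(path) - 1]
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) != 1) stop("boundary walk failed")
    path <- c(path, nxt)
    if (length(path) > n + 1) stop("boundary walk did not close")
  }
  if (length(path) - 1 != length(verts)) stop("multiple boundary components")
  xy[path, , drop = FALSE]
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("Utilization distribution: %d x %d grid, %.1f km cells, h = %.2f km, %d points\n",
              length(x$x), length(x$y), x$cell_km, x$h, x$n_points))
  invisible(x)
}
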