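#' Symmetric k-nearest-neighbor graph over ridge points
#'
#' Builds the weighted neighborhood graph that isometric mapping needs:
#' each point is connected to its `k` nearest neighbors (undirected union),
#' edge weights are Euclidean distances. Disconnected components are
#' reported in the `components` attribute.
#'
#' @param points a `ridge_points` data frame (or any data frame with `x`,
#'   `y`, `z`), at least 2 points.
#' @param k number of neighbors, >= 2.
#' @return an [igraph::graph] with vertex attributes `x`, `y`, `z`.
#' @export
build_neighbor_graph <- function(points, k = 8) {
  if (nrow(points) < 2) stop("need at least 2 points to build a graph")
  if (k < 2) stop("k must be >= 2")
  P <- as.matrix(points[, c("x", "y", "z")])
  n <- nrow(P)
  k_eff <- min(k, n - 1)
  edges <- vector("list", ceiling(n / 512))
  blk <- 1L
  for (s in seq(1, n, by = 512)) {
    e <- min(s + 511, n)
    # squared distances block x all
    D <- outer(rowSums(P[s:e, , drop = FALSE]^2), rowSums(P^2), "+") -
      2 * P[s:e, , drop = FALSE] %*% t(P)
    D[cbind(seq_len(e - s + 1), s:e)] <- Inf
    nn <- t(apply(D, 1, function(r) order(r)[seq_len(k_eff)]))
    edges[[blk]] <- cbind(rep(s:e, each = k_eff), as.vector(t(nn)))
    blk <- blk + 1L
  }
  ed <- do.call(rbind, edges)
  # undirected, deduplicated
  ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  w <- sqrt(rowSums((P[ed[, 1], , drop = FALSE] - P[ed[, 2], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(ed))
  igraph::E(g)$weight <- w
  igraph::V(g)$x <- P[, 1]; igraph::V(g)$y <- P[, 2]; igraph::V(g)$z <- P[, 3]
  comp <- igraph::components(g)
  attr(g, "components") <- comp
  if (comp$no > 1) {
    message(comp$no, " disconnected components in neighbor graph")
  }
  g
}

# deterministic argmax: largest value, ties broken by lexicographically
# smallest (x, y, z) coordinate
.argmax_lex <- function(val, P) {
  cand <- which(val == max(val))
  if (length(cand) > 1) {
    o <- order(P[cand, 1], P[cand, 2], P[cand, 3])
    cand <- cand[o]
  }
  cand[1]
}

#' Extract the principal curve from a ridge-point graph by isometric mapping
#'
#' Realizes the isometric-mapping step that links scattered ridge points into
#' one long continuous curve. Within the largest connected component, the
#' two points at maximal graph-geodesic distance are taken as endpoints;
#' every component point receives a 1D coordinate (its geodesic distance
#' from one endpoint -- a one-dimensional isometric embedding), points are
#' ordered by this coordinate, smoothed by a symmetric moving average of
#' `smoothing_span` ordered neighbors (endpoints fixed), and per-point
#' widths are carried over from the supporting ridge points (smoothed with
#' the same window). The alternative backend `"isomap"` orders points by the
#' first coordinate of the classical-scaling eigen-embedding of the geodesic
#' distance matrix; for tube-like clouds it must agree with the geodesic
#' ordering up to direction reversal.
#'
#' Paths are reported in the extracellular-to-intracellular direction
#' (decreasing Z).
#'
#' @param graph a [build_neighbor_graph()] result.
#' @param points the same ridge points the graph was built on (their `width`
#'   column, when present, supplies the path width profile).
#' @param smoothing_span moving-average window in points (odd, default 7).
#' @param backend `"geodesic"` (default) or `"isomap"`.
#' @param exact_diameter force exact all-pairs diameter search also on large
#'   components (default: exact up to 2500 vertices, then an iterated
#'   double-sweep heuristic).
#' @return a `permeation_path`: data frame with `arclength`, `x`, `y`, `z`,
#'   `width`; secondary components are kept in the `secondary` attribute.
#' @export
extract_principal_curve <- function(graph, points, smoothing_span = 7,
                                    backend = c("geodesic", "isomap"),
                                    exact_diameter = NULL) {
  backend <- match.arg(backend)
  comp <- attr(graph, "components") %||% igraph::components(graph)
  big <- which.max(comp$csize)
  vs <- which(comp$membership == big)
  if (length(vs) < 4) stop("largest component has fewer than 4 points; degenerate ridge set")
  P <- cbind(igraph::V(graph)$x, igraph::V(graph)$y, igraph::V(graph)$z)[vs, , drop = FALSE]
  sub <- igraph::induced_subgraph(graph, vs)
  n <- nrow(P)
  if (is.null(exact_diameter)) exact_diameter <- n <= 2500
  D <- NULL
  if (exact_diameter) {
    D <- igraph::distances(sub)
    rowmax <- apply(D, 1, max)
    a <- .argmax_lex(rowmax, P)
    b <- .argmax_lex(D[a, ], P)
    da <- D[a, ]
  } else {
    # iterated double sweep (exact on trees, near-exact on tube graphs)
    a <- .argmax_lex(P[, 3], P)  # deterministic start: topmost point
    for (it in 1:3) {
      da <- as.numeric(igraph::distances(sub, v = a))
      b <- .argmax_lex(da, P)
      db <- as.numeric(igraph::distances(sub, v = b))
      a2 <- .argmax_lex(db, P)
      if (identical(a2, a)) break
      a <- a2
    }
    da <- as.numeric(igraph::distances(sub, v = a))
    b <- .argmax_lex(da, P)
  }
  coord <- switch(backend,
    geodesic = da,
    isomap = {
      if (is.null(D)) D <- igraph::distances(sub)
      drop(stats::cmdscale(D, k = 1))
    })
  ord <- order(coord, P[, 1], P[, 2], P[, 3])
  Po <- P[ord, , drop = FALSE]
  w <- if ("width" %in% names(points)) points$width[vs][ord] else rep(NA_real_, n)
  # local average over groups of smoothing_span consecutive ordered points;
  # ridge voxels at nearly equal geodesic coordinate would otherwise
  # zig-zag transversely and inflate the arclength
  grp <- ceiling(seq_len(n) / max(1, smoothing_span))
  sm <- rowsum(Po, grp, reorder = TRUE) / as.vector(table(grp))
  wsm <- if (all(is.na(w))) rep(NA_real_, nrow(sm)) else
    as.vector(rowsum(w, grp, reorder = TRUE) / as.vector(table(grp)))
  # the curve terminates at the geodesic endpoints themselves
  sm <- rbind(Po[1, ], sm, Po[n, ])
  wsm <- c(w[1], wsm, w[n])
  sm <- .moving_average_rows(sm, 3)
  # drop zero-length steps so arclength is strictly increasing
  keep <- c(TRUE, rowSums(diff(sm)^2) > 1e-20)
  sm <- sm[keep, , drop = FALSE]
  wsm <- wsm[keep]
  # direction convention: extracellular (high Z) first
  if (sm[1, 3] < sm[nrow(sm), 3]) {
    sm <- sm[nrow(sm):1, , drop = FALSE]
    wsm <- rev(wsm)
  }
  seg <- sqrt(rowSums(diff(sm)^2))
  al <- c(0, cumsum(seg))
  out <- data.frame(arclength = al, x = sm[, 1], y = sm[, 2], z = sm[, 3],
                    width = wsm)
  secondary <- setdiff(seq_len(comp$no), big)
  structure(out,
            secondary = lapply(secondary, function(ci) {
              which(comp$membership == ci)
            }),
            endpoints = c(a, b), backend = backend,
            class = c("permeation_path", "data.frame"))
}

# symmetric moving average along rows; windows shrink symmetrically near the
# ends so the first and last rows are returned unchanged
.moving_average_rows <- function(M, span) {
  n <- nrow(M)
  if (span <= 1 || n < 3) return(M)
  half <- floor(span / 2)
  out <- M
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    if (h > 0) out[i, ] <- colMeans(M[(i - h):(i + h), , drop = FALSE])
  }
  out
}

#' @export
print.permeation_path <- function(x, ...) {
  cat(sprintf("permeation_path: %d points, length %.2f A, Z %.2f -> %.2f A\n",
              nrow(x), max(x$arclength), x$z[1], x$z[nrow(x)]))
  invisible(x)
}

#' Mean ridge width per arclength bin
#'
#' @param path a `permeation_path` with widths.
#' @param bin bin width along arclength in Angstrom, > 0.
#' @return data frame with `s_lo`, `s_hi`, `s_mid`, `mean_width`, `n`;
#'   bins containing no path points are absent from the output.
#' @export
path_width_profile <- function(path, bin = 1) {
  stopifnot(inherits(path, "permeation_path"))
  if (bin <= 0) stop("bin must be positive")
  if (all(is.na(path$width))) stop("path carries no widths")
  b <- floor(path$arclength / bin)
  ub <- sort(unique(b))
  mw <- vapply(ub, function(bb) mean(path$width[b == bb]), numeric(1))
  nn <- vapply(ub, function(bb) sum(b == bb), integer(1))
  data.frame(s_lo = ub * bin, s_hi = (ub + 1) * bin, s_mid = (ub + 0.5) * bin,
             mean_width = mw, n = nn)
}

#' Umbrella-sampling windows along a permeation path
#'
#' Divides the path evenly along the Z axis: window centers run from `z_hi`
#' down to `z_lo` at `spacing`, with additional extension windows from
#' `ext_hi` down to `ext_lo` prolonging the path into the bulk solution.
#' Each main window center is the path point at that Z (linear
#' interpolation); extension windows extrapolate along the path's end
#' tangent by default, or vertically with `extension = "vertical"`. The
#' cylindrical restraint radius of a window is the average ridge width
#' within `spacing / 2` in Z of its center (extension windows inherit the
#' width at the path end).
#'
#' @param path a `permeation_path` whose Z range covers `[z_lo, z_hi]`
#'   monotonically.
#' @param z_hi,z_lo main window center range in Angstrom (defaults 17.5 and
#'   5.5).
#' @param spacing center spacing in Angstrom (default 1).
#' @param ext_hi,ext_lo extension window range in Angstrom (defaults 22.5
#'   and 18.5); set to NULL to skip extensions.
#' @param extension `"tangent"` (default) or `"vertical"` extrapolation.
#' @return data frame with `index`, `center_z`, `x`, `y`, `z`, `radius`,
#'   `kind` ("main" or "extension"), ordered by decreasing Z.
#' @export
make_umbrella_windows <- function(path, z_hi = 17.5, z_lo = 5.5, spacing = 1,
                                  ext_hi = 22.5, ext_lo = 18.5,
                                  extension = c("tangent", "vertical")) {
  stopifnot(inherits(path, "permeation_path"))
  extension <- match.arg(extension)
  if (z_hi <= z_lo) stop("z_hi must be > z_lo")
  if (spacing <= 0) stop("spacing must be positive")
  z <- path$z
  # the path must cover the window range monotonically in Z
  rng <- range(z)
  if (rng[1] > z_lo || rng[2] < z_hi) {
    stop(sprintf("path Z range [%.2f, %.2f] does not span [%.2f, %.2f]",
                 rng[1], rng[2], z_lo, z_hi))
  }
  # monotonicity matters where windows are placed; wiggles at the path tips
  # outside the window range are irrelevant
  inwin <- which(z >= z_lo - spacing / 2 & z <= z_hi + spacing / 2)
  dz <- diff(z[inwin])
  if (any(dz > 1e-9) && any(dz < -1e-9)) {
    ref <- sign(dz[which(abs(dz) > 1e-9)[1]])
    bad <- which(sign(dz) != ref & abs(dz) > 1e-9)[1]
    stop(sprintf("path is not monotonic in Z near arclength %.2f A (Z %.2f -> %.2f)",
                 path$arclength[inwin[bad]], z[inwin[bad]], z[inwin[bad + 1]]))
  }
  # orient increasing in Z for interpolation
  o <- order(z)
  zi <- z[o]; xi <- path$x[o]; yi <- path$y[o]; wi <- path$width[o]
  centers_main <- seq(z_hi, z_lo, by = -spacing)
  interp <- function(zc, v) stats::approx(zi, v, xout = zc, ties = mean)$y
  main <- data.frame(center_z = centers_main,
                     x = interp(centers_main, xi),
                     y = interp(centers_main, yi),
                     z = centers_main, kind = "main")
  main$radius <- vapply(centers_main, function(zc) {
    sel <- abs(path$z - zc) <= spacing / 2
    if (!any(sel)) {
      interp(zc, wi)
    } else {
      mean(path$width[sel], na.rm = TRUE)
    }
  }, numeric(1))
  out <- main
  if (!is.null(ext_hi) && !is.null(ext_lo)) {
    if (ext_hi <= ext_lo) stop("ext_hi must be > ext_lo")
    centers_ext <- seq(ext_hi, ext_lo, by = -spacing)
    top <- which.max(path$z)
    p_top <- c(path$x[top], path$y[top], path$z[top])
    if (extension == "tangent") {
      nb <- order(abs(path$z - path$z[top]))[seq_len(min(5, nrow(path)))]
      fit_x <- stats::lm(path$x[nb] ~ path$z[nb])$coefficients
      fit_y <- stats::lm(path$y[nb] ~ path$z[nb])$coefficients
      ex <- fit_x[1] + fit_x[2] * centers_ext
      ey <- fit_y[1] + fit_y[2] * centers_ext
      if (anyNA(c(ex, ey))) { ex <- rep(p_top[1], length(centers_ext))
                              ey <- rep(p_top[2], length(centers_ext)) }
    } else {
      ex <- rep(p_top[1], length(centers_ext))
      ey <- rep(p_top[2], length(centers_ext))
    }
    w_end <- path$width[top]
    ext <- data.frame(center_z = centers_ext, x = ex, y = ey,
                      z = centers_ext, kind = "extension", radius = w_end)
    out <- rbind(ext, main)
  }
  out <- out[order(-out$center_z), ]
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("index", "center_z", "x", "y", "z", "radius", "kind")]
}
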