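## Mesh geometry: t-link thickness, heat-diffusion smoothing on the mesh
## graph, regional aggregation, and icosphere construction.

#' Cortical thickness between linked vertices
#'
#' The t-link thickness: Euclidean distance (mm) between vertex i of the
#' inner (WM/GM) surface and vertex i of the outer (GM/CSF) surface.
#'
#' @param pair a [SurfacePair-class].
#' @return A [VertexScalarMap-class] in mm, all values >= 0.
#' @export
linkThickness <- function(pair) {
  stopifnot(is(pair, "SurfacePair"))
  d <- vertices(outerSurface(pair)) - vertices(innerSurface(pair))
  VertexScalarMap(sqrt(rowSums(d * d)), units = "mm")
}

## Triangle areas, one per face.
.faceAreas <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Lumped (barycentric) vertex areas
#'
#' One third of the total area of the triangles incident to each vertex;
#' the diagonal mass matrix used by [diffusionSmooth()].
#'
#' @param mesh a [TriangleMesh-class].
#' @return Numeric vector of areas (mm^2), one per vertex.
#' @export
vertexAreas <- function(mesh) {
  f <- faces(mesh)
  fa <- .faceAreas(mesh)
  a <- numeric(nVertices(mesh))
  for (c in 1:3) {
    inc <- rowsum(fa, f[, c])
    idx <- as.integer(rownames(inc))
    a[idx] <- a[idx] + inc[, 1]
  }
  a / 3
}

## Cotangent edge weights as a sparse symmetric matrix W (w_ij = cot sum / 2).
.cotanWeights <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  cot_at <- function(a, b, c) {
    ## cotangent of the angle at vertex a in triangles (a, b, c)
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    dot / pmax(sqrt(cx^2 + cy^2 + cz^2), .Machine$double.eps)
  }
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  w <- 0.5 * c(cot_at(f[, 3], f[, 1], f[, 2]),
               cot_at(f[, 1], f[, 2], f[, 3]),
               cot_at(f[, 2], f[, 3], f[, 1]))
  n <- nVertices(mesh)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  Matrix::drop0(W)
}

#' Heat-diffusion smoothing of a vertex map
#'
#' Smooths a per-vertex scalar field by running the heat equation on the
#' mesh for total time \eqn{t = \mathrm{FWHM}^2 / (16 \ln 2)}, the standard
#' relation between a heat kernel's diffusion time and its full width at
#' half maximum. The Laplacian is cotangent-weighted with a lumped
#' (barycentric) vertex-area mass matrix, so the smoothing conserves the
#' area-weighted integral of the field; time stepping is explicit with the
#' step size bounded so every update is a convex combination of neighbor
#' values (discrete maximum principle on meshes with non-negative cotangent
#' weights).
#'
#' @param mesh the [TriangleMesh-class] carrying the field.
#' @param map a [VertexScalarMap-class] (or bare numeric vector) on `mesh`,
#'   all values finite.
#' @param fwhm kernel full width at half maximum in mm; 0 returns the input
#'   unchanged.
#' @return A [VertexScalarMap-class] of the same length and units.
#' @export
diffusionSmooth <- function(mesh, map, fwhm) {
  units <- "dimensionless"
  if (is(map, "VertexScalarMap")) { units <- mapUnits(map); map <- mapValues(map) }
  if (length(fwhm) != 1L || !is.finite(fwhm) || fwhm < 0)
    stop("fwhm must be a single non-negative number")
  if (length(map) != nVertices(mesh))
    stop(sprintf("map length %d does not match mesh vertex count %d",
                 length(map), nVertices(mesh)))
  if (any(!is.finite(map)))
    stop("diffusion smoothing requires finite values at every vertex")
  if (fwhm == 0) return(VertexScalarMap(map, units))

  t_total <- fwhm^2 / (16 * log(2))
  W <- .cotanWeights(mesh)
  m <- vertexAreas(mesh)
  s <- Matrix::rowSums(W)
  ## 0.25 x the positivity bound: keeps the convex-combination (maximum
  ## principle) property and keeps the first-order time-stepping error well
  ## below the kernel approximation tolerance
  dt_max <- 0.25 * min(m / pmax(s, .Machine$double.eps))
  nsteps <- max(10L, ceiling(t_total / dt_max))
  dt <- t_total / nsteps
  u <- map
  for (k in seq_len(nsteps)) {
    u <- u + (dt / m) * (as.numeric(W %*% u) - s * u)
  }
  VertexScalarMap(u, units)
}

#' Dense heat-kernel reference on a small mesh
#'
#' Exact matrix-exponential solution \eqn{\exp(-t M^{-1} L)} of the same
#' lumped cotangent heat equation that [diffusionSmooth()] time-steps,
#' computed by eigendecomposition of the symmetrized operator. Intended as
#' an independent reference on meshes of a few thousand vertices; cost is
#' cubic in the vertex count.
#'
#' @inheritParams diffusionSmooth
#' @return A [VertexScalarMap-class].
#' @export
heatKernelExact <- function(mesh, map, fwhm) {
  units <- "dimensionless"
  if (is(map, "VertexScalarMap")) { units <- mapUnits(map); map <- mapValues(map) }
  if (fwhm == 0) return(VertexScalarMap(map, units))
  t_total <- fwhm^2 / (16 * log(2))
  W <- as.matrix(.cotanWeights(mesh))
  L <- diag(rowSums(W)) - W
  m <- vertexAreas(mesh)
  ## symmetrize: S = M^-1/2 L M^-1/2; exp(-t M^-1 L) = M^-1/2 exp(-tS) M^1/2
  rm_ <- 1 / sqrt(m)
  S <- (rm_ * L) %*% diag(rm_)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  expS <- eig$vectors %*% (exp(-t_total * eig$values) * t(eig$vectors))
  u <- rm_ * as.numeric(expS %*% (sqrt(m) * map))
  VertexScalarMap(u, units)
}

#' Regional means of a vertex map
#'
#' Arithmetic mean of a per-vertex map over each labeled region. Unlabeled
#' vertices (region id 0) and flagged (NA) values are excluded. Regions in
#' the lexicon with no contributing vertices are omitted from the output
#' with a message. By default the mean is unweighted across vertices; set
#' `areaWeighted = TRUE` (and supply `mesh`) to weight by lumped vertex
#' area instead.
#'
#' @param map a [VertexScalarMap-class] (or numeric vector).
#' @param labels a [SurfaceLabelMap-class] on the same vertex set.
#' @param areaWeighted weight vertices by lumped area (default FALSE).
#' @param mesh the [TriangleMesh-class]; required when `areaWeighted`.
#' @return Named numeric vector, one mean per region name.
#' @export
regionalMean <- function(map, labels, areaWeighted = FALSE, mesh = NULL) {
  v <- if (is(map, "VertexScalarMap")) mapValues(map) else as.numeric(map)
  ids <- regionIds(labels)
  if (length(v) != length(ids))
    stop(sprintf("map length %d does not match label length %d",
                 length(v), length(ids)))
  wts <- if (areaWeighted) {
    if (is.null(mesh)) stop("areaWeighted = TRUE requires `mesh`")
    vertexAreas(mesh)
  } else rep(1, length(v))
  keep <- ids != 0L & !is.na(v)
  lex <- lexicon(labels)
  if (!any(keep)) {
    message("no labeled vertices with valid values; all regions omitted")
    return(stats::setNames(numeric(0), character(0)))
  }
  num <- rowsum((wts * v)[keep], ids[keep])
  den <- rowsum(wts[keep], ids[keep])
  out <- stats::setNames(as.numeric(num / den), lex[rownames(num)])
  empty <- setdiff(names(lex), rownames(num))
  if (length(empty))
    message(sprintf("regions with no contributing vertices omitted: %s",
                    paste(lex[empty], collapse = ", ")))
  out
}

#' Subdivided icosahedral sphere mesh
#'
#' A near-uniform triangulation of the sphere: a regular icosahedron whose
#' faces are recursively quadrisected, all vertices projected to the sphere.
#' Vertex counts by subdivision level: 12, 42, 162, 642, 2562, ...
#'
#' @param subdivisions non-negative integer subdivision level.
#' @param radius sphere radius in mm.
#' @param center length-3 center in mm.
#' @return A [TriangleMesh-class].
#' @export
icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    nv <- nrow(v)
    ## midpoint index for each undirected edge
    edges <- unique(rbind(
      cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
      cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
      cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))))
    key <- paste(edges[, 1], edges[, 2])
    mididx <- stats::setNames(nv + seq_len(nrow(edges)), key)
    mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    mkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m12 <- mididx[mkey(f[, 1], f[, 2])]
    m23 <- mididx[mkey(f[, 2], f[, 3])]
    m13 <- mididx[mkey(f[, 1], f[, 3])]
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m13, m23),
               cbind(m12, m23, m13))
  }
  TriangleMesh(sweep(v * radius, 2, center, "+"), f)
}
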