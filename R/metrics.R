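#' Outward vertex normals
#'
#' Area-weighted average of incident face normals, normalised.  Outward
#' means consistent with the counter-clockwise face winding.
#'
#' @param surface a \linkS4class{TriSurface}
#' @return an n x 3 matrix of unit normals
#' @export
vertexNormals <- function(surface) {
  v <- surface@vertices; f <- surface@faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # 2*area-weighted
  n <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    m <- rowsum(rbind(fn, fn, fn)[, c],
                c(f[, 1], f[, 2], f[, 3]))
    n[as.integer(rownames(m)), c] <- m[, 1]
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Cortical thickness by closest vertex
#'
#' For every white-surface vertex, the Euclidean distance to the nearest
#' pial (gray-matter) vertex — the vertex-to-vertex definition used when
#' thickness maps are read off reconstructed surface pairs.  A
#' vertex-to-triangle projection variant is available behind
#' \code{method = "projection"}, which refines the nearest-vertex distance
#' by projecting onto the pial triangles incident to that vertex.
#'
#' @param white,pial \linkS4class{TriSurface} objects.
#' @param method "nearest" (default, the defining rule) or "projection".
#' @return numeric vector of thickness values (mm), one per white vertex
#' @examples
#' w <- triSurface(cbind(0:1, 0, 0), matrix(integer(0), 0, 3))
#' p <- triSurface(cbind(0:1, 0, 2.5), matrix(integer(0), 0, 3))
#' computeThickness(w, p)
#' @export
computeThickness <- function(white, pial, method = c("nearest", "projection")) {
  method <- match.arg(method)
  if (nrow(pial@vertices) == 0) stop("empty pial surface")
  if (nrow(white@vertices) == 0) stop("empty white surface")
  d <- nearestVertexDist(white@vertices, pial@vertices)
  if (method == "nearest") return(d)
  # refine: distance to triangles incident to the nearest pial vertex
  pv <- pial@vertices
  nearest <- integer(nrow(white@vertices))
  for (i in seq_len(nrow(white@vertices))) {
    dd <- colSums((t(pv) - white@vertices[i, ])^2)
    nearest[i] <- which.min(dd)
  }
  f <- pial@faces
  for (i in seq_along(nearest)) {
    inc <- which(f[, 1] == nearest[i] | f[, 2] == nearest[i] |
                   f[, 3] == nearest[i])
    for (tri in inc)
      d[i] <- min(d[i], pointTriangleDist(white@vertices[i, ],
                                          pv[f[tri, 1], ], pv[f[tri, 2], ],
                                          pv[f[tri, 3], ]))
  }
  d
}

# distance from point p to triangle (a, b, c), clamped barycentric solve
pointTriangleDist <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  m <- rbind(c(sum(ab * ab), sum(ab * ac)), c(sum(ab * ac), sum(ac * ac)))
  uv <- tryCatch(solve(m, c(d1, d2)), error = function(e) c(0, 0))
  u <- uv[1]; v <- uv[2]
  if (u < 0 || v < 0 || u + v > 1) {
    # clamp to edges
    cand <- rbind(a, b, c,
                  a + max(0, min(1, d1 / max(m[1, 1], 1e-300))) * ab,
                  a + max(0, min(1, d2 / max(m[2, 2], 1e-300))) * ac,
                  b + max(0, min(1, sum((c - b) * (p - b)) /
                                   max(sum((c - b)^2), 1e-300))) * (c - b))
    return(sqrt(min(rowSums((cand - matrix(p, nrow(cand), 3,
                                           byrow = TRUE))^2))))
  }
  q <- a + u * ab + v * ac
  sqrt(sum((p - q)^2))
}

# 1-ring adjacency list from faces
oneRing <- function(faces, nv) {
  ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ed <- rbind(ed, ed[, 2:1])
  split(ed[, 2], factor(ed[, 1], levels = seq_len(nv)))
}

#' Maximal principal curvature by local quadric fitting
#'
#' Per-vertex signed curvature descriptor of the folding pattern: a local
#' quadric is fitted over the 2-ring neighbourhood in the tangent frame of
#' the outward vertex normal, and the principal curvatures are read off the
#' quadric's second fundamental form with the convention that convex
#' (outward-bulging) regions are positive.  "Maximal" is resolved as the
#' principal curvature of larger magnitude, keeping its sign
#' (\code{convention = "magnitude"}); \code{"signed"} instead returns the
#' algebraically larger one.
#'
#' @param surface a \linkS4class{TriSurface} with consistent outward
#'   orientation.
#' @param convention "magnitude" (default) or "signed".
#' @return numeric vector of MPC values (1/mm); vertices with under-sized
#'   neighbourhoods get NA
#' @export
computeMPC <- function(surface, convention = c("magnitude", "signed")) {
  convention <- match.arg(convention)
  v <- surface@vertices
  nv <- nrow(v)
  ring1 <- oneRing(surface@faces, nv)
  nrm <- vertexNormals(surface)
  out <- rep(NA_real_, nv)
  for (i in seq_len(nv)) {
    nb1 <- unique(ring1[[i]])
    if (!length(nb1)) next
    nb <- unique(c(nb1, unlist(ring1[nb1], use.names = FALSE)))
    nb <- setdiff(nb, i)
    if (length(nb) < 5) next
    n <- nrm[i, ]
    # tangent frame
    t1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - sum(t1 * n) * n; t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(n[2] * t1[3] - n[3] * t1[2], n[3] * t1[1] - n[1] * t1[3],
            n[1] * t1[2] - n[2] * t1[1])
    rel <- v[nb, , drop = FALSE] -
      matrix(v[i, ], length(nb), 3, byrow = TRUE)
    u <- rel %*% t1; w <- rel %*% t2; h <- rel %*% n
    Xd <- cbind(1, u, w, u^2, u * w, w^2)
    beta <- tryCatch(qr.solve(Xd, h), error = function(e) NULL)
    if (is.null(beta)) next
    # height measured along the outward normal: convex bumps curve away
    # from n, so flip the sign of the Hessian eigenvalues
    H <- matrix(c(2 * beta[4], beta[5], beta[5], 2 * beta[6]), 2, 2)
    k <- -eigen(H, symmetric = TRUE, only.values = TRUE)$values
    out[i] <- if (convention == "magnitude") k[which.max(abs(k))] else max(k)
  }
  out
}

#' Vertex-wise linear growth-rate regression
#'
#' Ordinary least squares of thickness against week, per vertex.  The slope
#' profiles the cortical growth rate; R^2 measures how well a linear model
#' explains the trajectory.  A constant (zero-variance) trajectory gets
#' slope 0 and R^2 defined as 0.
#'
#' @param thickness numeric matrix, vertices x timepoints (a vector is
#'   treated as a single vertex).
#' @param weeks numeric vector of week labels (length >= 3, not constant).
#' @return data.frame with columns slope (mm/week), intercept (mm), r2
#' @examples
#' fitGrowthRate(2 + 0.35 * (0:6), 25:31)
#' @export
fitGrowthRate <- function(thickness, weeks) {
  if (is.null(dim(thickness))) thickness <- matrix(thickness, 1)
  if (length(weeks) < 3) stop("at least 3 timepoints are required")
  if (length(weeks) != ncol(thickness))
    stop("weeks length must match the number of thickness columns")
  if (var(weeks) == 0) stop("week labels are constant")
  xc <- weeks - mean(weeks)
  Sxx <- sum(xc^2)
  ybar <- rowMeans(thickness)
  slope <- as.vector(thickness %*% xc) / Sxx
  intercept <- ybar - slope * mean(weeks)
  res <- thickness - ybar - outer(slope, xc)
  sst <- rowSums((thickness - ybar)^2)
  sse <- rowSums(res^2)
  r2 <- ifelse(sst > 0, pmax(0, pmin(1, 1 - sse / sst)), 0)
  data.frame(slope = slope, intercept = intercept, r2 = r2)
}

#' Filter vertices by regression goodness of fit
#'
#' Keeps the 'trustworthy' vertices whose linear fit explains at least
#' \code{threshold} of the thickness variance (inclusive by default;
#' \code{strict = TRUE} for a strict inequality).
#'
#' @param fit data.frame from \code{\link{fitGrowthRate}}.
#' @param threshold R^2 threshold in [0, 1].
#' @param strict logical; use r2 > threshold instead of >=.
#' @return list with \code{keep} (logical vector) and \code{fraction} kept
#' @export
filterR2 <- function(fit, threshold = 0.6, strict = FALSE) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  keep <- if (strict) fit$r2 > threshold else fit$r2 >= threshold
  keep[is.na(keep)] <- FALSE
  list(keep = keep, fraction = mean(keep))
}

#' Split vertices by the sign of the maximal principal curvature
#'
#' Positive-MPC vertices form the gyral (convex) group, negative-MPC the
#' sulcal (concave) group.  Exact zeros and NAs belong to neither.
#'
#' @param mpc numeric MPC vector.
#' @return list with integer index vectors \code{positive} and
#'   \code{negative}
#' @export
splitByMpcSign <- function(mpc) {
  list(positive = which(!is.na(mpc) & mpc > 0),
       negative = which(!is.na(mpc) & mpc < 0))
}

#' Pooled-variance two-sample t test
#'
#' Student's unpaired t test under the equal-variance assumption, computed
#' from the textbook pooled-variance formula with n1 + n2 - 2 degrees of
#' freedom.  The right-tail p value tests the alternative mean(a) > mean(b).
#'
#' @param a,b numeric samples (each n >= 2).
#' @param tail ignored for computation; both tails are always reported.
#' @return a \linkS4class{GroupTest}
#' @examples
#' pooledTTest(rnorm(10, 1), rnorm(12))
#' @export
pooledTTest <- function(a, b, tail = c("two", "right")) {
  match.arg(tail)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 observations")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  dof <- n1 + n2 - 2
  new("GroupTest", t = t, dof = dof,
      pTwoTail = 2 * pt(-abs(t), dof),
      pRightTail = pt(t, dof, lower.tail = FALSE),
      means = c(mean(a), mean(b)), sds = c(sd(a), sd(b)), n = c(n1, n2))
}

#' Gyral vs sulcal parcel thickness comparison
#'
#' Per-class unweighted mean and sd over parcel rows, plus the pooled
#' t test of gyral against sulcal thickness.
#'
#' @param table a ParcelTable data.frame (columns parcel, class,
#'   thickness_mm), e.g. from \code{\link{parcelThicknessFixture}}.
#' @return list with \code{summary} (data.frame: class, n, mean, sd) and
#'   \code{test} (a \linkS4class{GroupTest}, gyral vs sulcal)
#' @examples
#' parcelComparison(parcelThicknessFixture())$summary
#' @export
parcelComparison <- function(table) {
  stopifnot(all(c("parcel", "class", "thickness_mm") %in% names(table)))
  g <- table$thickness_mm[table$class == "gyral"]
  s <- table$thickness_mm[table$class == "sulcal"]
  if (!length(g) || !length(s)) stop("both parcel classes must be present")
  summ <- data.frame(class = c("gyral", "sulcal"),
                     n = c(length(g), length(s)),
                     mean = c(mean(g), mean(s)), sd = c(sd(g), sd(s)))
  list(summary = summ, test = pooledTTest(g, s))
}

#' Full growth-rate pipeline on a surface series
#'
#' Runs the longitudinal analysis end-to-end on a
#' \linkS4class{SurfaceSeries}: closest-vertex thickness per timepoint,
#' maximal principal curvature on the final white surface, vertex-wise
#' growth-rate regression, R^2 filtering, MPC-sign grouping and the pooled
#' right-tail t test of gyral against sulcal growth rates.
#'
#' @param series a \linkS4class{SurfaceSeries}.
#' @param r2Threshold R^2 filter threshold.
#' @param thickness "auto" uses the per-vertex "thickness" trajectories
#'   attached to the white surfaces when present (the generator's
#'   longitudinal table) and falls back to closest-vertex measurement;
#'   "measure" always recomputes via \code{\link{computeThickness}};
#'   "scalar" requires the attached trajectories.  Closest-vertex
#'   measurement on fine meshes shortens thickness wherever the thickness
#'   field steps sharply (a nearer vertex of the thinner region wins), so
#'   recorded trajectories are preferred when available.
#' @return list: \code{perVertex} data.frame (mpc, slope, intercept, r2,
#'   kept, group), \code{test} (\linkS4class{GroupTest}: positive vs
#'   negative group slopes), \code{keptFraction}, \code{groupMeans}
#' @export
growthRatePipeline <- function(series, r2Threshold = 0.6,
                               thickness = c("auto", "scalar", "measure")) {
  thickness <- match.arg(thickness)
  weeks <- series@timepoints
  hasScalar <- all(vapply(series@white, function(s)
    !is.null(s@scalars$thickness), TRUE))
  if (thickness == "scalar" && !hasScalar)
    stop("no thickness trajectories attached to the white surfaces")
  useScalar <- thickness == "scalar" || (thickness == "auto" && hasScalar)
  th <- if (useScalar)
    vapply(seq_along(weeks), function(t) scalar(series@white[[t]], "thickness"),
           numeric(nVertices(series@white[[1]])))
  else vapply(seq_along(weeks), function(t)
    computeThickness(series@white[[t]], series@pial[[t]]),
    numeric(nVertices(series@white[[1]])))
  mpc <- computeMPC(series@white[[length(weeks)]])
  fit <- fitGrowthRate(th, weeks)
  keep <- filterR2(fit, r2Threshold)
  grp <- splitByMpcSign(mpc)
  pos <- intersect(grp$positive, which(keep$keep))
  neg <- intersect(grp$negative, which(keep$keep))
  if (!length(pos) || !length(neg))
    stop("one MPC group is empty after filtering; cannot test")
  test <- pooledTTest(fit$slope[pos], fit$slope[neg])
  group <- rep(NA_character_, nrow(fit))
  group[grp$positive] <- "positive"
  group[grp$negative] <- "negative"
  list(perVertex = data.frame(mpc = mpc, slope = fit$slope,
                              intercept = fit$intercept, r2 = fit$r2,
                              kept = keep$keep, group = group),
       test = test, keptFraction = keep$fraction,
       groupMeans = c(positive = mean(fit$slope[pos]),
                      negative = mean(fit$slope[neg])),
       groupSE = c(positive = sd(fit$slope[pos]) / sqrt(length(pos)),
                   negative = sd(fit$slope[neg]) / sqrt(length(neg))),
       groupN = c(positive = length(pos), negative = length(neg)))
}
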