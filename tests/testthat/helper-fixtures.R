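# Shared fixtures, all generated in code.

# A delta truth with depth and SST active (the recovery benchmark truth).
truthDepthSst <- function() {
  defineSpeciesTruth("recov",
    occurrenceShapes = list(
      depth = list(type = "logistic", midpoint = 450, rate = -0.012),
      sst = list(type = "gaussian", center = 19.5, width = 1.6)),
    abundanceShapes = list(
      depth = list(type = "logistic", midpoint = 400, rate = -0.008),
      sst = list(type = "gaussian", center = 19.5, width = 2)),
    pMax = 0.85, muMax = 50, dispersion = 1)
}

# A constant-probability truth with no predictor effects (pure noise).
truthNoise <- function(p = 0.4) {
  defineSpeciesTruth("noise", pMax = p, muMax = 20, dispersion = 1)
}

# 900-haul survey from the depth+SST truth on a 64x64 seascape.
recoverySurvey <- function(seed) {
  env <- generateEnvironment(64, 64, 866, seed = seed)
  sv <- simulateSurvey(env, truthDepthSst(), surveyDesign(nStations = 100),
                       nYears = 9, seed = seed + 100)
  list(env = env, survey = sv)
}

# Small random depth raster for terrain oracles.
randomDepth <- function(nr, nc, seed, base = 200, amp = 40) {
  set.seed(seed)
  matrix(base + amp * rnorm(nr * nc), nr, nc)
}

# Independent Horn-stencil slope recomputation for one interior cell.
hornSlopeOracle <- function(z, r, c, cellSize) {
  dzdx <- ((z[r - 1, c + 1] + 2 * z[r, c + 1] + z[r + 1, c + 1]) -
             (z[r - 1, c - 1] + 2 * z[r, c - 1] + z[r + 1, c - 1])) /
    (8 * cellSize)
  dzdy <- ((z[r + 1, c - 1] + 2 * z[r + 1, c] + z[r + 1, c + 1]) -
             (z[r - 1, c - 1] + 2 * z[r - 1, c] + z[r - 1, c + 1])) /
    (8 * cellSize)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

# Independent triangulated surface-area computation over a 3x3 window:
# split each of the four unit cells into two triangles, sum their areas
# from the 3D cross product.
areaRatioOracle <- function(z, r, c, cellSize) {
  w <- z[(r - 1):(r + 1), (c - 1):(c + 1)]
  triArea3 <- function(a, b, d) {
    u <- b - a; v <- d - a
    0.5 * sqrt(sum(c(u[2] * v[3] - u[3] * v[2],
                     u[3] * v[1] - u[1] * v[3],
                     u[1] * v[2] - u[2] * v[1])^2))
  }
  surf <- 0
  for (i in 1:2) for (j in 1:2) {
    p00 <- c(0, 0, w[i, j]); p01 <- c(cellSize, 0, w[i, j + 1])
    p10 <- c(0, cellSize, w[i + 1, j])
    p11 <- c(cellSize, cellSize, w[i + 1, j + 1])
    surf <- surf + triArea3(p00, p01, p10) + triArea3(p01, p11, p10)
  }
  1 - (2 * cellSize)^2 / surf
}

# Brute-force AUC: pairwise concordance over all positive x negative pairs.
aucOracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Gaussian random field at scattered points with spherical covariance.
sphericalFieldFactory <- function(coords, range, sill = 1) {
  D <- as.matrix(dist(coords))
  C <- ifelse(D < range, sill * (1 - 1.5 * D / range + 0.5 * (D / range)^3),
              0)
  L <- chol(C + diag(1e-8, nrow(coords)))
  function() as.numeric(crossprod(L, rnorm(nrow(coords))))
}
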