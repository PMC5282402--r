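# Internal geometry helpers shared across modules.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n == 0) stop("zero-length vector has no direction")
  v / n
}

# Angle between two vectors in degrees, in [0, 180].
.angleDeg <- function(v1, v2) {
  ct <- sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

# Fold an angle between two undirected axes to [0, 90] degrees.
.foldAngle <- function(theta) ifelse(theta > 90, 180 - theta, theta)

# Least-squares plane through a point cloud: centroid, unit normal
# (eigenvector of the smallest principal moment) and RMS out-of-plane
# deviation.  Sign of the normal is made deterministic (largest-magnitude
# component positive) so results do not depend on member order.
.planeFit <- function(coords) {
  centroid <- colMeans(coords)
  centred <- sweep(coords, 2, centroid)
  ev <- eigen(crossprod(centred), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  k <- which.max(abs(normal))
  if (normal[k] < 0) normal <- -normal
  dev <- as.numeric(centred %*% normal)
  list(centroid = centroid, normal = normal, rms = sqrt(mean(dev^2)))
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Coordinate matrix accessor used throughout: n x 3 matrix in file order.
.xyz <- function(structure) {
  a <- structure@atoms
  cbind(a$x, a$y, a$z)
}
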