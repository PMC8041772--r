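# Independent reference implementations used as oracles. These deliberately
# take different routes than the package code they check.

# dihedral via explicit plane normals and a determinant for the sign
ref_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(p2 - p1, p3 - p2)
  n2 <- cross(p3 - p2, p4 - p3)
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  ang <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  # sign from the scalar triple product of n1, n2 and the central bond
  s <- sign(det(rbind(n1, n2, (p3 - p2))))
  if (s == 0) s <- 1
  wrapAngle(s * ang)
}

# fixed-step RK4 integration of the kinetic scheme, independent of deSolve
ref_rk4_progress <- function(params, e0, s0, times, nsub = 10) {
  rhs <- function(y) {
    S <- max(s0 - 2 * y[1], 0)
    A <- e0 - y[2]
    f <- (S / (Kd(params) + S))^2
    P <- max(y[1] - y[2], 0)
    c(kcat(params) * A * f, kon(params) * P * A - koff(params) * y[2])
  }
  y <- c(0, 0)
  out <- matrix(NA_real_, length(times), 2)
  out[1, ] <- y
  for (i in seq_len(length(times) - 1)) {
    h <- (times[i + 1] - times[i]) / nsub
    for (k in seq_len(nsub)) {
      k1 <- rhs(y); k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2); k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1, ] <- y
  }
  list(psyn = out[, 1], inhibited = out[, 2])
}

# all-pairs minimum heavy-atom distance contact scan, O(n^2) loops
ref_contacts <- function(atomsA, atomsB, cutoff) {
  res <- list()
  for (ra in unique(atomsA$resno)) {
    for (rb in unique(atomsB$resno)) {
      xa <- atomsA[atomsA$resno == ra, c("x", "y", "z"), drop = FALSE]
      xb <- atomsB[atomsB$resno == rb, c("x", "y", "z"), drop = FALSE]
      dmin <- Inf
      for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb)))
        dmin <- min(dmin, sqrt(sum((as.numeric(xa[i, ]) -
                                      as.numeric(xb[j, ]))^2)))
      if (dmin <= cutoff)
        res[[length(res) + 1]] <- data.frame(resnoA = ra, resnoB = rb,
                                             dist = dmin)
    }
  }
  if (!length(res))
    return(data.frame(resnoA = integer(0), resnoB = integer(0),
                      dist = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$resnoA, out$resnoB), , drop = FALSE]
}

# gap-free percent identity for substitution-only sequence pairs
ref_hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

# random rigid transform applied to an n x 3 coordinate matrix
random_rigid <- function(coords, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- dgcswitch:::.rotationMatrix(ax, runif(1, 0, 360))
  sweep(coords %*% t(R), 2, rnorm(3, 0, 10), "+")
}
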