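# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (all-pairs distances, scalar loops) so they share no code
# path with the package internals they check.

# squared physical distance from every voxel to the nearest foreground voxel
brute_d2 <- function(mask) {
  shp <- dim(mask$data)
  sp <- mask$spacing
  fg <- which(mask$data, arr.ind = TRUE)
  best <- rep(Inf, prod(shp))
  if (nrow(fg) > 0) {
    all_idx <- arrayInd(seq_len(prod(shp)), shp)
    P <- sweep(all_idx - 1, 2, sp, `*`)
    F <- sweep(fg - 1, 2, sp, `*`)
    for (m in seq_len(nrow(F))) {
      dd <- (P[, 1] - F[m, 1])^2 + (P[, 2] - F[m, 2])^2 + (P[, 3] - F[m, 3])^2
      best <- pmin(best, dd)
    }
  }
  array(best, shp)
}

brute_dilate <- function(mask, tol) {
  binary_volume(brute_d2(mask) <= tol^2, spacing = mask$spacing)
}

brute_overlap <- function(pred, gt, tol) {
  p <- pred$data; g <- gt$data
  list(tp = sum(p & g), fp = sum(p & !g), fn = sum(g & !p),
       fp_tau = sum(p & !(brute_d2(gt) <= tol^2)),
       fn_tau = sum(g & !(brute_d2(pred) <= tol^2)))
}

# sparse random mask (sometimes empty) on a small grid
random_mask <- function(shape, spacing, p = 0.05) {
  binary_volume(array(runif(prod(shape)) < p, shape), spacing = spacing)
}

# ball at a voxel index with a physical radius, for constructed fixtures
fixture_ball <- function(shape, spacing, centre_vox, radius_mm) {
  idx <- arrayInd(seq_len(prod(shape)), shape)
  P <- sweep(idx - 1, 2, spacing, `*`)
  c_mm <- (centre_vox - 1) * spacing
  d2 <- (P[, 1] - c_mm[1])^2 + (P[, 2] - c_mm[2])^2 + (P[, 3] - c_mm[3])^2
  binary_volume(array(d2 <= radius_mm^2, shape), spacing = spacing)
}

# scalar reference for the Conover unreplicated-blocked post hoc, written in
# the textbook notation (A1, C1, tie-corrected T2, t on (n-1)(k-1) df)
conover_reference <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- matrix(0, n, k)
  for (i in seq_len(n)) R[i, ] <- rank(mat[i, ])
  Rj <- colSums(R)
  A1 <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) A1 <- A1 + R[i, j]^2
  C1 <- n * k * (k + 1)^2 / 4
  T2 <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A1 - C1)
  df <- (n - 1) * (k - 1)
  denom <- sqrt(2 * n * (A1 - C1) / df * (1 - T2 / (n * (k - 1))))
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    t <- abs(Rj[i] - Rj[j]) / denom
    p[i, j] <- 2 * stats::pt(t, df, lower.tail = FALSE)
  }
  list(T2 = T2, p = p)
}

# small ready-made anisotropic grid
aniso <- function(shape = c(12, 12, 6)) {
  binary_volume(array(FALSE, shape), spacing = c(0.5, 0.5, 2.5))
}
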