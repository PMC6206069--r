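# Independent numerical oracles used to check the analytic implementations.

# --- SO(3)-quadrature density-overlap kernel --------------------------------
# k(A, B) = int_SO(3) |sum_s <rho_s^A, rho_s^B o R>|^2 dR, evaluated with
# closed-form Gaussian-Gaussian overlaps per rotation and Euler-angle
# quadrature (trapezoid in alpha/gamma, Gauss-Legendre in cos beta). This is
# the defining rotational average that the power-spectrum dot product
# reproduces, computed without any basis expansion.

overlap_at_rotation <- function(envA, envB, sigma2, smooth, R) {
  tot <- 0
  wA <- soapshift:::cutoff_weight(envA$r, envA$r_c, smooth)
  wB <- soapshift:::cutoff_weight(envB$r, envB$r_c, smooth)
  for (s in unique(c(envA$species, envB$species))) {
    ia <- which(envA$species == s); ib <- which(envB$species == s)
    if (!length(ia) || !length(ib)) next
    A <- envA$disp[ia, , drop = FALSE]
    B <- envB$disp[ib, , drop = FALSE] %*% t(R)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    tot <- tot + sum((wA[ia] %o% wB[ib]) * exp(-d2 / (4 * sigma2)))
  }
  tot * (pi * sigma2)^1.5
}

so3_kernel_raw <- function(envA, envB, sigma2, smooth, na = 24, nb = 18) {
  gl <- pracma::gaussLegendre(nb, -1, 1)
  angs <- 2 * pi * (0:(na - 1)) / na
  tot <- 0
  for (ib in seq_len(nb)) {
    beta <- acos(gl$x[ib])
    cb <- cos(beta); sb <- sin(beta)
    ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    for (a in angs) for (g in angs) {
      rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                    3, 3, byrow = TRUE)
      rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1),
                    3, 3, byrow = TRUE)
      tot <- tot + gl$w[ib] * (2 * pi / na)^2 *
        overlap_at_rotation(envA, envB, sigma2, smooth, rz1 %*% ry %*% rz2)^2
    }
  }
  tot
}

so3_kernel <- function(a, b, sigma2, smooth, ...) {
  so3_kernel_raw(a, b, sigma2, smooth, ...) /
    sqrt(so3_kernel_raw(a, a, sigma2, smooth, ...) *
           so3_kernel_raw(b, b, sigma2, smooth, ...))
}

# --- brute-force periodic neighbor enumeration ------------------------------
# exhaustive image search over a [-k, k]^3 block, independent of the
# plane-spacing-based image bound used by the package
brute_force_neighbors <- function(structure, center, r_c, k = 5) {
  pos <- soapshift:::wrap_positions(structure)
  out <- list()
  for (j in seq_len(nrow(pos)))
    for (a in -k:k) for (b in -k:k) for (cc in -k:k) {
      d <- pos[j, ] + c(a, b, cc) %*% structure$cell - pos[center, ]
      if (sqrt(sum(d^2)) <= r_c + 1e-9)
        out[[length(out) + 1]] <- list(species = structure$species[j],
                                       d = as.numeric(d))
    }
  out
}

# sorted multiset signature of a neighbor list, for order-free comparison
neighbor_signature <- function(species, disp, digits = 8) {
  r <- sqrt(rowSums(disp^2))
  paste(species, formatC(r, digits = digits, format = "f"))
}
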