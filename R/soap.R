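# SOAP power-spectrum descriptors and normalized similarity kernels.
#
# An environment's neighbor density is a superposition of Gaussians of
# variance sigma2, one per neighbor (self included), weighted by a smooth
# cutoff function, with a separate density channel per species. The density
# is expanded in an orthonormal radial basis times real spherical harmonics;
# contracting the expansion coefficients over the angular index m gives the
# rotationally invariant power spectrum, which is normalized to unit length
# so that the similarity kernel k = (p . p')^zeta lies in [0, 1].

#' SOAP descriptor parameters
#'
#' @param sigma2 variance of the atom-centered Gaussians, in Angstrom^2
#'   (default 0.16, i.e. a width of 0.4 Angstrom).
#' @param n_max number of radial basis functions (default 8).
#' @param l_max angular momentum truncation (default 6).
#' @param zeta kernel exponent, a positive integer (default 2).
#' @param smooth_width width in Angstrom of the cosine taper that takes the
#'   cutoff function from 1 to 0 at r_c (default 0.5; 0 gives a hard cutoff).
#' @param species fixed, ordered species channels. Absent species contribute
#'   zero blocks, keeping the descriptor length constant across structures.
#' @param n_quad Gauss-Legendre nodes used for the radial integrals.
#' @param basis_width width of each radial Gaussian basis function relative
#'   to the spacing of their centers.
#' @return An object of class `soap_params`.
#' @export
soap_params <- function(sigma2 = 0.16, n_max = 8L, l_max = 6L, zeta = 2L,
                        smooth_width = 0.5, species = ALLOWED_SPECIES,
                        n_quad = 50L, basis_width = 0.8) {
  stopifnot(sigma2 > 0, n_max >= 1L, l_max >= 0L, zeta >= 1L,
            smooth_width >= 0, n_quad >= 10L, basis_width > 0)
  structure(list(sigma2 = sigma2, n_max = as.integer(n_max),
                 l_max = as.integer(l_max), zeta = as.integer(zeta),
                 smooth_width = smooth_width, species = species,
                 n_quad = as.integer(n_quad), basis_width = basis_width),
            class = "soap_params")
}

params_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0)) ||
    identical(unclass(a), unclass(b))
}

#' Multi-cutoff kernel combination
#'
#' The combined kernel is the weighted average of single-cutoff kernels,
#' K = sum_t w_t K_t / sum_t w_t; dividing by the weight sum keeps the
#' self-similarity of identical environments equal to 1. The default ladder
#' uses cutoffs 2-7 Angstrom with weights 256, 128, 32, 8, 8, 1.
#'
#' @param cutoffs strictly increasing cutoff radii in Angstrom.
#' @param weights positive weights, one per cutoff.
#' @return An object of class `multiscale_spec`.
#' @export
multiscale_spec <- function(cutoffs = c(2, 3, 4, 5, 6, 7),
                            weights = c(256, 128, 32, 8, 8, 1)) {
  if (length(cutoffs) != length(weights) || !length(cutoffs))
    stop("cutoffs and weights must be non-empty and of equal length")
  if (any(diff(cutoffs) <= 0)) stop("cutoffs must be strictly increasing")
  if (any(weights <= 0)) stop("weights must be positive")
  structure(list(cutoffs = as.numeric(cutoffs),
                 weights = as.numeric(weights)),
            class = "multiscale_spec")
}

#' @export
print.multiscale_spec <- function(x, ...) {
  cat("<multiscale_spec> ",
      paste(sprintf("%g A (w=%g)", x$cutoffs, x$weights), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# smooth cutoff: 1 in the interior, cosine taper over the last smooth_width.
cutoff_weight <- function(r, r_c, w) {
  if (w <= 0) return(as.numeric(r <= r_c))
  out <- numeric(length(r))
  out[r <= r_c - w] <- 1
  mid <- r > r_c - w & r <= r_c
  out[mid] <- 0.5 * (1 + cos(pi * (r[mid] - (r_c - w)) / w))
  out
}

# ---- radial basis ----------------------------------------------------------

.soap_cache <- new.env(parent = emptyenv())

# Gaussians centered on [r_c/n_max, r_c], orthonormalized on [0, r_c] under
# the r^2 measure via the inverse square root of their overlap matrix.
# Returns quadrature nodes/weights and the orthonormal basis values at nodes.
radial_basis <- function(r_c, n_max, n_quad, basis_width) {
  key <- paste(r_c, n_max, n_quad, basis_width, sep = "|")
  hit <- .soap_cache[[key]]
  if (!is.null(hit)) return(hit)
  gl <- pracma::gaussLegendre(n_quad, 0, r_c)
  xq <- gl$x; wq <- gl$w
  centers <- seq(r_c / n_max, r_c, length.out = n_max)
  sg <- basis_width * (r_c / n_max)
  phi <- exp(-outer(xq, centers, "-")^2 / (2 * sg^2))
  s <- t(phi * (wq * xq^2)) %*% phi
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  if (min(e$values) < 1e-13 * max(e$values))
    stop("radial basis is numerically dependent; reduce n_max or basis_width")
  g <- phi %*% (e$vectors %*% (t(e$vectors) / sqrt(e$values)))
  out <- list(xq = xq, wq = wq, g = g)
  .soap_cache[[key]] <- out
  out
}

# ---- real spherical harmonics ---------------------------------------------

# Real spherical harmonics at unit vectors `u` (rows), returned as a list of
# J x (2l+1) matrices for l = 0..l_max (columns ordered m = -l..l). Rows with
# zero direction (the self neighbor) are passed in as c(0, 0, 1).
real_sph_harm <- function(u, l_max) {
  j <- nrow(u)
  ct <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  out <- vector("list", l_max + 1L)
  out[[1]] <- matrix(1 / sqrt(4 * pi), j, 1L)
  if (l_max == 0L) return(out)
  for (l in 1:l_max) {
    p <- pracma::legendre(l, ct)            # (l+1) x J, rows m = 0..l
    if (is.null(dim(p))) p <- matrix(p, ncol = 1L)
    y <- matrix(0, j, 2L * l + 1L)
    norm0 <- sqrt((2 * l + 1) / (4 * pi))
    y[, l + 1L] <- norm0 * p[1L, ]
    for (m in 1:l) {
      nm <- sqrt((2 * l + 1) / (2 * pi) *
                   exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      y[, l + 1L + m] <- nm * p[m + 1L, ] * cos(m * phi)
      y[, l + 1L - m] <- nm * p[m + 1L, ] * sin(m * phi)
    }
    out[[l + 1L]] <- y
  }
  out
}

# scaled modified spherical Bessel function e^{-x} i_l(x), vectorized.
scaled_sph_bessel <- function(x, l) {
  out <- numeric(length(x))
  small <- x < 1e-8
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- besselI(xs, l + 0.5, expon.scaled = TRUE) *
      sqrt(pi / (2 * xs))
  }
  if (any(small))
    out[small] <- if (l == 0L) 1 - x[small] else
      x[small]^l / prod(seq(1, 2 * l + 1, by = 2))
  out
}

# ---- descriptors -----------------------------------------------------------

# Expansion coefficients c[(s,n), lm] of the smoothed neighbor density.
soap_coefficients <- function(env, params) {
  rb <- radial_basis(env$r_c, params$n_max, params$n_quad, params$basis_width)
  xq <- rb$xq; wq <- rb$wq; g <- rb$g
  nmax <- params$n_max; lmax <- params$l_max
  nsp <- length(params$species)
  rj <- env$r
  j <- length(rj)
  if (!j) stop("internal error: empty environment for atom ",
               env$center_index, " of ", env$structure_id)
  wcut <- cutoff_weight(rj, env$r_c, params$smooth_width)
  u <- env$disp / ifelse(rj > 0, rj, 1)
  u[rj == 0, ] <- rep(c(0, 0, 1), each = sum(rj == 0))
  ylm <- real_sph_harm(u, lmax)
  x <- outer(xq, rj) / params$sigma2
  eg <- exp(-outer(xq, rj, "-")^2 / (2 * params$sigma2))
  gt <- t(g * (wq * xq^2))                  # n_max x Q
  spidx <- match(env$species, params$species)
  if (anyNA(spidx))
    stop("environment contains species outside the descriptor channels: ",
         paste(unique(env$species[is.na(spidx)]), collapse = ", "))
  coef <- matrix(0, nsp * nmax, (lmax + 1L)^2)
  for (l in 0:lmax) {
    sb <- matrix(scaled_sph_bessel(x, l), nrow = length(xq))
    ri <- 4 * pi * (gt %*% (eg * sb))       # n_max x J radial integrals
    cols <- (l^2 + 1L):((l + 1L)^2)
    yw <- ylm[[l + 1L]] * wcut
    for (s in seq_len(nsp)) {
      js <- which(spidx == s)
      if (!length(js)) next
      rows <- ((s - 1L) * nmax + 1L):(s * nmax)
      coef[rows, cols] <- ri[, js, drop = FALSE] %*% yw[js, , drop = FALSE]
    }
  }
  if (!all(is.finite(coef)))
    stop("non-finite density expansion for atom ", env$center_index,
         " of ", env$structure_id)
  coef
}

#' Compute the SOAP descriptor of one atomic environment
#'
#' @param env an `atomic_environment` from [extract_environments()].
#' @param params a [soap_params()] object.
#' @return A unit-norm numeric vector (the flattened power spectrum over
#'   species pairs, radial indices and angular momentum), with attributes
#'   `r_c`, `center_species` and `params`.
#' @export
compute_descriptor <- function(env, params = soap_params()) {
  coef <- soap_coefficients(env, params)
  lmax <- params$l_max
  a <- nrow(coef)
  p <- numeric(a * a * (lmax + 1L))
  for (l in 0:lmax) {
    cl <- coef[, (l^2 + 1L):((l + 1L)^2), drop = FALSE]
    pl <- tcrossprod(cl) * sqrt(8 * pi^2 / (2 * l + 1))
    p[(l * a * a + 1L):((l + 1L) * a * a)] <- pl
  }
  nrm <- sqrt(sum(p * p))
  if (!is.finite(nrm) || nrm <= 0)
    stop("degenerate power spectrum for atom ", env$center_index,
         " of ", env$structure_id)
  structure(p / nrm, r_c = env$r_c, center_species = env$center_species,
            params = params)
}

# index table of the flattened power spectrum, for block bookkeeping
power_spectrum_index <- function(params) {
  nmax <- params$n_max; lmax <- params$l_max; sp <- params$species
  a <- length(sp) * nmax
  an <- rep(seq_len(nmax), times = length(sp))
  as <- rep(sp, each = nmax)
  data.frame(l = rep(0:lmax, each = a * a),
             s1 = rep(rep(as, times = a), lmax + 1L),
             n1 = rep(rep(an, times = a), lmax + 1L),
             s2 = rep(rep(as, each = a), lmax + 1L),
             n2 = rep(rep(an, each = a), lmax + 1L),
             stringsAsFactors = FALSE)
}

#' Compute SOAP descriptors for a set of environments
#'
#' @param envs list of `atomic_environment` objects sharing one cutoff.
#' @param params a [soap_params()].
#' @return A `soap_descriptors` matrix (one row per environment) carrying the
#'   shared `r_c`, the `params` and per-row metadata.
#' @export
soap_descriptors <- function(envs, params = soap_params()) {
  if (!length(envs)) stop("no environments supplied")
  rcs <- vapply(envs, function(e) e$r_c, numeric(1))
  if (diff(range(rcs)) > 1e-12)
    stop("environments mix different cutoffs: ",
         paste(unique(rcs), collapse = ", "))
  d <- t(vapply(envs, function(e) as.numeric(compute_descriptor(e, params)),
                numeric(length(params$species)^2 * params$n_max^2 *
                          (params$l_max + 1L))))
  meta <- data.frame(
    structure_id = vapply(envs, function(e) e$structure_id, character(1)),
    atom_index = vapply(envs, function(e) e$center_index, integer(1)),
    species = vapply(envs, function(e) e$center_species, character(1)),
    stringsAsFactors = FALSE)
  rownames(d) <- paste(meta$structure_id, meta$atom_index, sep = ":")
  structure(d, r_c = rcs[1], params = params, meta = meta,
            class = c("soap_descriptors", "matrix", "array"))
}

#' Subset a descriptor set by environment (row)
#' @param x a [soap_descriptors()] matrix.
#' @param i row (environment) index; columns are always kept.
#' @param ... unused.
#' @export
`[.soap_descriptors` <- function(x, i, ...) {
  out <- unclass(x)[i, , drop = FALSE]
  attr(out, "r_c") <- attr(x, "r_c")
  attr(out, "params") <- attr(x, "params")
  attr(out, "meta") <- attr(x, "meta")[i, , drop = FALSE]
  class(out) <- class(x)
  out
}

desc_compatible <- function(a, b) {
  if (abs(attr(a, "r_c") - attr(b, "r_c")) > 1e-12)
    stop("descriptor cutoffs differ (", attr(a, "r_c"), " vs ",
         attr(b, "r_c"), " A)")
  if (!params_equal(attr(a, "params"), attr(b, "params")))
    stop("descriptors were computed with different SOAP parameters")
  invisible(TRUE)
}

#' SOAP similarity kernel between two descriptors
#'
#' @param a,b descriptors from [compute_descriptor()] (or single rows of a
#'   [soap_descriptors()] matrix), computed with identical parameters and
#'   cutoff.
#' @param zeta positive integer kernel exponent.
#' @return `(a . b)^zeta`, a similarity in `[0, 1]`.
#' @export
soap_kernel <- function(a, b, zeta = 2L) {
  desc_compatible(a, b)
  if (zeta < 1 || zeta != round(zeta)) stop("zeta must be a positive integer")
  sum(as.numeric(a) * as.numeric(b))^zeta
}

#' Kernel matrix between two descriptor sets
#'
#' @param a,b `soap_descriptors` matrices sharing parameters and cutoff
#'   (`b` defaults to `a`).
#' @param zeta positive integer kernel exponent.
#' @return A numeric matrix `K[i, j] = (a_i . b_j)^zeta` with `row_ids` /
#'   `col_ids` attributes.
#' @export
kernel_matrix <- function(a, b = a, zeta = 2L) {
  desc_compatible(a, b)
  if (zeta < 1 || zeta != round(zeta)) stop("zeta must be a positive integer")
  k <- tcrossprod(unclass(a), unclass(b))^zeta
  attr(k, "row_ids") <- rownames(a)
  attr(k, "col_ids") <- rownames(b)
  k
}

#' Multi-cutoff combined kernel matrix
#'
#' Computes `K = sum_t w_t K_t / sum_t w_t` over the cutoffs of a
#' [multiscale_spec()], each `K_t` being the single-cutoff kernel matrix.
#'
#' @param a_by_rc,b_by_rc lists of `soap_descriptors`, named by cutoff (as
#'   `as.character(r_c)`), aligned to the same environments across cutoffs.
#'   `b_by_rc` defaults to `a_by_rc`.
#' @param spec a [multiscale_spec()].
#' @param zeta positive integer kernel exponent.
#' @return The combined kernel matrix.
#' @export
multiscale_kernel_matrix <- function(a_by_rc, b_by_rc = a_by_rc,
                                     spec = multiscale_spec(), zeta = 2L) {
  k <- NULL
  for (t in seq_along(spec$cutoffs)) {
    key <- as.character(spec$cutoffs[t])
    if (is.null(a_by_rc[[key]]) || is.null(b_by_rc[[key]]))
      stop("missing descriptors for cutoff r_c = ", key, " A")
    kt <- kernel_matrix(a_by_rc[[key]], b_by_rc[[key]], zeta) * spec$weights[t]
    k <- if (is.null(k)) kt else k + kt
  }
  k / sum(spec$weights)
}
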