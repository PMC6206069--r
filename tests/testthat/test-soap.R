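test_that("descriptors are invariant to rotation, translation convention and permutation", {
  p <- soap_params(n_max = 6, l_max = 4)
  for (seed in c(2, 9, 21)) {
    e <- random_env(7, 4, seed)
    d <- compute_descriptor(e, p)
    expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-10)
    dr <- compute_descriptor(rotate_env(e, random_rotation(seed + 100)), p)
    expect_lt(max(abs(d - dr)), 1e-8)
    dp <- compute_descriptor(permute_env(e, seed + 200), p)
    expect_lt(max(abs(d - dp)), 1e-8)
  }
})

test_that("a self-only environment occupies only its own species block", {
  p <- soap_params(n_max = 4, l_max = 3)
  e <- toy_env(matrix(numeric(0), 0, 3), "C", r_c = 3)
  d <- compute_descriptor(e, p)
  idx <- soapshift:::power_spectrum_index(p)
  on_block <- idx$s1 == "C" & idx$s2 == "C"
  expect_true(any(abs(d[on_block]) > 0))
  expect_equal(max(abs(d[!on_block])), 0)
})

test_that("kernel obeys unit self-similarity, symmetry and the exponent law", {
  p <- soap_params(n_max = 6, l_max = 4)
  a <- compute_descriptor(random_env(5, 4, 31), p)
  b <- compute_descriptor(random_env(6, 4, 32), p)
  expect_equal(soap_kernel(a, a, 2), 1, tolerance = 1e-10)
  expect_equal(soap_kernel(a, b, 1), soap_kernel(b, a, 1))
  expect_equal(soap_kernel(a, b, 2), soap_kernel(a, b, 1)^2, tolerance = 1e-12)
  expect_gte(soap_kernel(a, b, 2), 0)
  expect_lte(soap_kernel(a, b, 2), 1)
  # mismatched cutoffs refuse to combine
  b2 <- compute_descriptor(random_env(6, 5, 33), p)
  expect_error(soap_kernel(a, b2, 2), "cutoff")
  # mismatched parameters refuse to combine
  b3 <- compute_descriptor(random_env(6, 4, 32), soap_params(n_max = 6,
                                                             l_max = 4,
                                                             sigma2 = 0.2))
  expect_error(soap_kernel(a, b3, 2), "parameters")
})

test_that("kernel matrices are consistent with the scalar kernel and PSD", {
  p <- soap_params(n_max = 5, l_max = 3)
  envs <- lapply(1:8, function(k) random_env(4 + k %% 3, 3.5, 40 + k))
  descs <- soap_descriptors(envs, p)
  K <- kernel_matrix(descs, zeta = 2)
  expect_equal(dim(K), c(8, 8))
  expect_equal(diag(K), rep(1, 8), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(K, t(K), tolerance = 1e-12, ignore_attr = TRUE)
  for (i in c(2, 5)) for (j in c(3, 8))
    expect_equal(K[i, j], soap_kernel(descs[i, ], descs[j, ], 2),
                 tolerance = 1e-12,
                 ignore_attr = TRUE)
  for (zeta in c(1, 2, 4)) {
    Kz <- kernel_matrix(descs, zeta = zeta)
    expect_gte(min(eigen((Kz + t(Kz)) / 2, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("multi-cutoff combination is the normalized weighted average", {
  w <- small_world()
  descs <- w$ds$desc
  n <- min(6, length(w$ds$y))
  sub <- lapply(descs, function(d) d[seq_len(n), ])
  k2 <- kernel_matrix(sub[["2"]], zeta = 2)
  k4 <- kernel_matrix(sub[["4"]], zeta = 2)
  # single-term spec degenerates to the single-cutoff matrix
  K1 <- multiscale_kernel_matrix(sub, spec = multiscale_spec(2, 1), zeta = 2)
  expect_equal(K1, k2, tolerance = 1e-14, ignore_attr = TRUE)
  # hand-computed weighted average
  Kw <- multiscale_kernel_matrix(sub, spec = multiscale_spec(c(2, 4), c(4, 1)),
                                 zeta = 2)
  expect_equal(Kw, (4 * k2 + k4) / 5, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(Kw), rep(1, n), tolerance = 1e-10, ignore_attr = TRUE)
  # all-equal weights give the plain mean
  Km <- multiscale_kernel_matrix(sub, spec = multiscale_spec(c(2, 4), c(1, 1)),
                                 zeta = 2)
  expect_equal(Km, (k2 + k4) / 2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(multiscale_kernel_matrix(sub, spec = multiscale_spec(c(2, 3),
                                                                    c(1, 1))),
               "r_c = 3")
})

test_that("zeta = 1 kernel matches the rotational density-overlap integral", {
  # converged basis; neighbors well inside the cutoff so the density is
  # fully supported on [0, r_c]
  p <- soap_params(n_max = 16, l_max = 14, zeta = 1, n_quad = 80)
  rc <- 3
  eA <- toy_env(rbind(c(1.0, 0.2, -0.3), c(-0.5, 0.9, 0.4)),
                c("H", "C", "O"), rc)
  eB <- toy_env(rbind(c(0.7, -0.6, 0.2), c(0.3, 0.5, -1.0)),
                c("H", "C", "H"), rc)
  k_impl <- soap_kernel(compute_descriptor(eA, p), compute_descriptor(eB, p),
                        1)
  k_orac <- so3_kernel(eA, eB, p$sigma2, p$smooth_width)
  expect_equal(k_impl, k_orac, tolerance = 1e-3)
})

test_that("descriptor changes continuously as a neighbor crosses the cutoff", {
  p <- soap_params(n_max = 6, l_max = 4)
  rc <- 3
  base <- rbind(c(1.2, 0.3, -0.4))
  inside <- toy_env(rbind(base, c(rc - 1e-5, 0, 0)), c("H", "C", "C"), rc)
  gone <- toy_env(base, c("H", "C"), rc)
  d_in <- compute_descriptor(inside, p)
  d_out <- compute_descriptor(gone, p)
  expect_lt(max(abs(d_in - d_out)), 1e-3)
})
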