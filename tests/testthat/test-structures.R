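test_that("extended-XYZ files parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "2",
    'Lattice="10 0 0 0 10 0 0 0 10" Properties=species:S:1:pos:R:3 id="two"',
    "H 0.0 0.0 0.0",
    "O 1.0 0.0 0.0"), f)
  s <- read_structures(f)
  expect_length(s, 1)
  expect_equal(length(s[[1]]$species), 2)
  expect_equal(det(s[[1]]$cell), 1000)
  expect_equal(s[[1]]$id, "two")

  # round trip of randomly generated structures is lossless
  set.seed(4)
  orig <- lapply(1:2, function(k) generate_crystal(8, seed = k, id = paste0("g", k)))
  g <- withr::local_tempfile(fileext = ".xyz")
  write_structures(orig, g)
  back <- read_structures(g)
  expect_length(back, 2)
  for (k in 1:2) {
    expect_equal(back[[k]]$positions, orig[[k]]$positions, tolerance = 1e-12)
    expect_identical(back[[k]]$species, orig[[k]]$species)
    expect_equal(back[[k]]$cell, orig[[k]]$cell, tolerance = 1e-12)
  }

  # empty set -> empty file, no frames
  e <- withr::local_tempfile(fileext = ".xyz")
  write_structures(list(), e)
  expect_length(read_structures(e), 0)
})

test_that("malformed files and disallowed elements give informative errors", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", 'Lattice="10 0 0 0 10" Properties=species:S:1:pos:R:3',
               "H 0 0 0"), f)
  expect_error(read_structures(f), "Lattice.*9 numbers|line 2")
  writeLines(c("1", "no header here at all", "H 0 0 0"), f)
  expect_error(read_structures(f), "line 2")
  writeLines(c("1", 'Lattice="10 0 0 0 10 0 0 0 10"', "S 0 0 0"), f)
  expect_error(read_structures(f), "S")
  expect_error(crystal(diag(3) * 0, "H", matrix(0, 1, 3)), "non-singular")
  expect_error(crystal(diag(3), c("H", "C"), matrix(0, 1, 3)), "length")
})

test_that("supercell replication scales atoms and volume", {
  s <- generate_crystal(4, seed = 11, cell_edge = 5)
  expect_equal(build_supercell(s, c(1, 1, 1))$positions, s$positions)
  s2 <- build_supercell(s, c(2, 1, 1))
  expect_equal(length(s2$species), 8)
  expect_equal(s2$cell[1, ], 2 * s$cell[1, ])
  s8 <- build_supercell(s, c(2, 2, 2))
  expect_equal(abs(det(s8$cell)), 8 * abs(det(s$cell)))
  expect_error(build_supercell(s, c(0, 1, 1)), "positive")
})

test_that("environment extraction handles isolation, pairs and images", {
  iso <- crystal(diag(3) * 20, "H", matrix(10, 1, 3))
  e <- extract_environments(iso, "all", 2)[[1]]
  expect_equal(length(e$r), 1)     # only the self neighbor
  expect_equal(e$r, 0)
  expect_equal(e$species, "H")

  pair <- crystal(diag(3) * 20, c("H", "H"),
                  rbind(c(5, 5, 5), c(5.74, 5, 5)))
  envs <- extract_environments(pair, "all", 2)
  for (e in envs) {
    expect_equal(length(e$r), 2)
    expect_equal(sort(e$r), c(0, 0.74), tolerance = 1e-12)
  }

  # 1-atom simple cubic, a = 3: self + 6 images at 3.0 inside r_c = 3.1
  sc <- crystal(diag(3) * 3, "H", matrix(0.5, 1, 3))
  e <- extract_environments(sc, "H", 3.1)[[1]]
  expect_equal(length(e$r), 7)
  expect_equal(sort(e$r), c(0, rep(3, 6)), tolerance = 1e-12)

  expect_error(extract_environments(sc, "H", -1), "positive")
})

test_that("neighbor lists match exhaustive image enumeration", {
  for (seed in c(3, 17, 42)) {
    s <- generate_crystal(6, seed = seed, cell_edge = 4.5, min_dist = 1.1,
                          id = paste0("bf", seed))
    for (r_c in c(2.5, 5.5)) {
      envs <- extract_environments(s, "all", r_c)
      for (i in seq_along(envs)) {
        bf <- brute_force_neighbors(s, i, r_c)
        sig_bf <- sort(vapply(bf, function(x)
          paste(x$species, formatC(sqrt(sum(x$d^2)), digits = 8,
                                   format = "f")), character(1)))
        sig <- sort(neighbor_signature(envs[[i]]$species, envs[[i]]$disp))
        expect_identical(sig, sig_bf)
      }
    }
  }
})

test_that("environments are invariant to translation and supercell repetition", {
  s <- generate_crystal(8, seed = 23, cell_edge = 5)
  r_c <- 3.5
  base <- extract_environments(s, "all", r_c)
  set.seed(1)
  shift <- runif(3, -7, 7)
  s2 <- s
  s2$positions <- sweep(s$positions, 2, shift, "+")
  moved <- extract_environments(s2, "all", r_c)
  sup <- build_supercell(s, c(2, 2, 2))
  sup_envs <- extract_environments(sup, "all", r_c)
  for (i in seq_along(base)) {
    sig0 <- sort(neighbor_signature(base[[i]]$species, base[[i]]$disp, 9))
    expect_identical(sort(neighbor_signature(moved[[i]]$species,
                                             moved[[i]]$disp, 9)), sig0)
    expect_identical(sort(neighbor_signature(sup_envs[[i]]$species,
                                             sup_envs[[i]]$disp, 9)), sig0)
  }
})

test_that("neighbor counts are monotone in the cutoff radius", {
  s <- generate_crystal(10, seed = 31, cell_edge = 5.5)
  counts <- sapply(c(1.5, 2.5, 3.5, 4.5, 6), function(rc)
    vapply(extract_environments(s, "all", rc), function(e) length(e$r),
           integer(1)))
  for (i in seq_len(nrow(counts)))
    expect_true(all(diff(counts[i, ]) >= 0))
})
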