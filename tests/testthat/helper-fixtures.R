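# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# build an atomic_environment directly from displacement vectors (the self
# neighbor at zero displacement is prepended)
toy_env <- function(disp, species, r_c, center = species[1]) {
  disp <- rbind(c(0, 0, 0), disp)
  soapshift:::new_environment(center, 1L, "toy", c(center, species[-1]),
                              disp, sqrt(rowSums(disp^2)), r_c)
}

# random environment with n neighbors inside 0.9 * r_c
random_env <- function(n, r_c, seed, species = c("H", "C", "N", "O")) {
  set.seed(seed)
  d <- matrix(rnorm(3 * n), n, 3)
  d <- d / sqrt(rowSums(d^2)) * runif(n, 0.5, 0.9 * r_c)
  toy_env(d, c("H", sample(species, n, replace = TRUE)), r_c)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

rotate_env <- function(env, R) {
  env$disp <- env$disp %*% t(R)
  env
}

permute_env <- function(env, seed) {
  set.seed(seed)
  p <- sample(length(env$r))
  env$disp <- env$disp[p, , drop = FALSE]
  env$r <- env$r[p]
  env$species <- env$species[p]
  env
}

# a small shared training world: 12 crystals + noiseless oracle labels,
# SOAP at two cutoffs to keep unit tests quick
small_world <- function() {
  fixture("small_world", {
    crystals <- lapply(1:12, function(k)
      generate_crystal(16, seed = 7000 + k, id = paste0("w", k)))
    rule <- oracle_rule(noise_sd = 0)
    tab <- oracle_table(crystals, rule)
    soap <- soap_params(n_max = 6, l_max = 4)
    ds <- shift_dataset(crystals, tab, "H", cutoffs = c(2, 4), soap = soap)
    list(crystals = crystals, rule = rule, tab = tab, ds = ds, soap = soap,
         spec = multiscale_spec(c(2, 4), c(4, 1)))
  })
}
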