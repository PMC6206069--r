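# Synthetic fixtures: random periodic organic-like crystals, a ground-truth
# shielding oracle with controllable short- and long-range structure, and
# perturbed "polymorph" families. These stand in for electronic-structure
# reference data so the whole pipeline is testable offline.

#' Synthetic shielding oracle rule
#'
#' The oracle assigns each atom
#' `sigma_i = a_s - b * N_i(r_s) + c * sum_{j != i, r_ij <= r_max}
#' exp(-r_ij / r_0) + noise`, where `N_i(r_s)` is the periodic neighbor
#' count within the short radius `r_s` and the long-range sum runs over all
#' periodic images up to `r_max`. The dominant short-range term and weaker
#' long-range tail mimic the cutoff dependence of real chemical shieldings.
#'
#' @param base named vector of per-element baseline shieldings `a_s` (ppm).
#' @param short_coeff `b`, ppm per short-range neighbor.
#' @param r_s short-range counting radius (Angstrom).
#' @param long_coeff `c`, amplitude of the long-range tail (ppm).
#' @param r_0 decay length of the tail (Angstrom).
#' @param r_max range cap of the tail (Angstrom); must exceed `r_s`.
#' @param noise_sd Gaussian label noise (ppm).
#' @param seed default RNG seed for the noise.
#' @return An `oracle_rule`.
#' @export
oracle_rule <- function(base = c(H = 30, C = 170, N = 250, O = 280),
                        short_coeff = 2, r_s = 1.6, long_coeff = 1,
                        r_0 = 3, r_max = 7, noise_sd = 0.1, seed = 1L) {
  stopifnot(all(is.finite(base)), r_s < r_max, noise_sd >= 0,
            is.finite(short_coeff), is.finite(long_coeff), r_0 > 0)
  structure(list(base = base, short_coeff = short_coeff, r_s = r_s,
                 long_coeff = long_coeff, r_0 = r_0, r_max = r_max,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "oracle_rule")
}

#' Generate a random packed periodic crystal
#'
#' Atoms are placed uniformly in a cubic cell by rejection sampling subject
#' to all periodic pairwise distances being at least `min_dist`. Species
#' counts follow the composition fractions (largest-remainder rounding).
#'
#' @param n_atoms number of atoms.
#' @param composition named fractions over H/C/N/O summing to 1.
#' @param cell_edge cubic cell edge (Angstrom).
#' @param min_dist minimum periodic interatomic distance (Angstrom).
#' @param seed RNG seed.
#' @param id structure label.
#' @return A [crystal()].
#' @export
generate_crystal <- function(n_atoms, composition = c(H = 0.5, C = 0.3,
                                                      N = 0.1, O = 0.1),
                             cell_edge = 6, min_dist = 1.0, seed = 1L,
                             id = paste0("synth_", seed)) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  bad <- setdiff(names(composition), ALLOWED_SPECIES)
  if (length(bad)) stop("disallowed element in composition: ",
                        paste(bad, collapse = ", "))
  counts <- floor(composition * n_atoms)
  rem <- n_atoms - sum(counts)
  if (rem > 0) {
    frac <- composition * n_atoms - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  species <- rep(names(counts), times = counts)
  with_seed(seed, {
    pos <- matrix(NA_real_, n_atoms, 3)
    placed <- 0L
    attempts <- 0L
    while (placed < n_atoms) {
      attempts <- attempts + 1L
      if (attempts > 1e5)
        stop("could not pack ", n_atoms, " atoms at min_dist = ", min_dist,
             " into a ", cell_edge, " A cell; increase cell_edge")
      cand <- stats::runif(3, 0, cell_edge)
      ok <- TRUE
      if (placed > 0L) {
        d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand, "-")
        d <- d - cell_edge * round(d / cell_edge)   # minimum image (cubic)
        ok <- all(rowSums(d * d) >= min_dist^2)
      }
      if (ok) { placed <- placed + 1L; pos[placed, ] <- cand }
    }
    crystal(diag(3) * cell_edge, species, pos, id = id)
  })
}

# periodic pairwise terms used by the oracle: for every atom, neighbor
# distances (excluding self) up to r
oracle_neighbor_dists <- function(structure, r) {
  pos <- wrap_positions(structure)
  n <- nrow(pos)
  tr <- image_shifts(structure$cell, r)
  m <- nrow(tr)
  allpos <- pos[rep(seq_len(n), times = m), , drop = FALSE] +
    tr[rep(seq_len(m), each = n), , drop = FALSE]
  lapply(seq_len(n), function(i) {
    d <- sweep(allpos, 2, pos[i, ], "-")
    rr <- sqrt(rowSums(d * d))
    rr[rr > 1e-9 & rr <= r + 1e-9]
  })
}

#' Ground-truth shieldings from the synthetic oracle
#'
#' @param structure a [crystal()].
#' @param rule an [oracle_rule()].
#' @param seed overrides `rule$seed` for the noise draw.
#' @return Per-atom shieldings (ppm), in atom order.
#' @export
oracle_shieldings <- function(structure, rule = oracle_rule(), seed = NULL) {
  validate_crystal(structure)
  dists <- oracle_neighbor_dists(structure, rule$r_max)
  sig <- vapply(seq_along(dists), function(i) {
    r <- dists[[i]]
    a <- rule$base[[structure$species[i]]]
    a - rule$short_coeff * sum(r <= rule$r_s + 1e-9) +
      rule$long_coeff * sum(exp(-r / rule$r_0))
  }, numeric(1))
  if (rule$noise_sd > 0) {
    s <- if (!is.null(seed)) seed else rule$seed
    sig <- sig + with_seed(s, stats::rnorm(length(sig), 0, rule$noise_sd))
  }
  sig
}

#' Oracle shielding table for a set of structures
#'
#' One noise stream (from `seed`) covers the whole set, so tables are
#' reproducible as a unit.
#'
#' @param structures list of [crystal()] objects.
#' @param rule an [oracle_rule()].
#' @param seed RNG seed for the noise (defaults to `rule$seed`).
#' @return Data frame with `structure_id`, `atom_index`, `element`,
#'   `sigma_ppm` — the training-table format of [shift_dataset()].
#' @export
oracle_table <- function(structures, rule = oracle_rule(), seed = NULL) {
  clean <- lapply(structures, function(s)
    oracle_shieldings(s, within_rule_no_noise(rule)))
  tab <- do.call(rbind, lapply(seq_along(structures), function(k) {
    s <- structures[[k]]
    data.frame(structure_id = s$id,
               atom_index = seq_along(s$species),
               element = s$species,
               sigma_ppm = clean[[k]], stringsAsFactors = FALSE)
  }))
  if (rule$noise_sd > 0) {
    s <- if (!is.null(seed)) seed else rule$seed
    tab$sigma_ppm <- tab$sigma_ppm +
      with_seed(s, stats::rnorm(nrow(tab), 0, rule$noise_sd))
  }
  tab
}

within_rule_no_noise <- function(rule) { rule$noise_sd <- 0; rule }

#' Generate a family of perturbed "polymorph" candidates
#'
#' Returns `n` copies of the parent with i.i.d. Gaussian displacements of
#' standard deviation `amplitude` on every coordinate (re-wrapped into the
#' cell), followed by the unperturbed parent as the final member — a
#' synthetic stand-in for a candidate list from crystal structure
#' prediction in which the true structure is present.
#'
#' @param parent a [crystal()].
#' @param n number of perturbed decoys.
#' @param amplitude per-coordinate displacement standard deviation
#'   (Angstrom, > 0).
#' @param seed RNG seed.
#' @return List of `n + 1` [crystal()] objects (decoys, then parent).
#' @export
make_polymorph_family <- function(parent, n, amplitude, seed = 1L) {
  validate_crystal(parent)
  if (amplitude <= 0) stop("amplitude must be > 0")
  out <- with_seed(seed, lapply(seq_len(n), function(k) {
    pos <- parent$positions +
      matrix(stats::rnorm(3 * nrow(parent$positions), 0, amplitude),
             ncol = 3)
    frac <- pos %*% solve(parent$cell)
    crystal(parent$cell, parent$species, (frac - floor(frac)) %*% parent$cell,
            id = paste0(parent$id, "_decoy", k))
  }))
  c(out, list(parent))
}
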