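# Crystal structures, extended-XYZ I/O and periodic neighbor environments.

ALLOWED_SPECIES <- c("H", "C", "N", "O")

#' Create a periodic crystal structure
#'
#' A `crystal` holds a periodic unit cell (rows of `cell` are the lattice
#' vectors in Angstrom), the element symbol of every atom and Cartesian
#' positions in Angstrom. Only the organic-crystal elements H, C, N and O are
#' admitted, matching the chemical space the shift models are trained for.
#'
#' @param cell 3x3 numeric matrix; rows are the lattice vectors (Angstrom).
#' @param species character vector of element symbols (subset of H, C, N, O).
#' @param positions Nx3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param id free-text label used to key shift tables and reports.
#' @return An object of class `crystal`.
#' @export
crystal <- function(cell, species, positions, id = "crystal") {
  cell <- matrix(as.numeric(cell), 3L, 3L)
  species <- as.character(species)
  positions <- matrix(as.numeric(positions), ncol = 3L)
  x <- structure(list(cell = cell, species = species, positions = positions,
                      id = as.character(id)[1L]),
                 class = "crystal")
  validate_crystal(x)
}

validate_crystal <- function(x) {
  if (!all(is.finite(x$cell)) || abs(det(x$cell)) <= 0)
    stop("crystal cell must be finite and non-singular (|det| > 0)")
  if (!all(is.finite(x$positions)))
    stop("crystal positions must be finite")
  if (length(x$species) != nrow(x$positions))
    stop("species length (", length(x$species), ") != number of positions (",
         nrow(x$positions), ")")
  bad <- setdiff(unique(x$species), ALLOWED_SPECIES)
  if (length(bad))
    stop("disallowed element symbol(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(ALLOWED_SPECIES, collapse = ", "), ")")
  x
}

#' @export
print.crystal <- function(x, ...) {
  cat("<crystal> ", x$id, ": ", length(x$species), " atoms (",
      paste(sprintf("%s=%d", names(table(x$species)), table(x$species)),
            collapse = ", "),
      "), volume ", format(abs(det(x$cell)), digits = 6), " A^3\n", sep = "")
  invisible(x)
}

# ---- extended XYZ ----------------------------------------------------------

# Parse the key=value comment line of an extxyz frame; values may be quoted.
parse_xyz_header <- function(line, lineno) {
  kv <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_:]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1L)
    stop("line ", lineno, ": malformed extended-XYZ header (no key=value pairs): ",
         line)
  for (i in seq_along(m)) {
    tok <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1L, eq - 1L)
    val <- substr(tok, eq + 1L, nchar(tok))
    val <- sub('^"', "", sub('"$', "", val))
    kv[[key]] <- val
  }
  kv
}

#' Read crystal structures from an extended-XYZ file
#'
#' Each frame must carry a `Lattice="ax ay az bx by bz cx cy cz"` entry
#' (row-major lattice vectors) in its comment line. Element symbols are
#' validated against the allowed set H, C, N, O.
#'
#' @param path file path of a (multi-frame) extended-XYZ file.
#' @return A list of [crystal()] objects, one per frame.
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # trailing blank lines are tolerated
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L)
      stop("line ", i, ": expected an atom count, got: ", lines[i])
    if (i + 1L + n > length(lines))
      stop("line ", i, ": frame declares ", n, " atoms but file is truncated")
    frame <- frame + 1L
    kv <- parse_xyz_header(lines[i + 1L], i + 1L)
    if (is.null(kv$Lattice))
      stop("line ", i + 1L, ": missing Lattice=... entry in extended-XYZ header")
    lat <- suppressWarnings(as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]]))
    if (length(lat) != 9L || anyNA(lat))
      stop("line ", i + 1L, ": Lattice entry must contain 9 numbers")
    cell <- matrix(lat, 3L, 3L, byrow = TRUE)
    id <- if (!is.null(kv$id)) kv$id else paste0("frame_", frame)
    species <- character(n)
    pos <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop("line ", ln, ": expected 'symbol x y z', got: ", lines[ln])
      species[k] <- tok[1L]
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz))
        stop("line ", ln, ": non-numeric coordinates: ", lines[ln])
      pos[k, ] <- xyz
    }
    out[[frame]] <- crystal(cell, species, pos, id = id)
    i <- i + 2L + n
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  out
}

#' Write crystal structures to an extended-XYZ file
#'
#' Coordinates and lattice vectors are written with 17 significant digits so
#' that a read/write round trip is lossless to well below 1e-10 Angstrom.
#'
#' @param structures list of [crystal()] objects (may be empty).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_structures <- function(structures, path) {
  if (inherits(structures, "crystal")) structures <- list(structures)
  lines <- character(0)
  for (s in structures) {
    validate_crystal(s)
    lat <- paste(sprintf("%.17g", as.vector(t(s$cell))), collapse = " ")
    hdr <- sprintf('Lattice="%s" Properties=species:S:1:pos:R:3 id="%s"',
                   lat, s$id)
    at <- sprintf("%-2s %.17g %.17g %.17g", s$species,
                  s$positions[, 1], s$positions[, 2], s$positions[, 3])
    lines <- c(lines, as.character(length(s$species)), hdr, at)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write to '", path, "': ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Replicate a crystal into a supercell
#'
#' @param structure a [crystal()].
#' @param replication integer vector of length 3, each >= 1.
#' @return A [crystal()] with the cell rows scaled and atoms replicated; the
#'   original atoms come first (zero-shift copy).
#' @export
build_supercell <- function(structure, replication) {
  validate_crystal(structure)
  rep3 <- as.integer(replication)
  if (length(rep3) != 3L || anyNA(rep3) || any(rep3 < 1L))
    stop("replication must be three positive integers")
  shifts <- as.matrix(expand.grid(a = 0:(rep3[1] - 1L),
                                  b = 0:(rep3[2] - 1L),
                                  c = 0:(rep3[3] - 1L)))
  cart <- shifts %*% structure$cell
  n <- nrow(structure$positions)
  pos <- matrix(NA_real_, n * nrow(cart), 3L)
  for (m in seq_len(nrow(cart)))
    pos[((m - 1L) * n + 1L):(m * n), ] <-
      sweep(structure$positions, 2L, cart[m, ], "+")
  crystal(diag(rep3) %*% structure$cell,
          rep(structure$species, times = nrow(cart)), pos,
          id = paste0(structure$id, "_", paste(rep3, collapse = "x")))
}

# ---- periodic neighbor search ---------------------------------------------

# Lattice translations covering all images within distance r of any point in
# the home cell. Based on the perpendicular spacing of the lattice planes.
image_shifts <- function(cell, r) {
  inv <- solve(cell)
  spacing <- 1 / sqrt(colSums(inv^2))
  n <- pmax(0L, as.integer(ceiling(r / spacing + 1e-9))) + 1L
  g <- as.matrix(expand.grid(-n[1]:n[1], -n[2]:n[2], -n[3]:n[3]))
  g %*% cell
}

wrap_positions <- function(structure) {
  frac <- structure$positions %*% solve(structure$cell)
  (frac - floor(frac)) %*% structure$cell
}

new_environment <- function(center_species, center_index, structure_id,
                            species, disp, r, r_c) {
  structure(list(center_species = center_species,
                 center_index = center_index,
                 structure_id = structure_id,
                 species = species, disp = disp, r = r, r_c = r_c),
            class = "atomic_environment")
}

#' @export
print.atomic_environment <- function(x, ...) {
  cat("<atomic_environment> ", x$center_species, " atom ", x$center_index,
      " of ", x$structure_id, ": ", length(x$r), " neighbors within ",
      x$r_c, " A\n", sep = "")
  invisible(x)
}

#' Extract periodic atomic environments
#'
#' Returns, for each selected atom, every neighbor (including periodic
#' images, and the atom itself at zero displacement) whose distance from the
#' center is at most `r_c`. The image sum is correct even when `r_c` exceeds
#' the cell dimensions, in which case several images of the same atom appear.
#'
#' @param structure a [crystal()].
#' @param element an element symbol, a vector of symbols, or `"all"`.
#' @param r_c cutoff radius in Angstrom (> 0).
#' @param indices optional integer vector restricting which atoms (of the
#'   requested element) become centers.
#' @return A list of `atomic_environment` objects.
#' @export
extract_environments <- function(structure, element = "all", r_c,
                                 indices = NULL) {
  validate_crystal(structure)
  if (!is.numeric(r_c) || length(r_c) != 1L || r_c <= 0)
    stop("r_c must be a single positive number")
  pos <- wrap_positions(structure)
  n <- nrow(pos)
  centers <- if (identical(element, "all")) seq_len(n)
             else which(structure$species %in% element)
  if (!is.null(indices)) centers <- intersect(indices, centers)
  tr <- image_shifts(structure$cell, r_c)
  m <- nrow(tr)
  # all candidate neighbor coordinates: atom j in image m
  allpos <- pos[rep(seq_len(n), times = m), , drop = FALSE] +
    tr[rep(seq_len(m), each = n), , drop = FALSE]
  allspec <- rep(structure$species, times = m)
  tol <- 1e-9
  lapply(centers, function(i) {
    d <- sweep(allpos, 2L, pos[i, ], "-")
    r <- sqrt(rowSums(d * d))
    keep <- r <= r_c + tol
    new_environment(structure$species[i], i, structure$id,
                    allspec[keep], d[keep, , drop = FALSE], r[keep], r_c)
  })
}

# Restrict an environment to a smaller cutoff (equivalent to re-extraction).
truncate_environment <- function(env, r_c) {
  if (r_c > env$r_c + 1e-9)
    stop("cannot truncate environment to a larger cutoff (", r_c, " > ",
         env$r_c, ")")
  keep <- env$r <= r_c + 1e-9
  new_environment(env$center_species, env$center_index, env$structure_id,
                  env$species[keep], env$disp[keep, , drop = FALSE],
                  env$r[keep], r_c)
}
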