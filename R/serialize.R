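# Model archive: a single self-contained JSON file holding a versioned
# manifest plus the numeric arrays (weights and reference descriptors at
# every cutoff) at full double precision. Deterministic content: identical
# models serialize to byte-identical files (no timestamps).

ARCHIVE_VERSION <- "1.0"

#' Save a fitted shift model to a JSON archive
#'
#' @param model a [shift_model()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_shift_model <- function(model, path) {
  if (!inherits(model, "shift_model")) stop("not a shift_model")
  arch <- list(
    manifest = list(
      format = "soapshift-model",
      version = ARCHIVE_VERSION,
      element = model$element,
      soap = unclass(model$soap),
      kernels = unclass(model$kernels),
      lambda = model$lambda,
      ymean = model$ymean,
      sigma_ref = model$sigma_ref,
      seed = model$seed,
      n_train = length(model$alpha)),
    meta = model$meta,
    y = model$y,
    alpha = model$alpha,
    ref_desc = lapply(model$ref_desc, function(d)
      list(r_c = attr(d, "r_c"),
           dim = dim(d),
           values = as.numeric(unclass(d)))))
  json <- jsonlite::toJSON(arch, digits = NA, auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a shift model archive
#'
#' Refuses archives written by a newer major format version.
#'
#' @param path archive path written by [save_shift_model()].
#' @return A [shift_model()] object (without the original call and training
#'   fit diagnostics).
#' @export
load_shift_model <- function(path) {
  arch <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  man <- arch$manifest
  if (!identical(man$format, "soapshift-model"))
    stop("not a soapshift model archive: ", path)
  major <- as.integer(strsplit(man$version, ".", fixed = TRUE)[[1]][1])
  have <- as.integer(strsplit(ARCHIVE_VERSION, ".", fixed = TRUE)[[1]][1])
  if (is.na(major) || major > have)
    stop("model archive version ", man$version,
         " is newer than this package supports (", ARCHIVE_VERSION, ")")
  soap <- do.call(soap_params, man$soap[c("sigma2", "n_max", "l_max", "zeta",
                                          "smooth_width", "species",
                                          "n_quad", "basis_width")])
  kernels <- multiscale_spec(man$kernels$cutoffs, man$kernels$weights)
  meta <- as.data.frame(arch$meta, stringsAsFactors = FALSE)
  ref_desc <- lapply(arch$ref_desc, function(d) {
    m <- matrix(d$values, d$dim[1], d$dim[2])
    rownames(m) <- paste(meta$structure_id, meta$atom_index, sep = ":")
    structure(m, r_c = d$r_c, params = soap, meta = meta,
              class = c("soap_descriptors", "matrix", "array"))
  })
  names(ref_desc) <- names(arch$ref_desc)
  alpha <- as.numeric(arch$alpha)
  structure(list(element = man$element, kernels = kernels, soap = soap,
                 lambda = man$lambda, alpha = alpha, jitter = NULL,
                 ymean = man$ymean, ref_desc = ref_desc, meta = meta,
                 y = as.numeric(arch$y),
                 fitted = NULL, sigma_ref = man$sigma_ref,
                 seed = man$seed, curation = list(),
                 version = man$version, call = NULL),
            class = "shift_model")
}
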