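# Gaussian-process (kernel ridge) regression of chemical shieldings.
#
# The predicted shielding of an environment X is sigma(X) = sum_i alpha_i
# k(X, X_i) over the retained training environments X_i, with k the
# normalized multi-cutoff SOAP kernel; the weights alpha solve
# (K + lambda I) alpha = y on the training kernel matrix.

#' Solve for the regression weights alpha
#'
#' Solves `(K + lambda I) alpha = y` by Cholesky factorization. If the
#' factorization fails, an adaptive diagonal jitter (1e-10, escalating
#' tenfold up to 1e-6) is added until it succeeds.
#'
#' @param K square symmetric kernel matrix (training x training).
#' @param y training labels (shieldings, ppm).
#' @param lambda ridge regularization, >= 0, on the unit-diagonal kernel.
#' @return Numeric weight vector `alpha` with attribute `jitter` (the jitter
#'   actually used).
#' @export
gpr_fit <- function(K, y, lambda = 1e-4) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  n <- nrow(K)
  if (length(y) != n) stop("length(y) (", length(y), ") != dim(K) (", n, ")")
  if (lambda < 0) stop("lambda must be >= 0")
  jitters <- c(0, 10^seq(-10, -6))
  err <- NULL
  for (j in jitters) {
    ch <- tryCatch(chol(K + diag(lambda + j, n)), error = function(e) e)
    if (inherits(ch, "error")) { err <- ch; next }
    alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    res <- max(abs((K + diag(lambda + j, n)) %*% alpha - y))
    if (res <= 1e-8 * max(abs(y), 1e-12))
      return(structure(as.numeric(alpha), jitter = j))
    err <- simpleError(sprintf("solve residual %.3g exceeds tolerance", res))
  }
  stop("kernel solve failed even with jitter 1e-6 (ill-conditioned kernel): ",
       conditionMessage(err))
}

#' Prediction-error summary
#'
#' @param pred predicted shieldings or shifts (ppm).
#' @param truth reference values (ppm), same length.
#' @return An `eval_report` with `rmse` (ppm), `r2` (NA when undefined:
#'   n < 2 or zero-variance truth), `n` and per-point `residuals`
#'   (predicted - truth).
#' @export
evaluate_shifts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ (", length(pred), " vs ",
         length(truth), ")")
  if (!length(pred)) stop("need at least one value")
  resd <- as.numeric(pred) - as.numeric(truth)
  sstot <- sum((truth - mean(truth))^2)
  r2 <- if (length(pred) >= 2 && sstot > 0) 1 - sum(resd^2) / sstot
        else NA_real_
  structure(list(rmse = sqrt(mean(resd^2)), r2 = r2, n = length(pred),
                 residuals = resd),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, RMSE = %.4g ppm, R2 = %s\n", x$n,
              x$rmse, ifelse(is.na(x$r2), "undefined", format(x$r2,
                                                              digits = 4))))
  invisible(x)
}

# ---- dataset ---------------------------------------------------------------

#' Assemble a per-element shift dataset with multi-cutoff descriptors
#'
#' Joins a shielding table to the atoms of the supplied structures, extracts
#' each labeled atom's periodic environment at the largest cutoff and derives
#' the smaller-cutoff environments from it, then computes SOAP descriptors
#' at every cutoff.
#'
#' @param structures list of [crystal()] objects with unique ids.
#' @param shifts data frame with columns `structure_id`, `atom_index`
#'   (1-based), `element`, `sigma_ppm`.
#' @param element the element this dataset regresses (one model per element).
#' @param cutoffs cutoff radii to cover (default the multiscale ladder).
#' @param soap a [soap_params()].
#' @return A `shift_dataset`: descriptor matrices per cutoff, labels `y`
#'   (ppm), and per-environment metadata.
#' @export
shift_dataset <- function(structures, shifts, element = "H",
                          cutoffs = c(2, 3, 4, 5, 6, 7),
                          soap = soap_params()) {
  need <- c("structure_id", "atom_index", "element", "sigma_ppm")
  if (!all(need %in% names(shifts)))
    stop("shifts table must have columns: ", paste(need, collapse = ", "))
  tab <- shifts[shifts$element == element, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for element ", element, " in the shift table")
  if (!all(is.finite(tab$sigma_ppm))) stop("shieldings must be finite")
  ids <- vapply(structures, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("structure ids must be unique")
  # the table may cover more structures than supplied; use the overlap
  tab <- tab[tab$structure_id %in% ids, , drop = FALSE]
  if (!nrow(tab))
    stop("the shift table labels none of the supplied structures")
  cutoffs <- sort(unique(as.numeric(cutoffs)))
  rc_max <- max(cutoffs)
  envs <- list(); y <- numeric(0)
  for (sid in unique(tab$structure_id)) {
    s <- structures[[match(sid, ids)]]
    rows <- tab[tab$structure_id == sid, , drop = FALSE]
    idx <- as.integer(rows$atom_index)
    if (any(idx < 1L | idx > length(s$species)))
      stop("atom_index out of range for structure ", sid)
    if (any(s$species[idx] != element))
      stop("structure ", sid, ": labeled atoms are not all ", element)
    e <- extract_environments(s, element, rc_max, indices = idx)
    ord <- match(idx, vapply(e, function(x) x$center_index, integer(1)))
    envs <- c(envs, e[ord])
    y <- c(y, rows$sigma_ppm)
  }
  desc <- lapply(cutoffs, function(rc) {
    soap_descriptors(lapply(envs, truncate_environment, r_c = rc), soap)
  })
  names(desc) <- as.character(cutoffs)
  meta <- attr(desc[[1]], "meta")
  structure(list(desc = desc, y = y, meta = meta, element = element,
                 cutoffs = cutoffs, soap = soap),
            class = "shift_dataset")
}

#' @export
print.shift_dataset <- function(x, ...) {
  cat("<shift_dataset> ", length(x$y), " ", x$element, " environments from ",
      length(unique(x$meta$structure_id)), " structures; cutoffs ",
      paste(x$cutoffs, collapse = "/"), " A\n", sep = "")
  invisible(x)
}

#' Subset a shift dataset by environment index
#' @param x a `shift_dataset`.
#' @param i integer or logical index over environments.
#' @param ... unused.
#' @export
`[.shift_dataset` <- function(x, i, ...) {
  x$desc <- lapply(x$desc, function(d) d[i, ])
  x$y <- x$y[i]
  x$meta <- x$meta[i, , drop = FALSE]
  x
}

# ---- the model -------------------------------------------------------------

#' Fit a per-element chemical-shielding model
#'
#' The single entry point of the package: curates the training environments
#' (removal of symmetry-equivalent duplicates, optional farthest-point
#' subsampling and cross-validation outlier pruning), builds the combined
#' multi-cutoff SOAP kernel and solves for the regression weights. Labels
#' are centered by their training mean before the solve; the mean is added
#' back at prediction.
#'
#' @param structures list of [crystal()] objects.
#' @param shifts shielding table (see [shift_dataset()]).
#' @param element element symbol to model (default `"H"`).
#' @param kernels a [multiscale_spec()].
#' @param soap a [soap_params()].
#' @param lambda ridge regularization (default 1e-4 on the unit-diagonal
#'   kernel).
#' @param dedup drop symmetry-equivalent training environments (default
#'   TRUE); `dedup_tol` is the similarity tolerance.
#' @param dedup_rc cutoff at which duplicate similarity is measured
#'   (default 4 Angstrom, or the nearest available cutoff).
#' @param fps_n optionally keep only the first `fps_n` environments in
#'   farthest-point-sampling order (combined-kernel metric).
#' @param prune flag and drop label outliers by cross-validated robust
#'   z-score (see [prune_outliers()]); `prune_z` and `folds` control it.
#' @param dedup_tol,prune_z,folds curation tuning parameters.
#' @param sigma_ref optional reference shielding (ppm) for shift conversion.
#' @param seed seed for the curation steps' fold assignment.
#' @param dataset a pre-built [shift_dataset()]; when given, `structures`
#'   and `shifts` are ignored.
#' @return An object of class `shift_model`.
#' @export
shift_model <- function(structures, shifts, element = "H",
                        kernels = multiscale_spec(), soap = soap_params(),
                        lambda = 1e-4, dedup = TRUE, dedup_tol = 1e-6,
                        dedup_rc = 4, fps_n = NULL, prune = FALSE,
                        prune_z = 5, folds = 5, sigma_ref = NULL,
                        seed = NULL, dataset = NULL) {
  cl <- match.call()
  ds <- if (!is.null(dataset)) dataset
        else shift_dataset(structures, shifts, element, kernels$cutoffs, soap)
  if (!all(as.character(kernels$cutoffs) %in% names(ds$desc)))
    stop("dataset lacks descriptors for some cutoffs in the kernel spec")
  element <- ds$element
  curation <- list()
  if (isTRUE(dedup)) {
    rc <- kernels$cutoffs[which.min(abs(kernels$cutoffs - dedup_rc))]
    rep <- deduplicate(ds$desc[[as.character(rc)]], tol = dedup_tol)
    curation$dedup <- rep
    ds <- ds[rep$kept]
  }
  if (!is.null(fps_n)) {
    K <- multiscale_kernel_matrix(ds$desc, spec = kernels, zeta = soap$zeta)
    ord <- fps_select(kernel_distance(K), fps_n)
    curation$fps <- ord
    ds <- ds[sort(ord)]
  }
  if (isTRUE(prune)) {
    rep <- prune_outliers(ds, kernels = kernels, lambda = lambda,
                          folds = folds, z_thresh = prune_z, seed = seed)
    curation$prune <- rep
    ds <- ds[rep$kept]
  }
  K <- multiscale_kernel_matrix(ds$desc, spec = kernels, zeta = soap$zeta)
  ymean <- mean(ds$y)
  alpha <- gpr_fit(K, ds$y - ymean, lambda)
  fit <- as.numeric(K %*% alpha) + ymean
  structure(list(element = element, kernels = kernels, soap = ds$soap,
                 lambda = lambda, alpha = as.numeric(alpha),
                 jitter = attr(alpha, "jitter"), ymean = ymean,
                 ref_desc = ds$desc, meta = ds$meta, y = ds$y,
                 fitted = fit, sigma_ref = sigma_ref, seed = seed,
                 curation = curation, version = "1.0", call = cl),
            class = "shift_model")
}

#' @export
print.shift_model <- function(x, ...) {
  cat("<shift_model> ", x$element, " shieldings; ", length(x$alpha),
      " reference environments from ", length(unique(x$meta$structure_id)),
      " structures\n", sep = "")
  cat("  kernels: ", paste(sprintf("%g A (w=%g)", x$kernels$cutoffs,
                                   x$kernels$weights), collapse = ", "),
      "; zeta = ", x$soap$zeta, "\n", sep = "")
  cat("  lambda = ", format(x$lambda), "; training RMSE = ",
      format(rmse(x$fitted, x$y), digits = 4), " ppm\n", sep = "")
  if (!is.null(x$sigma_ref))
    cat("  sigma_ref = ", format(x$sigma_ref), " ppm\n", sep = "")
  invisible(x)
}

#' @export
summary.shift_model <- function(object, ...) {
  ev <- evaluate_shifts(object$fitted, object$y)
  out <- list(element = object$element, n_train = length(object$alpha),
              n_structures = length(unique(object$meta$structure_id)),
              kernels = object$kernels, lambda = object$lambda,
              soap = object$soap, train_eval = ev,
              curation = lapply(object$curation, function(r)
                if (inherits(r, "curation_report")) r$stats else length(r)),
              sigma_ref = object$sigma_ref)
  class(out) <- "summary.shift_model"
  out
}

#' @export
print.summary.shift_model <- function(x, ...) {
  cat("Chemical-shielding model for ", x$element, "\n", sep = "")
  cat("  training environments: ", x$n_train, " (", x$n_structures,
      " structures)\n", sep = "")
  cat("  cutoffs/weights: ",
      paste(sprintf("%g/%g", x$kernels$cutoffs, x$kernels$weights),
            collapse = " "), "\n", sep = "")
  cat("  lambda: ", format(x$lambda), "\n", sep = "")
  cat(sprintf("  training fit: RMSE %.4g ppm, R2 %s\n", x$train_eval$rmse,
              format(x$train_eval$r2, digits = 4)))
  for (nm in names(x$curation)) {
    st <- x$curation[[nm]]
    if (is.list(st))
      cat(sprintf("  curation %s: removed %d of %d (%.2f%%)\n", nm,
                  st$n_removed, st$n_input, 100 * st$fraction_removed))
  }
  invisible(x)
}

#' @export
coef.shift_model <- function(object, ...) object$alpha

#' @export
fitted.shift_model <- function(object, ...) object$fitted

#' @export
residuals.shift_model <- function(object, ...) object$fitted - object$y

#' Predict chemical shieldings (or shifts) for new structures
#'
#' Implements `sigma(X) = sum_i alpha_i k(X, X_i)` (plus the training label
#' mean) with the model's combined multi-cutoff kernel.
#'
#' @param object a fitted [shift_model()].
#' @param newdata a list of [crystal()] objects, a single `crystal`, a
#'   `shift_dataset`, or a list of `atomic_environment`s extracted at (at
#'   least) the model's largest cutoff.
#' @param type `"shielding"` (default) or `"shift"`; shifts require a
#'   `sigma_ref` (argument or stored in the model) and are
#'   `delta = sigma_ref - sigma`.
#' @param sigma_ref overrides the model's stored reference shielding.
#' @param ... unused.
#' @return A data frame with `structure_id`, `atom_index`, `element` and
#'   `sigma_ppm` (plus `shift_ppm` for `type = "shift"`).
#' @export
predict.shift_model <- function(object, newdata, type = c("shielding", "shift"),
                                sigma_ref = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "crystal")) newdata <- list(newdata)
  if (is.list(newdata) && length(newdata) &&
      inherits(newdata[[1]], "atomic_environment")) {
    envs <- newdata
  } else if (inherits(newdata, "shift_dataset")) {
    envs <- NULL
    ds <- newdata
  } else {
    rc_max <- max(object$kernels$cutoffs)
    envs <- unlist(lapply(newdata, extract_environments,
                          element = object$element, r_c = rc_max),
                   recursive = FALSE)
    if (!length(envs))
      stop("no ", object$element, " atoms found in the supplied structures")
  }
  if (!is.null(envs)) {
    bad <- vapply(envs, function(e) e$center_species, character(1)) !=
      object$element
    if (any(bad))
      stop("environments are centered on the wrong element (model is for ",
           object$element, ")")
    desc <- lapply(object$kernels$cutoffs, function(rc)
      soap_descriptors(lapply(envs, truncate_environment, r_c = rc),
                       object$soap))
    names(desc) <- as.character(object$kernels$cutoffs)
    meta <- attr(desc[[1]], "meta")
  } else {
    if (ds$element != object$element)
      stop("dataset element ", ds$element, " does not match the model (",
           object$element, ")")
    desc <- ds$desc
    meta <- ds$meta
  }
  Kq <- multiscale_kernel_matrix(desc, object$ref_desc,
                                 spec = object$kernels,
                                 zeta = object$soap$zeta)
  sigma <- as.numeric(Kq %*% object$alpha) + object$ymean
  out <- data.frame(structure_id = meta$structure_id,
                    atom_index = meta$atom_index,
                    element = meta$species,
                    sigma_ppm = sigma, stringsAsFactors = FALSE)
  if (type == "shift") {
    sref <- if (!is.null(sigma_ref)) sigma_ref else object$sigma_ref
    if (is.null(sref))
      stop("shift prediction needs sigma_ref (argument or model$sigma_ref)")
    out$shift_ppm <- sref - out$sigma_ppm
  }
  out
}

#' Observed vs fitted plot of a shielding model
#' @param x a `shift_model`.
#' @param ... passed to [plot()].
#' @export
plot.shift_model <- function(x, ...) {
  plot(x$y, x$fitted, xlab = "reference shielding (ppm)",
       ylab = "fitted shielding (ppm)",
       main = paste0(x$element, " shielding model"), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

# ---- learning curves -------------------------------------------------------

#' Learning curves for single-cutoff and combined kernels
#'
#' Splits the dataset by structure into a training pool and a fixed held-out
#' test set, orders the pool by farthest point sampling under the combined
#' kernel metric, and reports the held-out RMSE of models trained on growing
#' prefixes of that ordering, for each kernel specification.
#'
#' @param dataset a [shift_dataset()].
#' @param sizes increasing training-set sizes (environments).
#' @param kernel_specs named list of [multiscale_spec()]s; the default is
#'   one singleton spec per cutoff of the dataset plus the combined
#'   multiscale ladder (`"msk"`).
#' @param lambda ridge regularization.
#' @param seed seed for the train/test structure split.
#' @param test_frac fraction of structures held out for testing.
#' @return A data frame (class `learning_curve`) with columns `kernel`,
#'   `size`, `rmse_ppm`, `n_test`.
#' @export
learning_curve <- function(dataset, sizes, kernel_specs = NULL,
                           lambda = 1e-4, seed = 1, test_frac = 0.2) {
  if (is.null(kernel_specs)) {
    kernel_specs <- lapply(dataset$cutoffs, function(rc)
      multiscale_spec(rc, 1))
    names(kernel_specs) <- paste0("rc", dataset$cutoffs)
    if (length(dataset$cutoffs) == 6 &&
        all(dataset$cutoffs == c(2, 3, 4, 5, 6, 7)))
      kernel_specs$msk <- multiscale_spec()
  }
  sids <- unique(dataset$meta$structure_id)
  n_test <- max(1L, round(test_frac * length(sids)))
  test_sid <- with_seed(seed, sample(sids, n_test))
  is_test <- dataset$meta$structure_id %in% test_sid
  train <- dataset[!is_test]
  test <- dataset[is_test]
  if (any(sizes > length(train$y)))
    stop("requested size exceeds the training pool (", length(train$y), ")")
  zeta <- dataset$soap$zeta
  Kord <- multiscale_kernel_matrix(train$desc, spec = multiscale_spec(
    dataset$cutoffs, rep(1, length(dataset$cutoffs))), zeta = zeta)
  ord <- fps_select(kernel_distance(Kord), length(train$y))
  out <- list()
  for (nm in names(kernel_specs)) {
    spec <- kernel_specs[[nm]]
    Ktr <- multiscale_kernel_matrix(train$desc, spec = spec, zeta = zeta)
    Kte <- multiscale_kernel_matrix(test$desc, train$desc, spec = spec,
                                    zeta = zeta)
    for (sz in sizes) {
      idx <- ord[seq_len(sz)]
      ymean <- mean(train$y[idx])
      alpha <- gpr_fit(Ktr[idx, idx, drop = FALSE], train$y[idx] - ymean,
                       lambda)
      pred <- as.numeric(Kte[, idx, drop = FALSE] %*% alpha) + ymean
      out[[length(out) + 1L]] <- data.frame(
        kernel = nm, size = sz, rmse_ppm = rmse(pred, test$y),
        n_test = length(test$y), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("learning_curve", "data.frame")
  res
}

#' @export
plot.learning_curve <- function(x, ...) {
  ks <- unique(x$kernel)
  cols <- seq_along(ks)
  plot(range(x$size), range(x$rmse_ppm), log = "xy", type = "n",
       xlab = "training environments", ylab = "test RMSE (ppm)", ...)
  for (i in seq_along(ks)) {
    xi <- x[x$kernel == ks[i], ]
    lines(xi$size, xi$rmse_ppm, col = cols[i], type = "b", pch = 16)
  }
  legend("bottomleft", legend = ks, col = cols, lty = 1, pch = 16, cex = 0.8)
  invisible(x)
}
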