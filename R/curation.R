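# Training-set curation: farthest point sampling, removal of
# symmetry-equivalent environments, and cross-validated outlier pruning.

curation_report <- function(kept, removed, reason, ids = NULL) {
  stats <- list(n_input = length(kept) + length(removed),
                n_kept = length(kept), n_removed = length(removed),
                fraction_removed = if (length(kept) + length(removed))
                  length(removed) / (length(kept) + length(removed)) else 0)
  structure(list(kept = kept, removed = removed, reason = reason,
                 kept_ids = if (!is.null(ids)) ids[kept],
                 removed_ids = if (!is.null(ids)) ids[removed],
                 stats = stats),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> kept %d / removed %d of %d (%.2f%%)\n",
              x$stats$n_kept, x$stats$n_removed, x$stats$n_input,
              100 * x$stats$fraction_removed))
  if (x$stats$n_removed)
    print(table(x$reason))
  invisible(x)
}

#' Farthest point sampling
#'
#' Greedy max-min ordering: after the start item, each successive pick
#' maximizes the minimum distance to all previously picked items. Ties are
#' broken by the lowest index. With `start = "max-norm"` the start is the
#' item with the largest total squared distance to all others (for centered
#' Euclidean data this is the largest-norm item).
#'
#' @param d square symmetric distance matrix. For kernel similarities use
#'   [kernel_distance()] first (`d = sqrt(2 - 2k)`).
#' @param n number of items to select (`n <= nrow(d)`).
#' @param start integer index of the first pick, or `"max-norm"`.
#' @return Integer vector of `n` selected indices, in pick order.
#' @export
fps_select <- function(d, n, start = "max-norm") {
  d <- as.matrix(d)
  m <- nrow(d)
  if (ncol(d) != m) stop("d must be square")
  if (n > m) stop("n (", n, ") exceeds the number of items (", m, ")")
  if (n < 1L) stop("n must be >= 1")
  first <- if (identical(start, "max-norm")) which.max(rowSums(d^2))
           else as.integer(start)
  picks <- integer(n)
  picks[1L] <- first
  if (n > 1L) {
    mind <- d[first, ]
    for (i in 2:n) {
      mind[picks[seq_len(i - 1L)]] <- -Inf
      picks[i] <- which.max(mind)
      mind <- pmin(mind, d[picks[i], ])
    }
  }
  picks
}

#' Kernel-induced distance matrix
#'
#' @param K normalized kernel matrix (unit self-similarity).
#' @return `sqrt(pmax(0, 2 - 2K))`, the metric induced by the kernel.
#' @export
kernel_distance <- function(K) {
  K <- as.matrix(K)
  d <- sqrt(pmax(0, 2 - 2 * K))
  matrix(d, nrow(K), ncol(K))
}

#' Remove symmetry-equivalent environments
#'
#' Scans environments in input order and flags one as a duplicate when its
#' kernel similarity (descriptor dot product) to an already-kept environment
#' *of the same structure* exceeds `1 - tol`. Crystal-symmetry copies have
#' similarity 1 up to floating-point noise; environments from different
#' structures are never compared.
#'
#' @param descs a [soap_descriptors()] matrix (one cutoff).
#' @param tol similarity tolerance, `0 < tol < 1` (default 1e-6).
#' @return A `curation_report` with kept/removed indices and reasons.
#' @export
deduplicate <- function(descs, tol = 1e-6) {
  if (!(tol > 0 && tol < 1)) stop("tol must be in (0, 1)")
  meta <- attr(descs, "meta")
  x <- unclass(descs)
  n <- nrow(x)
  keep <- logical(n)
  for (sid in unique(meta$structure_id)) {
    idx <- which(meta$structure_id == sid)
    kept_local <- integer(0)
    for (i in idx) {
      dup <- length(kept_local) &&
        any(x[kept_local, , drop = FALSE] %*% x[i, ] > 1 - tol)
      if (!dup) { keep[i] <- TRUE; kept_local <- c(kept_local, i) }
    }
  }
  curation_report(which(keep), which(!keep),
                  rep("duplicate", sum(!keep)), rownames(x))
}

#' Flag label outliers by cross-validated robust z-score
#'
#' Computes k-fold cross-validation predictions for every environment
#' (folds split by structure, never by environment), forms the residuals
#' `r_i = predicted - label`, and flags environments with
#' `|r_i - median(r)| > z_thresh * 1.4826 * MAD(r)` as outliers. If the MAD
#' degenerates to zero while the residuals still spread, the standard
#' deviation is used instead (with a warning).
#'
#' @param dataset a [shift_dataset()].
#' @param kernels a [multiscale_spec()] used for the CV models.
#' @param lambda ridge regularization.
#' @param folds number of CV folds (>= 2).
#' @param z_thresh robust z-score threshold (default 5).
#' @param seed seed for the fold assignment.
#' @return A `curation_report`; `$details` holds the CV residuals.
#' @export
prune_outliers <- function(dataset, kernels = multiscale_spec(),
                           lambda = 1e-4, folds = 5, z_thresh = 5,
                           seed = NULL) {
  if (folds < 2) stop("folds must be >= 2")
  sids <- unique(dataset$meta$structure_id)
  if (length(sids) < folds)
    stop("need at least ", folds, " structures for ", folds, "-fold CV")
  fold_of_sid <- with_seed(seed,
    sample(rep(seq_len(folds), length.out = length(sids))))
  fold <- fold_of_sid[match(dataset$meta$structure_id, sids)]
  zeta <- dataset$soap$zeta
  K <- multiscale_kernel_matrix(dataset$desc, spec = kernels, zeta = zeta)
  pred <- numeric(length(dataset$y))
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    ymean <- mean(dataset$y[tr])
    alpha <- gpr_fit(K[tr, tr, drop = FALSE], dataset$y[tr] - ymean, lambda)
    pred[te] <- as.numeric(K[te, tr, drop = FALSE] %*% alpha) + ymean
  }
  r <- pred - dataset$y
  med <- stats::median(r)
  scale <- stats::mad(r)                    # 1.4826 * MAD by default
  if (scale == 0 && stats::sd(r) > 0) {
    warning("MAD of CV residuals is zero; falling back to the standard ",
            "deviation")
    scale <- stats::sd(r)
  }
  out <- if (scale > 0) abs(r - med) > z_thresh * scale
         else rep(FALSE, length(r))
  rep <- curation_report(which(!out), which(out),
                         rep("outlier", sum(out)),
                         paste(dataset$meta$structure_id,
                               dataset$meta$atom_index, sep = ":"))
  rep$details <- data.frame(dataset$meta, cv_pred = pred, residual = r,
                            flagged = out)
  rep
}

#' Farthest-point-sampling order over whole structures
#'
#' The structure-structure similarity is the mean over all pairs of
#' same-element environment kernels at a single mid-range cutoff (default
#' 4 Angstrom), the standard average-kernel structure metric.
#'
#' @param structures list of [crystal()] objects.
#' @param n number of structures to select.
#' @param element element of the compared environments, or `"all"`.
#' @param r_c single cutoff used for the comparison.
#' @param soap a [soap_params()].
#' @param start see [fps_select()].
#' @return Integer vector of selected structure indices, in pick order.
#' @export
fps_structures <- function(structures, n, element = "all", r_c = 4,
                           soap = soap_params(), start = "max-norm") {
  descs <- lapply(structures, function(s)
    soap_descriptors(extract_environments(s, element, r_c), soap))
  m <- length(descs)
  K <- matrix(1, m, m)
  for (i in seq_len(m)) for (j in seq_len(i)) {
    K[i, j] <- K[j, i] <- mean(kernel_matrix(descs[[i]], descs[[j]],
                                             zeta = soap$zeta))
  }
  # the averaged kernel is no longer unit-diagonal; normalize it so the
  # induced metric is well defined
  dg <- sqrt(diag(K))
  K <- K / (dg %o% dg)
  fps_select(kernel_distance(K), n, start)
}
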