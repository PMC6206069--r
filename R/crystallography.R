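# Shielding -> shift referencing, comparison to assigned experimental
# shifts, and chemical-shift-driven ranking of candidate crystal structures.

#' Fit the reference shielding sigma_ref
#'
#' Uses the conversion `delta = sigma_ref - sigma`: with the slope
#' constrained to -1, the least-squares reference is
#' `sigma_ref = mean(sigma_calc + delta_exp)`. The unconstrained straight
#' line is also fitted (when n >= 2) and reported as a diagnostic only.
#'
#' @param sigma_calc calculated/predicted shieldings (ppm), paired by
#'   assignment with `delta_exp`.
#' @param delta_exp experimental shifts (ppm).
#' @return A `reference_fit`: `sigma_ref` (ppm), `n`, and diagnostic
#'   `slope` / `intercept` of the unconstrained fit (NA when n < 2).
#' @export
fit_sigma_ref <- function(sigma_calc, delta_exp) {
  if (!length(sigma_calc)) stop("need at least one (sigma, delta) pair")
  if (length(sigma_calc) != length(delta_exp))
    stop("sigma_calc and delta_exp lengths differ")
  sref <- mean(sigma_calc + delta_exp)
  slope <- intercept <- NA_real_
  if (length(sigma_calc) >= 2 && stats::sd(sigma_calc) > 0) {
    fit <- stats::lm(delta_exp ~ sigma_calc)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  structure(list(sigma_ref = sref, n = length(sigma_calc),
                 slope = slope, intercept = intercept),
            class = "reference_fit")
}

#' @export
print.reference_fit <- function(x, ...) {
  cat(sprintf("<reference_fit> sigma_ref = %.4f ppm (n = %d)\n",
              x$sigma_ref, x$n))
  if (!is.na(x$slope))
    cat(sprintf("  diagnostic unconstrained fit: slope %.4f, intercept %.4f\n",
                x$slope, x$intercept))
  invisible(x)
}

#' Convert shieldings to chemical shifts
#'
#' `delta = sigma_ref - sigma`, elementwise.
#'
#' @param sigma shieldings (ppm).
#' @param scale a single `sigma_ref` value, a `reference_fit`, or a named
#'   vector mapping elements to `sigma_ref` values.
#' @param element element symbol, required when `scale` is a named vector.
#' @return Shifts (ppm).
#' @export
to_shifts <- function(sigma, scale, element = NULL) {
  sref <- if (inherits(scale, "reference_fit")) scale$sigma_ref
          else if (!is.null(names(scale))) {
            if (is.null(element)) stop("element is required with a named scale")
            if (!element %in% names(scale))
              stop("no sigma_ref for element ", element, " in the scale")
            unname(scale[[element]])
          } else as.numeric(scale)[1]
  sref - as.numeric(sigma)
}

#' Assigned experimental shift set
#'
#' @param label resonance labels (unique).
#' @param element element symbol per resonance.
#' @param shift_ppm experimental shift per resonance (ppm).
#' @param groups list of 1-based atom-index vectors, one per resonance,
#'   giving the equivalent nuclei carrying that resonance in the reference
#'   structure. Groups must be non-empty and disjoint within an element.
#' @return An `experiment_shifts` object.
#' @export
experiment_shifts <- function(label, element, shift_ppm, groups) {
  label <- as.character(label)
  if (anyDuplicated(label)) stop("resonance labels must be unique")
  if (length(label) != length(element) || length(label) != length(shift_ppm) ||
      length(label) != length(groups))
    stop("label, element, shift_ppm and groups must have equal length")
  if (!all(is.finite(shift_ppm))) stop("experimental shifts must be finite")
  if (any(!vapply(groups, length, integer(1))))
    stop("every resonance needs a non-empty group of atom indices")
  for (el in unique(element)) {
    idx <- unlist(groups[element == el])
    if (anyDuplicated(idx))
      stop("equivalent-nucleus groups overlap within element ", el)
  }
  structure(list(label = label, element = as.character(element),
                 shift_ppm = as.numeric(shift_ppm),
                 groups = lapply(groups, as.integer)),
            class = "experiment_shifts")
}

#' @export
print.experiment_shifts <- function(x, ...) {
  cat("<experiment_shifts> ", length(x$label), " resonances (",
      paste(unique(x$element), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read an assigned experimental shift table
#'
#' Comma-separated with header `label,element,shift_ppm,atom_indices`;
#' `atom_indices` are semicolon-joined and 0-based in the file (converted to
#' 1-based on read).
#'
#' @param path CSV file path.
#' @return An [experiment_shifts()] object.
#' @export
read_experiment <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "element", "shift_ppm", "atom_indices")
  if (!all(need %in% names(tab)))
    stop("experiment table must have columns: ", paste(need, collapse = ", "))
  groups <- lapply(strsplit(as.character(tab$atom_indices), ";"),
                   function(s) as.integer(s) + 1L)
  experiment_shifts(tab$label, tab$element, tab$shift_ppm, groups)
}

#' Aggregate per-atom shifts over equivalent nuclei
#'
#' Equivalent nuclei (e.g. the three protons of a rotating methyl group)
#' share one observed resonance; the predicted value for a resonance is the
#' unweighted mean of its group's per-atom shifts (fast-exchange limit).
#'
#' @param delta per-atom shifts (ppm), indexed by atom position (1-based).
#' @param experiment an [experiment_shifts()] giving the groups.
#' @param species optional element symbols of the atoms, checked against the
#'   resonance elements when given.
#' @return Named numeric vector of per-resonance predicted shifts, in the
#'   experiment's label order.
#' @export
aggregate_predicted <- function(delta, experiment, species = NULL) {
  out <- numeric(length(experiment$label))
  for (i in seq_along(experiment$groups)) {
    g <- experiment$groups[[i]]
    if (any(g < 1L | g > length(delta)))
      stop("atom index out of range in group for resonance ",
           experiment$label[i])
    if (!is.null(species) && any(species[g] != experiment$element[i]))
      stop("group for resonance ", experiment$label[i],
           " contains atoms of the wrong element")
    out[i] <- mean(delta[g])
  }
  names(out) <- experiment$label
  out
}

#' RMSE between predicted and experimental shifts
#'
#' @param pred_by_label named numeric vector of per-resonance predictions
#'   (ppm).
#' @param experiment an [experiment_shifts()].
#' @return Unweighted RMSE over resonance labels (ppm).
#' @export
rmse_vs_experiment <- function(pred_by_label, experiment) {
  miss <- setdiff(experiment$label, names(pred_by_label))
  extra <- setdiff(names(pred_by_label), experiment$label)
  if (length(miss) || length(extra))
    stop("label mismatch; missing: [", paste(miss, collapse = ", "),
         "], unexpected: [", paste(extra, collapse = ", "), "]")
  rmse(pred_by_label[experiment$label], experiment$shift_ppm)
}

#' Rank candidate structures against experimental shifts
#'
#' Candidates are sorted by ascending aggregate RMSE to the experimental
#' shift set; a candidate is accepted when its RMSE falls within the
#' confidence threshold. The default threshold of 0.49 ppm is the 1H
#' confidence interval calibrated for GIPAW-quality shifts and should be
#' re-assessed for other nuclei or reference methods.
#'
#' @param candidates named list: per candidate structure id, a named vector
#'   of per-resonance predicted shifts (ppm).
#' @param experiment an [experiment_shifts()].
#' @param threshold acceptance threshold (ppm), default 0.49.
#' @return A `candidate_ranking` data frame with columns `id`, `rmse_ppm`,
#'   `rank`, `accepted`; ties in RMSE are broken by structure id.
#' @export
rank_candidates <- function(candidates, experiment, threshold = 0.49) {
  if (!length(candidates)) stop("need at least one candidate")
  if (is.null(names(candidates)) || anyDuplicated(names(candidates)))
    stop("candidates must be a uniquely named list")
  rms <- vapply(candidates, rmse_vs_experiment, numeric(1),
                experiment = experiment)
  ord <- order(rms, names(candidates))
  out <- data.frame(id = names(candidates)[ord], rmse_ppm = unname(rms[ord]),
                    rank = seq_along(ord),
                    accepted = unname(rms[ord]) <= threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("candidate_ranking", "data.frame")
  out
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat("Candidate ranking (threshold ", attr(x, "threshold"), " ppm):\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rank candidate structures with a fitted shielding model
#'
#' Convenience pipeline: predict per-atom shieldings for every candidate,
#' convert to shifts, aggregate over equivalent nuclei, and rank.
#'
#' @param model a fitted [shift_model()].
#' @param candidates list of [crystal()] candidates with unique ids.
#' @param experiment an [experiment_shifts()] (resonances of the model's
#'   element).
#' @param sigma_ref reference shielding (ppm); defaults to the model's.
#' @param threshold acceptance threshold (ppm).
#' @return A `candidate_ranking`.
#' @export
rank_structures <- function(model, candidates, experiment,
                            sigma_ref = NULL, threshold = 0.49) {
  keep <- experiment$element == model$element
  if (!all(keep))
    stop("experiment contains resonances of elements other than ",
         model$element)
  preds <- lapply(candidates, function(s) {
    p <- predict(model, s, type = "shift", sigma_ref = sigma_ref)
    delta <- numeric(length(s$species))
    delta[p$atom_index] <- p$shift_ppm
    aggregate_predicted(delta, experiment, species = s$species)
  })
  names(preds) <- vapply(candidates, function(s) s$id, character(1))
  rank_candidates(preds, experiment, threshold)
}
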