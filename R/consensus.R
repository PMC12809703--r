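#' Count EES misclassifications against the acceptability threshold
#'
#' A cell is misclassified when prediction and target fall on opposite sides
#' of the threshold; the boundary itself counts as acceptable on both sides.
#'
#' @param y,t Aligned numeric vectors of predicted and target EES values.
#' @param threshold Acceptability cutoff (default 1.3).
#' @return Integer count.
#' @export
misclassification_count <- function(y, t, threshold = 1.3) {
  if (length(y) != length(t)) stop("y and t must have equal length")
  sum((snap(y) >= threshold) != (snap(t) >= threshold))
}

#' Rank archived networks for consensus building
#'
#' Deterministic total order: misclassification count ascending, then Fobj
#' descending, then pE ascending, then model position ascending. (The
#' original workflow also used visual inspection of validation plots; the
#' tiebreak chain replaces that step so rankings are reproducible.)
#'
#' @param archive An `optimization_archive` from [run_batch()].
#' @param subset Which compounds the misclassification count is taken over:
#'   `"all"` (default), `"tr"`, `"va"` or `"it"`.
#' @return A list of class `model_ranking` with `models` (reordered),
#'   `table` (data frame of model_id, misclass, fobj, pe) and `subset`.
#' @export
rank_models <- function(archive, subset = c("all", "tr", "va", "it")) {
  subset <- match.arg(subset)
  if (!length(archive$models)) stop("archive is empty")
  tab <- do.call(rbind, lapply(seq_along(archive$models), function(i) {
    m <- archive$models[[i]]$metrics
    mis <- if (subset == "all") m$misclass$total else m$misclass[[subset]]
    data.frame(model_id = i, misclass = mis, fobj = m$fobj, pe = m$pe)
  }))
  ord <- order(tab$misclass, -tab$fobj, tab$pe, tab$model_id)
  structure(list(models = archive$models[ord], table = tab[ord, ],
                 subset = subset),
            class = "model_ranking")
}

#' Build a consensus model from the top-ranked networks
#'
#' @param ranking A [rank_models()] result.
#' @param k Number of member networks (default 5; at least 2).
#' @param params An [ees_params()] governing feasibility calls.
#' @return A list of class `consensus_model` with `members` and `params`.
#' @export
build_consensus <- function(ranking, k = 5L, params = ees_params()) {
  if (k < 2L) stop("a consensus needs at least 2 members")
  if (k > length(ranking$models)) {
    stop("k = ", k, " exceeds the ", length(ranking$models), " ranked models")
  }
  structure(list(members = ranking$models[seq_len(k)], params = params),
            class = "consensus_model")
}

#' Scaled median absolute deviation (MADe)
#'
#' `1.4826 * median(|v - median(v)|)`: a robust estimator of the standard
#' deviation (the constant makes it consistent for normal data).
#'
#' @param values Numeric vector with at least one value.
#' @return Nonnegative scalar.
#' @export
mad_e <- function(values) {
  if (!length(values)) stop("mad_e needs at least one value")
  1.4826 * median(abs(values - median(values)))
}

#' Predict consensus EES mobile-phase profiles
#'
#' Each member network predicts a full 9-point profile per compound; the
#' consensus reports the member median and MADe per cell, flags a mobile
#' phase feasible when the median EES meets the acceptability threshold, and
#' nominates the feasible mobile phase with the highest median EES (ties go
#' to the lowest index). Compounds with no feasible mobile phase get no
#' nomination (a flat, unresolvable profile).
#'
#' @param model A [build_consensus()] result.
#' @param x_new Descriptor matrix in original units.
#' @param grid Mobile-phase grid.
#' @return Data frame of class `profile_prediction` with one row per
#'   compound x mobile phase and columns `compound_id`, `mp_index`,
#'   `acn_percent`, `ees_median`, `ees_made`, `feasible`, `nominated`.
#' @export
consensus_predict <- function(model, x_new, grid = mobile_phase_grid()) {
  preds <- lapply(model$members, predict_ann, x_new = x_new,
                  params = model$params)
  n <- nrow(preds[[1]]); nmp <- ncol(preds[[1]])
  arr <- array(unlist(preds), dim = c(n, nmp, length(preds)))
  med <- apply(arr, c(1, 2), median)
  made <- apply(arr, c(1, 2), mad_e)
  ids <- rownames(unclass(x_new))
  if (is.null(ids)) ids <- paste0("compound_", seq_len(n))

  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    feas <- is_acceptable(med[i, ], model$params)
    nom <- rep(FALSE, nmp)
    if (any(feas)) {
      cand <- which(feas)
      nom[cand[which.max(med[i, cand])]] <- TRUE
    }
    data.frame(compound_id = ids[i], mp_index = grid$mp_index,
               acn_percent = grid$acn_percent,
               ees_median = med[i, ], ees_made = made[i, ],
               feasible = feas, nominated = nom)
  }))
  rownames(out) <- NULL
  class(out) <- c("profile_prediction", class(out))
  out
}

#' Nominated mobile phase per compound
#'
#' @param profiles A [consensus_predict()] result.
#' @return Named integer vector of nominated mobile-phase indices (NA where
#'   no mobile phase is feasible).
#' @export
nominated_mp <- function(profiles) {
  ids <- unique(profiles$compound_id)
  vapply(ids, function(id) {
    rows <- profiles[profiles$compound_id == id, ]
    if (any(rows$nominated)) rows$mp_index[rows$nominated][1] else NA_integer_
  }, integer(1))
}
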