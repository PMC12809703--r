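#' Penalized determination index Q for one subset
#'
#' `Q = Rsign^2 - |1 - b1| - |b0|`, where `Rsign^2 = R * |R|` with R the
#' Pearson correlation between predictions and targets, and `b1`, `b0` the
#' slope and intercept of the ordinary least-squares regression of `y`
#' (predictions) on `t` (targets). Q is maximized (Q = 1) only by a strong,
#' approximately unbiased fit (b1 ~ 1, b0 ~ 0).
#'
#' @param y Numeric vector of predictions.
#' @param t Numeric vector of targets, aligned with `y`.
#' @param worst Value returned (with attribute `degenerate = TRUE`) when the
#'   correlation is undefined because `t` or `y` is constant. Default -3,
#'   keeping degenerate candidates comparable instead of failing.
#' @return The Q value, with attribute `degenerate`.
#' @export
q_index <- function(y, t, worst = -3) {
  if (length(y) != length(t)) stop("y and t must have equal length")
  if (length(y) < 3) stop("q_index needs at least 3 paired values")
  if (sd(t) == 0 || sd(y) == 0) {
    return(structure(worst, degenerate = TRUE))
  }
  r <- cor(y, t)
  b1 <- cov(y, t) / var(t)
  b0 <- mean(y) - b1 * mean(t)
  structure(r * abs(r) - abs(1 - b1) - abs(b0), degenerate = FALSE)
}

#' Overfitting-penalized quality pQ across the three subsets
#'
#' `pQ = 100 * (mQ - p_overfit * sQ)` where mQ and sQ are the mean and sample
#' standard deviation of the training, validation and internal-test Q values.
#' The spread term discourages subset-to-subset instability (overfitting).
#'
#' @param q_tr,q_va,q_it Q values per subset (see [q_index()]).
#' @param p_overfit Overfitting penalty weight (default 2).
#' @return The pQ value (at most 100).
#' @export
pq_metric <- function(q_tr, q_va, q_it, p_overfit = 2) {
  q <- c(as.numeric(q_tr), as.numeric(q_va), as.numeric(q_it))
  if (any(!is.finite(q))) stop("pq_metric needs three finite Q values")
  100 * (mean(q) - p_overfit * sd(q))
}

#' Grade absolute prediction errors into severity levels per subset
#'
#' Each prediction cell contributes to at most one level based on its
#' absolute error `e = |y - t|` in EES units: Level 1 when `0.2 < e < 0.4`,
#' Level 2 when `0.4 <= e < 0.6`, Level 3 when `e >= 0.6`; errors of at most
#' 0.2 are not counted.
#'
#' @param y,t Numeric vectors of predictions and targets (descaled EES
#'   units), aligned.
#' @param subsets Character vector of subset labels (`"tr"`, `"va"`, `"it"`,
#'   case-insensitive), aligned with `y`.
#' @return Named integer vector of class `error_level_counts` with elements
#'   `tr1, tr2, tr3, va1, va2, va3, it1, it2, it3`.
#' @export
error_levels <- function(y, t, subsets) {
  if (length(y) != length(t) || length(y) != length(subsets)) {
    stop("y, t and subsets must be aligned")
  }
  subsets <- tolower(as.character(subsets))
  bad <- setdiff(unique(subsets), c("tr", "va", "it"))
  if (length(bad)) stop("unknown subset label '", bad[1], "'")
  e <- snap(abs(y - t))
  lvl <- ifelse(e >= 0.6, 3L, ifelse(e >= 0.4, 2L, ifelse(e > 0.2, 1L, 0L)))
  counts <- integer(9)
  names(counts) <- c("tr1", "tr2", "tr3", "va1", "va2", "va3",
                     "it1", "it2", "it3")
  for (s in c("tr", "va", "it")) {
    for (l in 1:3) {
      counts[paste0(s, l)] <- sum(subsets == s & lvl == l)
    }
  }
  structure(counts, class = c("error_level_counts", "integer"))
}

#' Weighted error penalty pE
#'
#' `pE = 0.1*(Tr1+Va1+IT1) + 0.2*Tr2 + 0.3*Tr3 + 1*Va2 + 1.5*Va3 + 2*IT2 +
#' 3*IT3`: larger errors and more critical subsets (IT > Va > Tr) weigh
#' more heavily.
#'
#' @param counts An [error_levels()] result (or named vector with the same
#'   element names).
#' @return The nonnegative pE value.
#' @export
pe_metric <- function(counts) {
  counts <- unclass(counts)
  if (any(counts < 0)) stop("error-level counts must be >= 0")
  0.1 * (counts[["tr1"]] + counts[["va1"]] + counts[["it1"]]) +
    0.2 * counts[["tr2"]] + 0.3 * counts[["tr3"]] +
    1.0 * counts[["va2"]] + 1.5 * counts[["va3"]] +
    2.0 * counts[["it2"]] + 3.0 * counts[["it3"]]
}

#' Combined optimizer objective Fobj
#'
#' Balances fit quality against graded errors. Under the default `"penalty"`
#' convention `Fobj = w*pQ - (1-w)*pE`, so higher Fobj means strong,
#' stable fit and low error, and the optimizer maximizes it. The `"literal"`
#' convention `Fobj = w*pQ + (1-w)*pE` is available for comparison but
#' rewards error and is not recommended.
#'
#' @param pq The pQ value.
#' @param pe The pE value.
#' @param w Weight on pQ, in `[0, 1]` (default 0.5, equal weighting).
#' @param pe_sign `"penalty"` (default) or `"literal"`.
#' @return The Fobj value.
#' @export
fobj <- function(pq, pe, w = 0.5, pe_sign = c("penalty", "literal")) {
  pe_sign <- match.arg(pe_sign)
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (!is.finite(pq) || !is.finite(pe)) stop("pq and pe must be finite")
  if (pe_sign == "penalty") w * pq - (1 - w) * pe else w * pq + (1 - w) * pe
}

#' Objective weights container
#'
#' @param w Weight on pQ in Fobj (default 0.5).
#' @param p_overfit Overfitting penalty in pQ (default 2).
#' @param pe_sign Sign convention for pE in Fobj; see [fobj()].
#' @param worst_q Q value assigned to degenerate (constant) prediction or
#'   target vectors (default -3).
#' @return A list of class `objective_weights`.
#' @export
objective_weights <- function(w = 0.5, p_overfit = 2,
                              pe_sign = c("penalty", "literal"),
                              worst_q = -3) {
  pe_sign <- match.arg(pe_sign)
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  structure(list(w = w, p_overfit = p_overfit, pe_sign = pe_sign,
                 worst_q = worst_q),
            class = "objective_weights")
}

#' @importFrom stats cov var
NULL
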