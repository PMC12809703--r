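#' Parameters governing the EES computation
#'
#' Bundles the penalty factor and practical rules for the Efficient
#' Enantioseparation metric: `EES = Rs - p * max(0, k2 - k2lim)`, evaluated
#' after rounding the inputs to one decimal, truncating k2 at `k2_cap` and
#' capping Rs at `rs_cap`, and floored at `floor`. EES >= `threshold` marks a
#' mobile phase as practically acceptable.
#'
#' @param p Dimensionless penalty factor (default 45).
#' @param k2lim Maximum acceptable retention factor of the most-retained
#'   enantiomer (default 20).
#' @param k2_cap Truncation applied to k2 before the penalty (default 30).
#' @param rs_cap Cap applied to Rs (default 6).
#' @param floor Minimum EES value (default -1).
#' @param decimals Decimal places the raw Rs and k2 are rounded to,
#'   half-away-from-zero (default 1).
#' @param threshold Acceptable-EES cutoff (default 1.3).
#' @return A list of class `ees_params`.
#' @export
ees_params <- function(p = 45, k2lim = 20, k2_cap = 30, rs_cap = 6,
                       floor = -1, decimals = 1, threshold = 1.3) {
  if (p < 0) stop("p must be >= 0")
  if (!(k2lim > 0 && k2lim <= k2_cap)) stop("need 0 < k2lim <= k2_cap")
  if (!(rs_cap > threshold && threshold > 0)) stop("need rs_cap > threshold > 0")
  if (!(floor < threshold)) stop("need floor < threshold")
  structure(
    list(p = p, k2lim = k2lim, k2_cap = k2_cap, rs_cap = rs_cap,
         floor = floor, decimals = decimals, threshold = threshold),
    class = "ees_params"
  )
}

# round half away from zero, the convention of chromatographic reporting
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# snap away sub-nanoscale binary-representation noise so that decimal-grid
# inputs compare exactly against decimal thresholds (e.g. 4.3 - 10*(20.3-20)
# must equal 1.3, not 1.2999999999999928)
snap <- function(x) round(x, 9)

#' Compute the Efficient Enantioseparation (EES) value
#'
#' Applies, in order: rounding of Rs and k2 to `params$decimals`; capping of
#' Rs at `rs_cap` and truncation of k2 at `k2_cap`; the penalized formula
#' `Rs - p * max(0, k2 - k2lim)`; and the floor. The result always lies in
#' `[floor, rs_cap]` and equals the capped Rs whenever the rounded k2 does
#' not exceed `k2lim`. Vectorized over `rs` and `k2`.
#'
#' @param rs Enantioresolution value(s), >= 0.
#' @param k2 Retention factor(s) of the most-retained enantiomer, >= 0.
#' @param params An [ees_params()] object.
#' @return Numeric vector of EES values.
#' @examples
#' compute_ees(3.1, 51.2)   # resolved but impractically retained: -1
#' compute_ees(2.0, 10.0)   # fast enough: EES equals Rs
#' @export
compute_ees <- function(rs, k2, params = ees_params()) {
  if (any(rs < 0) || any(k2 < 0)) stop("rs and k2 must be >= 0")
  rs <- pmin(round_half_away(rs, params$decimals), params$rs_cap)
  k2 <- pmin(round_half_away(k2, params$decimals), params$k2_cap)
  ees <- snap(rs - params$p * pmax(0, k2 - params$k2lim))
  pmax(ees, params$floor)
}

#' Is an EES value practically acceptable?
#'
#' @param ees EES value(s).
#' @param params An [ees_params()] object; the cutoff is `params$threshold`
#'   and the boundary is inclusive.
#' @return Logical vector, `TRUE` where `ees >= threshold`.
#' @export
is_acceptable <- function(ees, params = ees_params()) {
  snap(ees) >= params$threshold
}

#' Build the EES target matrix from chromatographic records
#'
#' Each compound must have exactly one (Rs, k2) record per mobile-phase index
#' 1-9; cell (compound, mp) of the result is [compute_ees()] applied to that
#' record.
#'
#' @param records A `chromatogram_records` table (see [read_matrix()]).
#' @param params An [ees_params()] object.
#' @param grid Mobile-phase grid, [mobile_phase_grid()].
#' @return Numeric matrix (n_compounds x 9) of class `target_matrix`, columns
#'   `mp1..mp9`, compound ids as row names, row order following first
#'   appearance in `records`.
#' @export
build_target_matrix <- function(records, params = ees_params(),
                                grid = mobile_phase_grid()) {
  ids <- unique(records$compound_id)
  nmp <- nrow(grid)
  key <- paste(records$compound_id, records$mp_index)
  if (anyDuplicated(key)) {
    stop("duplicate chromatogram record for (",
         key[duplicated(key)][1], ")")
  }
  tab <- table(records$compound_id)
  short <- names(tab)[tab != nmp]
  if (length(short)) {
    have <- records$mp_index[records$compound_id == short[1]]
    stop("compound '", short[1], "' is missing mobile phase(s) ",
         paste(setdiff(grid$mp_index, have), collapse = ", "))
  }
  m <- matrix(NA_real_, nrow = length(ids), ncol = nmp,
              dimnames = list(ids, paste0("mp", grid$mp_index)))
  m[cbind(match(records$compound_id, ids), records$mp_index)] <-
    compute_ees(records$rs, records$k2, params)
  class(m) <- c("target_matrix", class(m))
  m
}

ees_grid_values <- function(params) {
  step <- 10^(-params$decimals)
  list(
    rs = snap(seq(0, params$rs_cap, by = step)),
    k2 = snap(seq(0, params$k2_cap, by = step))
  )
}

#' False-positive rate of the EES rule for a given penalty factor
#'
#' A false positive is a (Rs, k2) condition scored acceptable
#' (EES >= threshold) although its rounded k2 exceeds `k2lim`. In
#' `"enumerate"` mode every one-decimal pair with Rs in `[0, rs_cap]` and k2
#' in `[0, k2_cap]` is evaluated exactly once (61 x 301 = 18361 cells at the
#' defaults), which is exact and deterministic. In `"montecarlo"` mode
#' `n_draws` pairs are drawn uniformly from the same grids under `seed`.
#'
#' @param p Penalty factor to test (overrides `params$p`).
#' @param params An [ees_params()] object.
#' @param mode `"enumerate"` or `"montecarlo"`.
#' @param n_draws Number of draws in Monte-Carlo mode.
#' @param seed Integer seed for Monte-Carlo mode.
#' @return A list of class `fp_report` with fields `p`, `rate_percent`,
#'   `n_evaluated`, `n_false_positive`, `mode`.
#' @export
simulate_false_positive_rate <- function(p, params = ees_params(),
                                         mode = c("enumerate", "montecarlo"),
                                         n_draws = 1e6, seed = 1) {
  mode <- match.arg(mode)
  pars <- params
  pars$p <- p
  g <- ees_grid_values(pars)
  if (mode == "enumerate") {
    rs <- rep(g$rs, times = length(g$k2))
    k2 <- rep(g$k2, each = length(g$rs))
  } else {
    if (n_draws < 1) stop("n_draws must be >= 1 in montecarlo mode")
    rs <- with_local_seed(seed, sample(g$rs, n_draws, replace = TRUE))
    k2 <- with_local_seed(seed + 1L, sample(g$k2, n_draws, replace = TRUE))
  }
  ees <- compute_ees(rs, k2, pars)
  fp <- is_acceptable(ees, pars) & snap(k2) > pars$k2lim
  structure(
    list(p = p, rate_percent = 100 * sum(fp) / length(fp),
         n_evaluated = length(fp), n_false_positive = sum(fp), mode = mode),
    class = "fp_report"
  )
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("EES false-positive report (p = %g, %s mode)\n", x$p, x$mode))
  cat(sprintf("  %d / %d cells -> %.4f%%\n",
              x$n_false_positive, x$n_evaluated, x$rate_percent))
  invisible(x)
}

#' Select the smallest penalty factor meeting a false-positive bound
#'
#' Evaluates candidates in ascending order by exhaustive enumeration and
#' returns the first whose false-positive percentage does not exceed
#' `target_rate_percent`.
#'
#' @param candidates Ascending integer vector of penalty factors to try.
#' @param target_rate_percent Upper bound on the false-positive percentage.
#' @param params An [ees_params()] object.
#' @return The selected penalty factor.
#' @export
select_penalty_factor <- function(candidates, target_rate_percent,
                                  params = ees_params()) {
  if (is.unsorted(candidates)) stop("candidates must be sorted ascending")
  for (p in candidates) {
    rep <- simulate_false_positive_rate(p, params, mode = "enumerate")
    if (rep$rate_percent <= target_rate_percent) return(p)
  }
  stop("no candidate penalty factor achieves a false-positive rate <= ",
       target_rate_percent, "%")
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
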