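#' Configuration for the synthetic screening-data generator
#'
#' The generator emulates the structure of a chiral HPLC screening campaign:
#' a mixed count/binary/continuous molecular-descriptor matrix with a known
#' informative subset, and per-compound (Rs, k2) measurements across the
#' nine-point acetonitrile gradient in which retention decays with organic
#' fraction and only a minority of compounds is resolvable.
#'
#' @param n_compounds Number of compounds (default 76).
#' @param n_descriptors Number of descriptor columns (default 62).
#' @param n_informative Number of descriptors carrying signal (default 5;
#'   always the first columns).
#' @param resolved_fraction Target share of compounds with at least one
#'   acceptable EES (default 0.3, reflecting the majority-unresolved class
#'   balance typical of a single chiral column).
#' @param noise_sd Measurement noise on Rs and log-k2 (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_compounds = 76L, n_descriptors = 62L,
                           n_informative = 5L, resolved_fraction = 0.3,
                           noise_sd = 0.05, seed = 1L) {
  if (n_informative > n_descriptors) stop("n_informative > n_descriptors")
  if (resolved_fraction < 0 || resolved_fraction > 1) {
    stop("resolved_fraction must be in [0, 1]")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative = as.integer(n_informative),
                 resolved_fraction = resolved_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a synthetic descriptor matrix
#'
#' Informative columns (the first `n_informative`) are continuous standard
#' normals; the remaining columns cycle through small-integer counts
#' (emulating topological counts around a chiral center), binary flags, and
#' continuous noise. Fully reproducible from the seed.
#'
#' @param cfg A [fixture_config()].
#' @return A list with `descriptors` (matrix with compound ids as row names,
#'   columns `x1..xV`) and `informative_mask` (logical).
#' @export
generate_descriptors <- function(cfg = fixture_config()) {
  n <- cfg$n_compounds; v <- cfg$n_descriptors; k <- cfg$n_informative
  with_local_seed(cfg$seed, {
    m <- matrix(NA_real_, n, v,
                dimnames = list(sprintf("C%03d", seq_len(n)),
                                paste0("x", seq_len(v))))
    for (j in seq_len(v)) {
      m[, j] <- if (j <= k) {
        rnorm(n)
      } else if (j %% 3 == 0) {
        as.numeric(rpois(n, lambda = 2))
      } else if (j %% 3 == 1) {
        as.numeric(rbinom(n, 1, 0.3))
      } else {
        rnorm(n)
      }
    }
    mask <- seq_len(v) <= k
    class(m) <- c("descriptor_matrix", class(m))
    list(descriptors = m, informative_mask = mask)
  })
}

softplus <- function(x) log1p(exp(x))

#' Generate synthetic chromatographic records
#'
#' Two latent compound scores, both linear in the informative descriptors,
#' drive the chromatography: a retention score r and a chiral-recognition
#' score c. Retention follows a reversed-phase law, `k2 = exp(a0 + 0.9 r -
#' 4.5 (acn - 0.3))` plus log-normal noise, so retention decays with
#' acetonitrile fraction and a tail of compounds exceeds the retention limit
#' at the most aqueous mobile phases. Resolution is gated at compound level:
#' the top `resolved_fraction` of compounds by c get `Rs = 2.6 softplus(c)
#' * hump(k2)` (a retention hump that vanishes as k2 goes to 0 and rolls off
#' at very long retention) plus noise; the rest get near-zero Rs. Rs and k2
#' are rounded to one decimal and truncated at zero; k1 is a stored
#' plausibility column, always at most k2.
#'
#' @param descriptors Descriptor matrix.
#' @param informative_mask Logical vector marking informative columns.
#' @param cfg A [fixture_config()].
#' @param grid Mobile-phase grid.
#' @return A `chromatogram_records` data frame (9 rows per compound).
#' @export
generate_chromatograms <- function(descriptors, informative_mask,
                                   cfg = fixture_config(),
                                   grid = mobile_phase_grid()) {
  x <- unclass(descriptors)
  xi <- x[, informative_mask, drop = FALSE]
  n <- nrow(x)
  with_local_seed(cfg$seed + 1L, {
    # latent weights with magnitude bounded away from zero, so every
    # informative descriptor genuinely carries signal
    k <- ncol(xi)
    wr <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.6, 1.4)
    wc <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.6, 1.4)
    r <- as.vector(scale(xi %*% wr))
    cc <- as.vector(scale(xi %*% wc))
    n_res <- round(n * cfg$resolved_fraction)
    gate <- rank(cc, ties.method = "first") > n - n_res

    acn <- grid$acn_percent / 100
    recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
      logk2 <- 1.8 + 0.9 * r - 4.5 * (acn[j] - 0.3) +
        rnorm(n, sd = cfg$noise_sd)
      k2 <- exp(logk2)
      hump <- (k2 / (k2 + 1.5)) * exp(-k2 / 35)
      rs <- ifelse(gate,
                   pmax(0, 2.6 * softplus(cc) * hump +
                          rnorm(n, sd = cfg$noise_sd)),
                   abs(rnorm(n, sd = 0.06)))
      k2 <- round_half_away(pmax(k2, 0), 1)
      data.frame(compound_id = rownames(x),
                 mp_index = grid$mp_index[j],
                 rs = round_half_away(rs, 1),
                 k2 = k2,
                 k1 = round_half_away(k2 * runif(n, 0.55, 0.95), 1))
    }))
    recs <- recs[order(match(recs$compound_id, rownames(x)), recs$mp_index), ]
    rownames(recs) <- NULL
    chromatogram_records(recs)
  })
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_descriptors()], [generate_chromatograms()] and
#' [build_target_matrix()]; optionally writes the CSV bundle plus a
#' ground-truth JSON to a directory.
#'
#' @param cfg A [fixture_config()].
#' @param params An [ees_params()] used to build the target matrix.
#' @param dir Optional output directory for `descriptors.csv`,
#'   `chromatograms.csv`, `target.csv` and `ground_truth.json`.
#' @return A list of class `fixture_dataset` with `descriptors`,
#'   `chromatograms`, `target`, `informative_mask` and `config`.
#' @export
generate_dataset <- function(cfg = fixture_config(), params = ees_params(),
                             dir = NULL) {
  d <- generate_descriptors(cfg)
  recs <- generate_chromatograms(d$descriptors, d$informative_mask, cfg)
  target <- build_target_matrix(recs, params)
  ds <- structure(list(descriptors = d$descriptors, chromatograms = recs,
                       target = target,
                       informative_mask = d$informative_mask, config = cfg),
                  class = "fixture_dataset")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(d$descriptors, file.path(dir, "descriptors.csv"), "descriptor")
    write_matrix(recs, file.path(dir, "chromatograms.csv"), "chromatogram")
    write_matrix(target, file.path(dir, "target.csv"), "target")
    jsonlite::write_json(
      list(informative_descriptors = which(d$informative_mask),
           config = unclass(cfg)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  ds
}
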