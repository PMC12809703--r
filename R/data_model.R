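#' Mobile-phase grid
#'
#' The nine buffer/acetonitrile mobile phases used throughout the package,
#' indexed 1-9 by increasing acetonitrile content (30-98 % v/v).
#'
#' @return A data frame with columns `mp_index` (integer 1-9) and
#'   `acn_percent` (volume percent acetonitrile).
#' @examples
#' mobile_phase_grid()
#' @export
mobile_phase_grid <- function() {
  data.frame(
    mp_index = 1:9,
    acn_percent = c(30, 40, 50, 60, 70, 80, 90, 95, 98)
  )
}

n_mobile_phases <- function() 9L

#' Construct and validate a train/validation/internal-test split
#'
#' @param tr,va,it Integer vectors of 1-based compound indices for the
#'   training, validation and internal-test subsets.
#' @return A list of class `subset_split` with elements `tr`, `va`, `it`.
#' @seealso [validate_split()]
#' @export
subset_split <- function(tr, va, it) {
  structure(
    list(tr = as.integer(tr), va = as.integer(va), it = as.integer(it)),
    class = "subset_split"
  )
}

#' Validate a subset split against the dataset size and configured subset sizes
#'
#' The three subsets must be pairwise disjoint, jointly cover all compounds,
#' stay within `1..n_compounds`, and have the configured validation and
#' internal-test sizes (training takes the remainder).
#'
#' @param split A [subset_split()].
#' @param n_compounds Number of compounds in the dataset.
#' @param sizes Named numeric vector `c(va = ..., it = ...)` giving the
#'   required subset sizes. Default `c(va = 7, it = 3)`.
#' @return `split`, invisibly unchanged, if valid; otherwise an error stating
#'   which rule failed.
#' @export
validate_split <- function(split, n_compounds, sizes = c(va = 7, it = 3)) {
  stopifnot(inherits(split, "subset_split"))
  all_idx <- c(split$tr, split$va, split$it)
  if (anyNA(all_idx)) stop("split contains NA indices")
  if (any(all_idx < 1L | all_idx > n_compounds)) {
    stop("split contains out-of-range compound indices (valid range 1..",
         n_compounds, ")")
  }
  if (anyDuplicated(all_idx)) {
    stop("split subsets overlap: index ", all_idx[duplicated(all_idx)][1],
         " appears in more than one subset")
  }
  if (length(all_idx) != n_compounds) {
    stop("split does not cover all compounds: covers ", length(all_idx),
         " of ", n_compounds)
  }
  if (length(split$va) != sizes[["va"]]) {
    stop("validation subset has ", length(split$va),
         " compounds, expected ", sizes[["va"]])
  }
  if (length(split$it) != sizes[["it"]]) {
    stop("internal-test subset has ", length(split$it),
         " compounds, expected ", sizes[["it"]])
  }
  invisible(split)
}

# ---- CSV I/O ---------------------------------------------------------------

check_ids <- function(ids, what) {
  if (anyNA(ids) || any(ids == "")) stop(what, ": missing compound id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(what, ": duplicate compound id '", dup[1], "'")
  as.character(ids)
}

check_numeric_cols <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      stop(what, ": column '", cl, "' is not numeric")
    }
    if (anyNA(v)) {
      stop(what, ": missing value in column '", cl, "' (row ",
           which(is.na(v))[1], ")")
    }
  }
  invisible(df)
}

#' Read a descriptor matrix, target matrix, or chromatographic table from CSV
#'
#' Three schemas are supported. Descriptors: `compound_id,<name1>,...`
#' (one numeric column per descriptor). Targets: `compound_id,mp1,...,mp9`.
#' Chromatograms: `compound_id,mp_index,rs,k2[,k1]` with one row per
#' compound x mobile phase.
#'
#' @param path Path to a CSV file.
#' @param kind One of `"descriptor"`, `"target"`, `"chromatogram"`.
#' @return For `"descriptor"` and `"target"`, a numeric matrix with compound
#'   ids as row names (class `descriptor_matrix` / `target_matrix`); for
#'   `"chromatogram"`, a data frame of class `chromatogram_records`.
#' @export
read_matrix <- function(path, kind = c("descriptor", "target", "chromatogram")) {
  kind <- match.arg(kind)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicate column header '", names(df)[duplicated(names(df))][1],
         "' in ", path)
  }
  if (names(df)[1] != "compound_id") {
    stop("first column of ", path, " must be 'compound_id', found '",
         names(df)[1], "'")
  }
  switch(kind,
    descriptor = {
      ids <- check_ids(df$compound_id, "descriptor CSV")
      check_numeric_cols(df, names(df)[-1], "descriptor CSV")
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- ids
      class(m) <- c("descriptor_matrix", class(m))
      m
    },
    target = {
      expected <- paste0("mp", 1:9)
      if (!identical(names(df)[-1], expected)) {
        stop("target CSV must have columns compound_id,", paste(expected, collapse = ","))
      }
      ids <- check_ids(df$compound_id, "target CSV")
      check_numeric_cols(df, expected, "target CSV")
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- ids
      class(m) <- c("target_matrix", class(m))
      m
    },
    chromatogram = {
      need <- c("compound_id", "mp_index", "rs", "k2")
      if (!all(need %in% names(df))) {
        stop("chromatogram CSV must have columns ",
             paste(need, collapse = ","), "[,k1]")
      }
      check_numeric_cols(df, intersect(c("mp_index", "rs", "k2", "k1"), names(df)),
                         "chromatogram CSV")
      chromatogram_records(df)
    }
  )
}

#' Construct a validated table of chromatographic records
#'
#' @param df Data frame with columns `compound_id`, `mp_index`, `rs`, `k2`
#'   and optionally `k1` (retention factor of the least-retained enantiomer,
#'   stored but unused by the EES computation).
#' @return The validated data frame with class `chromatogram_records`.
#' @export
chromatogram_records <- function(df) {
  if (any(df$mp_index != as.integer(df$mp_index)) ||
      any(df$mp_index < 1 | df$mp_index > n_mobile_phases())) {
    stop("mp_index must be an integer in 1..9 (row ",
         which(df$mp_index < 1 | df$mp_index > 9 |
               df$mp_index != as.integer(df$mp_index))[1], ")")
  }
  if (any(df$rs < 0)) stop("rs must be >= 0 (row ", which(df$rs < 0)[1], ")")
  if (any(df$k2 < 0)) stop("k2 must be >= 0 (row ", which(df$k2 < 0)[1], ")")
  if (!is.null(df$k1) && any(df$k1 > df$k2)) {
    stop("k1 must not exceed k2 (row ", which(df$k1 > df$k2)[1], ")")
  }
  df$compound_id <- as.character(df$compound_id)
  df$mp_index <- as.integer(df$mp_index)
  class(df) <- unique(c("chromatogram_records", class(df)))
  df
}

#' Write a descriptor/target matrix or chromatogram table to CSV
#'
#' Inverse of [read_matrix()]; round-trips numerically (values are written
#' with full precision).
#'
#' @param x Object returned by [read_matrix()] or built by the package.
#' @param path Output CSV path.
#' @param kind Schema to write; see [read_matrix()].
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, kind = c("descriptor", "target", "chromatogram")) {
  kind <- match.arg(kind)
  if (kind == "chromatogram") {
    df <- as.data.frame(x)
  } else {
    df <- data.frame(compound_id = rownames(x), check.names = FALSE)
    df <- cbind(df, as.data.frame(unclass(x), check.names = FALSE))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Autoscaling -----------------------------------------------------------

#' Column-wise autoscaling (z-scoring)
#'
#' Centers each column by its mean and scales by its sample (n-1) standard
#' deviation. Constant columns are mapped to all-zeros and their scale is
#' recorded as 0, so [descale()] restores the constant exactly.
#'
#' @param m Numeric matrix with at least 2 rows.
#' @return A list with elements `x` (the scaled matrix), `center` (per-column
#'   means) and `scale` (per-column standard deviations; 0 for constant
#'   columns).
#' @export
autoscale <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) < 2L) stop("autoscale needs a matrix with >= 2 rows")
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 0
  div <- ifelse(scl == 0, 1, scl)
  x <- sweep(sweep(m, 2, ctr, "-"), 2, div, "/")
  x[, scl == 0] <- 0
  list(x = x, center = ctr, scale = scl)
}

#' Invert autoscaling
#'
#' @param scaled Numeric matrix in autoscaled units.
#' @param params List with `center` and `scale` as returned by [autoscale()].
#' @return Matrix in original units (`scaled * scale + center` per column;
#'   columns with recorded scale 0 restore the stored center).
#' @export
descale <- function(scaled, params) {
  scaled <- unclass(scaled)
  if (ncol(scaled) != length(params$center)) {
    stop("descale: matrix has ", ncol(scaled), " columns but scaler has ",
         length(params$center))
  }
  sweep(sweep(scaled, 2, params$scale, "*"), 2, params$center, "+")
}

apply_scaler <- function(m, params) {
  if (ncol(m) != length(params$center)) {
    stop("scaler mismatch: matrix has ", ncol(m), " columns, scaler ",
         length(params$center))
  }
  div <- ifelse(params$scale == 0, 1, params$scale)
  x <- sweep(sweep(unclass(m), 2, params$center, "-"), 2, div, "/")
  x[, params$scale == 0] <- 0
  x
}
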