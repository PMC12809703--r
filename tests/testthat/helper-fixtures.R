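# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_dataset <- function(seed = 1L) {
  cached(paste0("ds_", seed), generate_dataset(fixture_config(seed = seed)))
}

# brute-force per-cell error grader, kept deliberately naive and independent
# of error_levels()
brute_force_levels <- function(y, t, subsets) {
  counts <- setNames(integer(9), c("tr1", "tr2", "tr3", "va1", "va2", "va3",
                                   "it1", "it2", "it3"))
  for (i in seq_along(y)) {
    e <- round(abs(y[i] - t[i]), 9)
    lev <- if (e >= 0.6) 3 else if (e >= 0.4) 2 else if (e > 0.2) 1 else 0
    if (lev > 0) {
      key <- paste0(subsets[i], lev)
      counts[key] <- counts[key] + 1L
    }
  }
  counts
}

brute_force_pe <- function(counts) {
  w <- c(tr1 = 0.1, tr2 = 0.2, tr3 = 0.3, va1 = 0.1, va2 = 1, va3 = 1.5,
         it1 = 0.1, it2 = 2, it3 = 3)
  sum(w[names(counts)] * counts)
}

# small descriptor/target pair with a purely linear signal in one column
linear_toy <- function(n = 40, seed = 7) {
  set.seed(seed)
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  t <- matrix(rep(2 * x[, "a"] + 1, 9), ncol = 9)
  colnames(t) <- paste0("mp", 1:9)
  list(x = x, t = t)
}

toy_split <- function(n, va = 7, it = 3, seed = 5) {
  set.seed(seed)
  idx <- sample.int(n, va + it)
  subset_split(setdiff(seq_len(n), idx), idx[seq_len(va)],
               idx[va + seq_len(it)])
}
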