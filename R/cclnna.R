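#' Optimizer configuration
#'
#' Controls the chaotic competitive-learning population search over the
#' continuous `[0,1]` genome encoding split slots, topology and descriptor
#' switches.
#'
#' @param population Population size (default 250).
#' @param iterations Number of iterations (default 500).
#' @param seed Integer seed.
#' @param binarize_cutoff Threshold above which a descriptor-switch gene
#'   counts as "included" (default 0.8).
#' @param elitism Preserve the incumbent best across iterations (default
#'   TRUE; makes the best-so-far history non-decreasing).
#' @param attraction Scale of the pull toward the population best (default 0.9).
#' @param chaos_scale Initial amplitude of the local logistic-map kick
#'   (default 0.5; decays quadratically over the run to `chaos_floor`).
#' @param chaos_floor Final kick amplitude (default 0.02).
#' @param mutation_rate_range Start and end of the per-gene kick probability
#'   schedule (default `c(1, 0.15)`; late iterations perturb only a small
#'   random subset of genes, which sharpens convergence).
#' @param jump_prob Per-gene probability that the loser of a competitive
#'   pair has a gene replaced outright by the chaotic state (default 0.25).
#'   The logistic map's invariant (arcsine) density concentrates near 0 and
#'   1, so loser jumps can carry a descriptor switch across the binarization
#'   cutoff at any stage of the run, while winners keep refining with small
#'   local kicks.
#' @param regen_prob Probability that the loser of a competitive pair whose
#'   proposal also failed is regenerated at random (default 0.05).
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(population = 250L, iterations = 500L, seed = 1L,
                             binarize_cutoff = 0.8, elitism = TRUE,
                             attraction = 0.9, chaos_scale = 0.5,
                             chaos_floor = 0.02,
                             mutation_rate_range = c(1, 0.15),
                             jump_prob = 0.25, regen_prob = 0.05) {
  if (population < 2L) stop("population must be >= 2")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (binarize_cutoff <= 0 || binarize_cutoff >= 1) {
    stop("binarize_cutoff must be in (0, 1)")
  }
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 binarize_cutoff = binarize_cutoff, elitism = isTRUE(elitism),
                 attraction = attraction, chaos_scale = chaos_scale,
                 chaos_floor = chaos_floor,
                 mutation_rate_range = mutation_rate_range,
                 jump_prob = jump_prob, regen_prob = regen_prob),
            class = "optimizer_config")
}

genome_length <- function(n_descriptors, va_size = 7L, it_size = 3L) {
  as.integer(va_size + it_size + 2L + n_descriptors)
}

#' Decode a continuous genome into a split, topology and feature mask
#'
#' Genome layout (74 genes for 62 descriptors): positions 1-10 are split
#' slots (7 validation + 3 internal-test compounds), 11-12 the topology, and
#' 13 onward the descriptor switches. Split slots map to distinct compound
#' indices by `floor(g * n)` with forward-cyclic collision repair; topology
#' genes map linearly (`n1 = 1 + round(g * 29)`, `n2 = round(g * 30)`);
#' switch genes at or above the cutoff include the descriptor, and if none
#' passes, the single highest-gene descriptor is included.
#'
#' @param vec Numeric genome in `[0,1]`.
#' @param n_compounds Number of compounds (> va + it slots).
#' @param n_descriptors Number of descriptor switches.
#' @param cutoff Binarization cutoff (default 0.8).
#' @param va_size,it_size Validation / internal-test subset sizes (7 / 3).
#' @return A list of class `decoded_candidate` with `split`, `topology` and
#'   `feature_mask`.
#' @export
decode_solution <- function(vec, n_compounds, n_descriptors, cutoff = 0.8,
                            va_size = 7L, it_size = 3L) {
  n_slots <- va_size + it_size
  expected <- genome_length(n_descriptors, va_size, it_size)
  if (length(vec) != expected) {
    stop("genome has length ", length(vec), ", expected ", expected)
  }
  if (any(vec < 0 | vec > 1)) stop("genome values must lie in [0, 1]")
  if (n_compounds <= n_slots) {
    stop("need more than ", n_slots, " compounds to decode a split")
  }

  # split slots: rank-unique decoding with forward-cyclic collision repair
  slots <- integer(n_slots)
  taken <- logical(n_compounds)
  for (i in seq_len(n_slots)) {
    idx <- min(floor(vec[i] * n_compounds), n_compounds - 1L) + 1L
    while (taken[idx]) idx <- if (idx == n_compounds) 1L else idx + 1L
    taken[idx] <- TRUE
    slots[i] <- idx
  }
  va <- slots[seq_len(va_size)]
  it <- slots[va_size + seq_len(it_size)]
  tr <- setdiff(seq_len(n_compounds), slots)

  n1 <- 1L + as.integer(round(vec[n_slots + 1L] * 29))
  n2 <- as.integer(round(vec[n_slots + 2L] * 30))

  switches <- vec[(n_slots + 3L):expected]
  mask <- switches >= cutoff
  if (!any(mask)) mask[which.max(switches)] <- TRUE

  structure(list(split = subset_split(tr, va, it),
                 topology = ann_topology(n1, n2),
                 feature_mask = mask),
            class = "decoded_candidate")
}

#' Evaluate one genome: decode, train a network, score it
#'
#' Decodes the genome, autoscales descriptors and targets over the full
#' dataset, trains the encoded network, back-transforms its predictions and
#' computes the per-subset Q values, pQ, graded error counts, pE, Fobj and
#' misclassification counts against the acceptability threshold.
#'
#' @param vec Numeric genome in `[0,1]`.
#' @param x Descriptor matrix in original units.
#' @param t Target matrix (EES units).
#' @param train_cfg A [training_config()].
#' @param weights An [objective_weights()].
#' @param params An [ees_params()] (threshold for misclassification counts).
#' @param cutoff Binarization cutoff for the switch genes.
#' @return A list with `model` (a fully annotated `trained_ann`) and `fobj`.
#' @export
evaluate_candidate <- function(vec, x, t, train_cfg = training_config(),
                               weights = objective_weights(),
                               params = ees_params(), cutoff = 0.8) {
  x <- unclass(x); t <- unclass(t)
  if (nrow(x) != nrow(t)) stop("x and t must be row-aligned")
  dec <- decode_solution(vec, nrow(x), ncol(x), cutoff = cutoff)

  xsc <- autoscale(x)
  tsc <- autoscale(t)
  xm <- xsc$x[, dec$feature_mask, drop = FALSE]

  model <- train_ann(xm, tsc$x, dec$split, dec$topology, train_cfg)
  model$feature_mask <- dec$feature_mask
  model$descriptor_names <- colnames(x)
  model$x_scaler <- list(center = xsc$center, scale = xsc$scale)
  model$t_scaler <- list(center = tsc$center, scale = tsc$scale)

  # objective uses unclipped descaled predictions
  y <- descale(forward_ann(model$weights, model$topology, xm), model$t_scaler)

  sub <- dec$split
  qs <- lapply(list(tr = sub$tr, va = sub$va, it = sub$it), function(idx) {
    q_index(as.vector(y[idx, ]), as.vector(t[idx, ]), worst = weights$worst_q)
  })
  pq <- pq_metric(qs$tr, qs$va, qs$it, p_overfit = weights$p_overfit)

  labels <- character(nrow(x))
  labels[sub$tr] <- "tr"; labels[sub$va] <- "va"; labels[sub$it] <- "it"
  cell_labels <- rep(labels, times = ncol(t))
  counts <- error_levels(as.vector(y), as.vector(t), cell_labels)
  pe <- pe_metric(counts)
  f <- fobj(pq, pe, w = weights$w, pe_sign = weights$pe_sign)

  mis <- vapply(list(tr = sub$tr, va = sub$va, it = sub$it), function(idx) {
    misclassification_count(as.vector(y[idx, ]), as.vector(t[idx, ]),
                            threshold = params$threshold)
  }, integer(1))

  model$metrics <- list(
    q = list(tr = as.numeric(qs$tr), va = as.numeric(qs$va),
             it = as.numeric(qs$it)),
    pq = pq, error_counts = unclass(counts), pe = pe, fobj = f,
    misclass = list(tr = mis[["tr"]], va = mis[["va"]], it = mis[["it"]],
                    total = sum(mis))
  )
  list(model = model, fobj = f)
}

#' Run the chaotic competitive-learning population search
#'
#' Maintains a population of genomes in `[0,1]^D`. Each iteration proposes,
#' for every member, a move combining attraction toward the population best,
#' a logistic-map chaotic perturbation (applied to a random subset of genes
#' whose size shrinks over the run), and — for the loser of a randomly drawn
#' competitive pair — an additional pull toward the pair winner. Proposals
#' replace their parent only when they score at least as well (competitive
#' replacement); losers whose proposal also failed may be regenerated at
#' random. The incumbent best is preserved (elitism), so the best-so-far
#' history is non-decreasing.
#'
#' @param x,t Descriptor and target matrices (ignored when `objective_fn` is
#'   supplied).
#' @param cfg An [optimizer_config()].
#' @param train_cfg A [training_config()] for candidate evaluation.
#' @param weights An [objective_weights()].
#' @param params An [ees_params()].
#' @param objective_fn Optional surrogate objective `function(vec) ->
#'   numeric` replacing network training (used for algorithm verification);
#'   when supplied, `n_genes` must be given too.
#' @param n_genes Genome length for surrogate runs.
#' @return A list of class `cclnna_run` with `best_model` (NULL for
#'   surrogate runs), `best_vec`, `best_fobj`, `history` (best-so-far Fobj
#'   per iteration) and `config`.
#' @export
cclnna_optimize <- function(x = NULL, t = NULL, cfg = optimizer_config(),
                            train_cfg = training_config(),
                            weights = objective_weights(),
                            params = ees_params(),
                            objective_fn = NULL, n_genes = NULL) {
  surrogate <- !is.null(objective_fn)
  if (surrogate) {
    if (is.null(n_genes)) stop("surrogate runs need n_genes")
    D <- as.integer(n_genes)
    evalf <- function(v) list(model = NULL, fobj = objective_fn(v))
  } else {
    if (is.null(x) || is.null(t)) stop("x and t are required")
    D <- genome_length(ncol(x))
    evalf <- function(v) {
      evaluate_candidate(v, x, t, train_cfg, weights, params,
                         cutoff = cfg$binarize_cutoff)
    }
  }

  P <- cfg$population
  with_local_seed(cfg$seed, {
    pop <- matrix(runif(P * D), P, D)
    Z <- matrix(runif(P * D, 0.1, 0.9), P, D)
    evals <- apply(pop, 1, evalf)
    fit <- vapply(evals, `[[`, numeric(1), "fobj")
    best_i <- which.max(fit)
    best_vec <- pop[best_i, ]
    best_fobj <- fit[best_i]
    best_model <- evals[[best_i]]$model

    history <- numeric(cfg$iterations)
    mr <- cfg$mutation_rate_range
    for (it in seq_len(cfg$iterations)) {
      frac <- it / cfg$iterations
      alpha <- cfg$chaos_scale * (1 - frac)^2 + cfg$chaos_floor
      mrate <- mr[1] + (mr[2] - mr[1]) * frac
      Z <- 4 * Z * (1 - Z)

      perm <- sample.int(P)
      pairing <- matrix(perm[seq_len(2L * (P %/% 2L))], ncol = 2)
      loser <- logical(P)
      winner_of <- integer(P)
      for (r in seq_len(nrow(pairing))) {
        a <- pairing[r, 1]; b <- pairing[r, 2]
        lo <- if (fit[a] < fit[b]) a else b
        loser[lo] <- TRUE
        winner_of[lo] <- if (lo == a) b else a
      }

      pull <- cfg$attraction * matrix(runif(P * D), P, D) *
        (matrix(best_vec, P, D, byrow = TRUE) - pop)
      kick <- matrix(runif(P * D) < mrate, P, D)
      cand <- pop + pull + alpha * (Z - 0.5) * kick
      if (any(loser)) {
        li <- which(loser)
        cand[li, ] <- cand[li, ] +
          0.5 * matrix(runif(length(li) * D), length(li), D) *
          (pop[winner_of[li], , drop = FALSE] - pop[li, , drop = FALSE])
        jump <- matrix(runif(length(li) * D) < cfg$jump_prob,
                       length(li), D)
        cand[li, ][jump] <- Z[li, , drop = FALSE][jump]
      }
      cand <- pmin(pmax(cand, 0), 1)

      for (i in seq_len(P)) {
        if (cfg$elitism && i == best_i) next
        ev <- evalf(cand[i, ])
        if (ev$fobj >= fit[i]) {
          pop[i, ] <- cand[i, ]
          fit[i] <- ev$fobj
          if (ev$fobj > best_fobj) {
            best_fobj <- ev$fobj
            best_vec <- pop[i, ]
            best_model <- ev$model
            best_i <- i
          }
        } else if (loser[i] && runif(1) < cfg$regen_prob) {
          pop[i, ] <- runif(D)
          ev2 <- evalf(pop[i, ])
          fit[i] <- ev2$fobj
          if (ev2$fobj > best_fobj) {
            best_fobj <- ev2$fobj
            best_vec <- pop[i, ]
            best_model <- ev2$model
            best_i <- i
          }
        }
      }
      history[it] <- best_fobj
    }

    structure(list(best_model = best_model, best_vec = best_vec,
                   best_fobj = best_fobj, history = history, config = cfg),
              class = "cclnna_run")
  })
}

#' Run several independent optimizations and archive the resulting networks
#'
#' @param x,t Descriptor and target matrices.
#' @param n_runs Number of independent optimizer runs (the full-scale study
#'   design uses 70).
#' @param base_seed Base seed; run r uses `base_seed + 1000 * (r - 1)`.
#' @param cfg,train_cfg,weights,params Configuration objects; `cfg$seed` is
#'   overridden per run.
#' @return A list of class `optimization_archive` with `models` (best
#'   network per run, sorted by Fobj descending), `fobj`, `seeds`,
#'   `histories` and `config`.
#' @export
run_batch <- function(x, t, n_runs, base_seed = 1L,
                      cfg = optimizer_config(), train_cfg = training_config(),
                      weights = objective_weights(), params = ees_params()) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  seeds <- as.integer(base_seed + 1000L * (seq_len(n_runs) - 1L))
  runs <- lapply(seeds, function(s) {
    run_cfg <- cfg
    run_cfg$seed <- s
    cclnna_optimize(x, t, run_cfg, train_cfg, weights, params)
  })
  f <- vapply(runs, `[[`, numeric(1), "best_fobj")
  ord <- order(f, decreasing = TRUE)
  models <- lapply(runs[ord], `[[`, "best_model")
  for (i in seq_along(models)) models[[i]]$run_seed <- seeds[ord][i]
  structure(list(models = models, fobj = f[ord], seeds = seeds[ord],
                 histories = lapply(runs[ord], `[[`, "history"),
                 config = cfg),
            class = "optimization_archive")
}
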