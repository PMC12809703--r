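test_that("genome length covers split slots, topology and switches", {
  expect_equal(eesprofiler:::genome_length(62), 74L)
  expect_equal(eesprofiler:::genome_length(10), 22L)
})

test_that("decoding maps switches, topology and split slots as specified", {
  vec <- rep(0.5, 74)
  vec[11:12] <- 0          # topology genes at the lower bound
  vec[13] <- 0.85          # switch just above the cutoff
  vec[14] <- 0.79          # switch just below
  dec <- decode_solution(vec, 76, 62)
  expect_true(dec$feature_mask[1])
  expect_false(dec$feature_mask[2])
  expect_equal(dec$topology$n1, 1L)
  expect_equal(dec$topology$n2, 0L)
  expect_silent(validate_split(dec$split, 76))

  # all-below-cutoff masks are repaired to the single strongest switch
  vec2 <- rep(0.1, 74); vec2[13] <- 0.7
  dec2 <- decode_solution(vec2, 76, 62)
  expect_identical(which(dec2$feature_mask), 1L)

  expect_error(decode_solution(rep(0.5, 73), 76, 62), "length")
  expect_error(decode_solution(rep(1.5, 74), 76, 62), "\\[0, 1\\]")
  expect_error(decode_solution(rep(0.5, 22), 10, 10), "more than 10")
})

test_that("decoded splits are always 7/3/66 and disjoint over random genomes", {
  set.seed(4)
  for (i in 1:2000) {
    vec <- runif(74)
    dec <- decode_solution(vec, 76, 62)
    expect_silent(validate_split(dec$split, 76))
    expect_gte(sum(dec$feature_mask), 1)
    expect_true(dec$topology$n1 >= 1 && dec$topology$n1 <= 30)
    expect_true(dec$topology$n2 >= 0 && dec$topology$n2 <= 30)
  }
})

test_that("candidate evaluation is deterministic and favors informative masks", {
  ds <- default_dataset()
  set.seed(31)
  vec <- runif(74)
  cfg <- training_config(max_epochs = 150)
  e1 <- evaluate_candidate(vec, ds$descriptors, ds$target, cfg)
  e2 <- evaluate_candidate(vec, ds$descriptors, ds$target, cfg)
  expect_identical(e1$fobj, e2$fobj)

  base <- rep(0.3, 74)
  set.seed(6); base[1:12] <- runif(12)
  informative <- base; informative[12 + 1:5] <- 0.9
  noise <- base; noise[12 + c(20, 30, 40, 50, 60)] <- 0.9
  fi <- evaluate_candidate(informative, ds$descriptors, ds$target, cfg)$fobj
  fn <- evaluate_candidate(noise, ds$descriptors, ds$target, cfg)$fobj
  expect_gt(fi, fn)
})

test_that("a perfectly predicted dataset scores pQ 100, pE 0, Fobj 50", {
  # composition check on the objective path with y == t
  y <- matrix(rnorm(27), 3)
  q <- as.numeric(q_index(as.vector(y), as.vector(y)))
  pq <- pq_metric(q, q, q)
  pe <- pe_metric(error_levels(as.vector(y), as.vector(y),
                               rep("tr", length(y))))
  expect_equal(fobj(pq, pe), 50)
})

test_that("surrogate optimization converges to the sphere optimum", {
  surr <- function(v) -sum((v - 0.5)^2)
  run <- cclnna_optimize(cfg = optimizer_config(population = 30,
                                                iterations = 200, seed = 3),
                         objective_fn = surr, n_genes = 74)
  expect_lt(max(abs(run$best_vec - 0.5)), 0.05)
  expect_true(all(run$best_vec >= 0 & run$best_vec <= 1))
  expect_length(run$history, 200)
  expect_true(all(diff(run$history) >= 0))
})

test_that("batch runs record distinct seeds and sort by objective", {
  surr <- function(v) -sum((v - 0.25)^2)
  ds <- default_dataset()
  cfg <- optimizer_config(population = 6, iterations = 4, seed = 1)
  tc <- training_config(max_epochs = 60)
  arch <- run_batch(ds$descriptors, ds$target, n_runs = 3, base_seed = 11,
                    cfg = cfg, train_cfg = tc)
  expect_length(arch$models, 3)
  expect_length(unique(arch$seeds), 3)
  expect_true(all(diff(arch$fobj) <= 0))

  arch2 <- run_batch(ds$descriptors, ds$target, n_runs = 3, base_seed = 11,
                     cfg = cfg, train_cfg = tc)
  expect_identical(arch$fobj, arch2$fobj)
  expect_identical(arch$models[[1]]$weights, arch2$models[[1]]$weights)
})
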