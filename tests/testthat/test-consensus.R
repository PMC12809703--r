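test_that("misclassification counts cells on opposite sides of the cutoff", {
  expect_equal(misclassification_count(1.2, 1.4), 1)
  expect_equal(misclassification_count(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(misclassification_count(c(1.4, 1.3, 0.0), c(0.5, 2.0, 1.3)), 2)
  # boundary counts as acceptable on both sides
  expect_equal(misclassification_count(1.3, 1.3), 0)
  expect_error(misclassification_count(1:2, 1:3), "equal length")
})

test_that("MADe is the scaled median absolute deviation", {
  expect_equal(mad_e(c(2, 2, 2)), 0)
  expect_equal(mad_e(c(1, 2, 3, 4, 100)), 1.4826)
  expect_equal(mad_e(c(-1, 0, 1)), 1.4826)
  expect_error(mad_e(numeric(0)), "at least one")
})

fake_model <- function(id, misclass, fobj, pe) {
  structure(list(metrics = list(misclass = list(total = misclass,
                                                tr = misclass, va = 0, it = 0),
                                fobj = fobj, pe = pe),
                 id = id),
            class = "trained_ann")
}

test_that("ranking orders by misclassification, then Fobj, pE, position", {
  arch <- structure(list(models = list(
    fake_model(1, 2, 40, 1), fake_model(2, 0, 30, 2),
    fake_model(3, 0, 45, 3), fake_model(4, 0, 45, 1)
  )), class = "optimization_archive")
  rk <- rank_models(arch)
  expect_equal(rk$table$model_id, c(4, 3, 2, 1))
  expect_error(rank_models(structure(list(models = list()),
                                     class = "optimization_archive")),
               "empty")
})

test_that("consensus building takes the top k with sane bounds", {
  arch <- structure(list(models = lapply(1:6, function(i)
    fake_model(i, i %% 3, 50 - i, 1))), class = "optimization_archive")
  rk <- rank_models(arch)
  cm <- build_consensus(rk, 5)
  expect_length(cm$members, 5)
  expect_identical(cm$members[[1]], rk$models[[1]])
  expect_error(build_consensus(rk, 1), "at least 2")
  expect_error(build_consensus(rk, 7), "exceeds")
  all_cm <- build_consensus(rk, 6)
  expect_length(all_cm$members, 6)
})

consensus_fixture <- function() {
  cached("consensus_fixture", {
    ds <- default_dataset()
    arch <- run_batch(ds$descriptors, ds$target, n_runs = 4, base_seed = 3,
                      cfg = optimizer_config(population = 8, iterations = 6),
                      train_cfg = training_config(max_epochs = 120))
    list(ds = ds, cm = build_consensus(rank_models(arch), 4))
  })
}

test_that("consensus profiles aggregate members by median and MADe", {
  fx <- consensus_fixture()
  x_new <- unclass(fx$ds$descriptors)[1:6, ]
  prof <- consensus_predict(fx$cm, x_new)
  expect_equal(nrow(prof), 6 * 9)
  expect_true(all(prof$ees_made >= 0))

  member_preds <- lapply(fx$cm$members, predict_ann, x_new = x_new)
  arr <- array(unlist(member_preds), dim = c(6, 9, 4))
  lo <- apply(arr, c(1, 2), min); hi <- apply(arr, c(1, 2), max)
  med <- matrix(prof$ees_median, 6, 9, byrow = TRUE)
  expect_true(all(med >= lo - 1e-12 & med <= hi + 1e-12))
  expect_equal(prof$feasible, prof$ees_median >= 1.3)
})

test_that("consensus prediction is invariant to member order", {
  fx <- consensus_fixture()
  x_new <- unclass(fx$ds$descriptors)[1:4, ]
  p1 <- consensus_predict(fx$cm, x_new)
  shuffled <- fx$cm
  shuffled$members <- shuffled$members[c(3, 1, 4, 2)]
  p2 <- consensus_predict(shuffled, x_new)
  expect_equal(p1, p2)
})

test_that("nomination picks the highest-median feasible mobile phase", {
  fx <- consensus_fixture()
  prof <- consensus_predict(fx$cm, fx$ds$descriptors)
  for (id in unique(prof$compound_id)) {
    rows <- prof[prof$compound_id == id, ]
    if (any(rows$feasible)) {
      expect_equal(sum(rows$nominated), 1)
      nom <- rows[rows$nominated, ]
      expect_equal(nom$ees_median, max(rows$ees_median[rows$feasible]))
    } else {
      # flat unresolvable profile: no nomination
      expect_equal(sum(rows$nominated), 0)
    }
  }
  noms <- nominated_mp(prof)
  expect_equal(sum(!is.na(noms)),
               sum(tapply(prof$feasible, prof$compound_id, any)[
                 unique(prof$compound_id)]))
})

test_that("all-members-agree cells have MADe exactly 0", {
  fx <- consensus_fixture()
  dup <- fx$cm
  dup$members <- rep(fx$cm$members[1], 3)
  prof <- consensus_predict(dup, unclass(fx$ds$descriptors)[1:3, ])
  expect_true(all(prof$ees_made == 0))
})
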