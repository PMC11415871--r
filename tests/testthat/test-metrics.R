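test_that("Dice handles identity, disjoint, partial overlap and empty masks", {
  m <- array(FALSE, c(10, 10, 10)); m[2:5, 2:5, 2:5] <- TRUE
  expect_identical(dice(m, m), 1)
  n <- array(FALSE, c(10, 10, 10)); n[7:9, 7:9, 7:9] <- TRUE
  expect_identical(dice(m, n), 0)

  # |A| = |B| = 100, overlap 50 -> 2*50/200 = 0.5
  a <- array(FALSE, c(20, 20, 20)); a[1:4, 1:5, 1:5] <- TRUE
  b <- array(FALSE, c(20, 20, 20)); b[3:6, 1:5, 1:5] <- TRUE
  expect_identical(sum(a), 100L)
  expect_identical(sum(a & b), 50L)
  expect_identical(dice(a, b), 0.5)

  empty <- array(FALSE, c(5, 5, 5))
  expect_identical(dice(empty, empty), 1)
  expect_error(dice(m, array(FALSE, c(9, 9, 9))), class = "vasarify_data_error")
})

test_that("Dice is symmetric on random masks", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_mask(c(8, 8, 8), runif(1, 0.1, 0.6))
    b <- random_mask(c(8, 8, 8), runif(1, 0.1, 0.6))
    expect_identical(dice(a, b), dice(b, a))
  }
})

test_that("kappa reproduces closed-form cases", {
  expect_identical(as.numeric(cohen_kappa(c(1, 2, 1, 2), c(1, 2, 1, 2))), 1)
  # alternating two-category disagreement: P_o = 0, P_e = 0.5 -> -1
  expect_equal(as.numeric(cohen_kappa(c(1, 2, 1, 2), c(2, 1, 2, 1))), -1)
  # 3-category linearly weighted example, hand-computed: kappa = 3/7
  expect_equal(as.numeric(cohen_kappa(c(1, 2, 3, 3), c(1, 3, 3, 2),
                                      weighting = "linear")), 3 / 7)
  k <- cohen_kappa(c(2, 2, 2), c(2, 2, 2))
  expect_identical(as.numeric(k), 1)
  expect_identical(attr(k, "flag"), "degenerate-identical")
})

test_that("kappa matches brute-force confusion recomputation on random pairs", {
  set.seed(22)
  for (i in 1:50) {
    k <- sample(2:5, 1); n <- sample(5:30, 1)
    x <- sample(seq_len(k), n, replace = TRUE)
    y <- sample(seq_len(k), n, replace = TRUE)
    for (w in c("none", "linear")) {
      got <- as.numeric(cohen_kappa(x, y, weighting = w, categories = 1:k))
      ref <- bf_kappa(x, y, weighting = w, categories = 1:k)
      if (is.na(ref)) expect_true(is.na(got) || got == 1)
      else expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("kappa is invariant under order-preserving relabelling", {
  set.seed(23)
  x <- sample(1:4, 40, replace = TRUE); y <- sample(1:4, 40, replace = TRUE)
  relab <- c(10, 20, 30, 40)   # equally spaced, order preserved
  expect_equal(as.numeric(cohen_kappa(x, y, "linear", categories = 1:4)),
               as.numeric(cohen_kappa(relab[x], relab[y], "linear",
                                      categories = relab)))
  expect_equal(as.numeric(cohen_kappa(x, y, "none", categories = 1:4)),
               as.numeric(cohen_kappa(relab[x], relab[y], "none",
                                      categories = relab)))
})

test_that("linear weights over the declared scale are globally scale-invariant", {
  # widening the declared category range rescales every linear weight by
  # the same factor, so the weighted kappa is unchanged; both declared
  # sets must still match the brute-force recomputation
  x <- c(1, 2, 2, 1, 3); y <- c(2, 1, 2, 1, 1)
  narrow <- as.numeric(cohen_kappa(x, y, "linear", categories = 1:3))
  wide <- as.numeric(cohen_kappa(x, y, "linear", categories = 1:6))
  expect_equal(narrow, bf_kappa(x, y, "linear", categories = 1:3))
  expect_equal(wide, bf_kappa(x, y, "linear", categories = 1:6))
  expect_equal(narrow, wide, tolerance = 1e-12)
})

test_that("balanced accuracy averages per-class recall", {
  expect_identical(balanced_accuracy(c("A", "B"), c("A", "B")), 1)
  # constant predictor on two balanced classes
  expect_identical(balanced_accuracy(c("A", "A", "B", "B"), rep("A", 4)), 0.5)
  # 6-case construction: recalls 1, 0.5, 0.5 -> 2/3
  expect_equal(balanced_accuracy(c("A", "A", "B", "B", "C", "C"),
                                 c("A", "A", "B", "C", "C", "B")), 2 / 3)
  expect_error(balanced_accuracy(character(), character()),
               class = "vasarify_data_error")
})

test_that("balanced accuracy matches brute force and plain accuracy when balanced", {
  set.seed(24)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    truth <- sample(c("A", "B", "C"), n, replace = TRUE)
    pred <- sample(c("A", "B", "C"), n, replace = TRUE)
    expect_equal(balanced_accuracy(truth, pred),
                 bf_balanced_accuracy(truth, pred))
  }
  # exactly balanced classes + class-symmetric predictor: equals accuracy
  truth <- rep(c("A", "B"), each = 10)
  pred <- truth; pred[c(1, 11)] <- c("B", "A")   # one error per class
  expect_equal(balanced_accuracy(truth, pred), mean(truth == pred))
})

test_that("equity stratification scores strata independently", {
  tabs <- make_rater_tables(120, rate = 0, seed = 42)
  strat <- equity_stratification(tabs$a, tabs$b, metric = "kappa")
  ok <- strat[strat$flag == "ok", ]
  expect_true(all(ok$value == 1))
  expect_true(all(strat$flag[strat$n < 2] == "insufficient"))
  expect_true(all(is.na(strat$value[strat$flag == "insufficient"])))

  # corrupt rater B only in the 40-49 decade of one feature
  b <- tabs$a
  target <- b$feature_id == "f5" & b$age >= 40 & b$age < 50
  lv <- length(vasari_feature_levels()$f5) - 1L
  b$code[target] <- (b$code[target] + 3L) %% lv + 1L
  strat <- equity_stratification(tabs$a, b, metric = "kappa")
  f5 <- strat[strat$feature_id == "f5" & strat$flag == "ok", ]
  expect_true(all(f5$value[f5$decade != "40-49"] == 1))
  expect_true(all(f5$value[f5$decade == "40-49"] < 1))
  other <- strat[strat$feature_id != "f5" & strat$flag == "ok", ]
  expect_true(all(other$value == 1))

  # oracle: stratum kappa equals the global metric on the stratum subset
  sub_a <- tabs$a[tabs$a$feature_id == "f5" & tabs$a$sex == "female" &
                    tabs$a$age >= 40 & tabs$a$age < 50, ]
  sub_b <- b[b$feature_id == "f5" & b$case_id %in% sub_a$case_id, ]
  if (nrow(sub_a) >= 2) {
    cats <- seq_along(vasari_feature_levels()$f5) - 1L
    want <- as.numeric(cohen_kappa(sub_a$code,
                                   sub_b$code[match(sub_a$case_id, sub_b$case_id)],
                                   "linear", categories = cats))
    got <- strat$value[strat$feature_id == "f5" & strat$sex == "female" &
                         strat$decade == "40-49"]
    expect_equal(got, want)
  }
})

test_that("equity stratification requires covariates", {
  tabs <- make_rater_tables(10, rate = 0, seed = 1)
  a <- tabs$a; a$age <- NULL; a$sex <- NULL
  expect_error(equity_stratification(a, tabs$b), class = "vasarify_data_error")
})

test_that("agreement_summary reports per-feature values and a labelled mean", {
  tabs <- make_rater_tables(40, rate = 0.3, seed = 5)
  res <- agreement_summary(tabs$a, tabs$b, metric = "kappa")
  expect_setequal(res$per_feature$feature_id, feature_names())
  expect_equal(res$mean_value, mean(res$per_feature$value), tolerance = 1e-12)
  acc <- agreement_summary(tabs$a, tabs$b, metric = "balanced_accuracy")
  expect_true(all(acc$per_feature$value >= 0 & acc$per_feature$value <= 1))
})
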