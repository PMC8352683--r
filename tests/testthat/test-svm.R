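test_that("the 1-D two-point toy recovers the analytic max-margin plane", {
  # points -1 (class -1) and +1 (class +1): the max-margin separator is
  # omega = 1, c = 0 (margins exactly 1 at both points)
  X <- matrix(c(-1, 1), ncol = 1)
  fit <- svm_fit_binary(X, c(-1, 1), C = 1e4)
  expect_equal(fit$omega, 1, tolerance = 1e-6)
  expect_equal(fit$c, 0, tolerance = 1e-6)
})

test_that("duplicating every sample leaves the hyperplane unchanged", {
  set.seed(3)
  inst <- random_separable_2d(16)
  f1 <- svm_fit_binary(inst$X, inst$y, C = 100)
  f2 <- svm_fit_binary(rbind(inst$X, inst$X), c(inst$y, inst$y), C = 100)
  expect_equal(f2$omega, f1$omega, tolerance = 1e-6)
  expect_equal(f2$c, f1$c, tolerance = 1e-6)
})

test_that("permuting the sample order leaves the decision function unchanged", {
  set.seed(4)
  inst <- random_separable_2d(24)
  f1 <- svm_fit_binary(inst$X, inst$y, C = 10, tol = 1e-10)
  perm <- sample(24)
  f2 <- svm_fit_binary(inst$X[perm, ], inst$y[perm], C = 10, tol = 1e-10)
  expect_lt(max(abs(svm_score(f1, inst$X) - svm_score(f2, inst$X))), 1e-8)
})

test_that("fit matches the libsvm reference on random separable instances", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (rep in 1:10) {
    inst <- random_separable_2d(20)
    fit <- svm_fit_binary(inst$X, inst$y, C = 1e4)
    # every training point must respect the (near-hard) margin
    expect_gte(min(inst$y * svm_score(fit, inst$X)), 1 - 1e-6)
    ref <- e1071::svm(inst$X, factor(inst$y), kernel = "linear", cost = 1e4,
                      scale = FALSE)
    ref_pred <- as.numeric(as.character(predict(ref, inst$X)))
    expect_identical(sign(svm_score(fit, inst$X)), ref_pred)
  }
})

test_that("degenerate and invalid inputs are rejected", {
  X <- matrix(rbinom(20, 1, 0.5), 10, 2)
  expect_error(svm_fit_binary(X, rep(1, 10)), "both classes")
  expect_error(svm_fit_binary(X, c(rep(1, 5), rep(0, 5))), "\\+1/-1")
  expect_error(svm_fit_binary(X, c(rep(1, 5), rep(-1, 5)), C = -1), "> 0")
})

test_that("the membership decision follows the sign rule with 0 as nonmember", {
  plane <- structure(list(omega = c(1, 0, 0), c = -0.5), class = "linear_svm")
  expect_identical(svm_decide(plane, c(1, 0, 0)), "member")     # score 0.5
  expect_identical(svm_decide(plane, c(0, 1, 1)), "nonmember")  # score -0.5
  zero <- structure(list(omega = c(0, 0, 0), c = 0), class = "linear_svm")
  expect_identical(svm_decide(zero, c(1, 1, 1)), "nonmember")   # boundary
  expect_error(svm_decide(plane, c(1, 0)), "features")
  # random planes/points agree with the direct sign computation
  set.seed(6)
  for (rep in 1:20) {
    om <- rnorm(4); cc <- rnorm(1); x <- rnorm(4)
    p <- structure(list(omega = om, c = cc), class = "linear_svm")
    expect_identical(svm_decide(p, x),
                     if (sum(om * x) + cc > 0) "member" else "nonmember")
  }
})

test_that("one-vs-rest fits one plane per class, in taxonomy order", {
  dat <- small_disjoint_data(seed = 9)
  anc <- symtriage:::code_ancestry(dat$taxonomy, dat$records$disease)
  X <- as.matrix(dat$records[dat$taxonomy$symptom_names])
  set <- fit_one_vs_rest(X, anc$subclass_code, C = 1e4)
  classes <- sort(unique(anc$subclass_code))
  expect_identical(set$classes, classes)
  expect_identical(length(set$planes), length(classes))
  # disjoint profiles: each plane classifies its own training points as members
  for (cl in classes) {
    rows <- which(anc$subclass_code == cl)
    expect_true(all(svm_decide(set$planes[[as.character(cl)]],
                               X[rows, , drop = FALSE]) == "member"))
  }
  expect_error(fit_one_vs_rest(X, anc$subclass_code, classes = c(classes, 9999L)),
               "no samples for class 9999")
})

test_that("the two planes of a 2-class set mirror each other's decisions", {
  set.seed(15)
  inst <- random_separable_2d(30)
  set <- fit_one_vs_rest(inst$X, ifelse(inst$y > 0, 2L, 1L), C = 1e4)
  d1 <- svm_decide(set$planes[["1"]], inst$X)
  d2 <- svm_decide(set$planes[["2"]], inst$X)
  expect_true(all(d1 != d2))
})

test_that("sequential identification returns the first firing class or none", {
  plane <- function(om, cc) structure(list(omega = om, c = cc),
                                      class = "linear_svm")
  set <- structure(list(level = "main", parent_code = NA_integer_,
                        classes = c(101L, 102L, 103L),
                        planes = list(`101` = plane(c(0, 1), -2),
                                      `102` = plane(c(1, 0), -0.5),
                                      `103` = plane(c(1, 1), -1))),
                   class = "ovr_svm")
  expect_identical(sequential_identify(set, c(1, 0)), 102L)  # only 102 fires
  expect_true(is.na(sequential_identify(set, c(0, 0))))     # no plane fires
  expect_identical(argmax_identify(set, c(0, 0)), 102L)     # scores -2,-.5,-1
})

test_that("sequential equals argmax whenever exactly one plane fires", {
  set.seed(21)
  plane <- function() structure(list(omega = rnorm(3), c = rnorm(1)),
                                class = "linear_svm")
  for (rep in 1:50) {
    set <- structure(list(level = "main", parent_code = NA_integer_,
                          classes = 1:4,
                          planes = stats::setNames(replicate(4, plane(),
                                                             simplify = FALSE),
                                                   as.character(1:4))),
                     class = "ovr_svm")
    x <- rnorm(3)
    fired <- sum(symtriage:::ovr_scores(set, x) > 0)
    if (fired == 1) {
      expect_identical(sequential_identify(set, x), argmax_identify(set, x))
    }
    # argmax agrees with a brute-force maximum over all planes
    expect_identical(argmax_identify(set, x),
                     set$classes[which.max(vapply(set$planes, svm_score,
                                                  numeric(1), x))])
  }
})

test_that("per-sample weights shift the plane and uniform weights do not", {
  set.seed(30)
  inst <- random_separable_2d(20, gap = 1.5)
  base <- svm_fit_binary(inst$X, inst$y, C = 1)
  unif <- svm_fit_binary(inst$X, inst$y, C = 1, weights = rep(7, 20))
  expect_equal(unif$omega, base$omega, tolerance = 1e-8)
  expect_equal(unif$c, base$c, tolerance = 1e-8)
  expect_error(svm_fit_binary(inst$X, inst$y, weights = rep(-1, 20)), "positive")
})

test_that("one-vs-rest JSON persistence round-trips decisions", {
  dat <- small_disjoint_data(seed = 13)
  anc <- symtriage:::code_ancestry(dat$taxonomy, dat$records$disease)
  X <- as.matrix(dat$records[dat$taxonomy$symptom_names])
  set <- fit_one_vs_rest(X, anc$main_code, C = 10, level = "main")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(set, path)
  back <- read_model(path)
  expect_identical(back$classes, set$classes)
  expect_identical(back$level, "main")
  expect_equal(predict(back, X), predict(set, X), tolerance = 0)
})
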