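test_that("squared distance is the 14-D sum of squared differences", {
  a <- c(1, rep(0, 13))
  b <- c(0, 1, rep(0, 12))
  expect_identical(squared_distance(a, a), 0)
  expect_identical(squared_distance(a, rep(0, 14)), 1)
  expect_identical(squared_distance(a, b), 2)
})

test_that("decision scores are normalized kernel-weighted label averages", {
  # all training drugs positive for class m -> score exactly +1 at any theta
  f <- matrix(stats::runif(3 * 14), 3, 14)
  l <- matrix(-1, 3, 14)
  l[, 2] <- 1
  for (theta in c(1e-3, 1, 1e3)) {
    s <- decision_scores(mlgkr_model(f, l, theta), stats::runif(14))
    expect_equal(s[[2L]], 1)
  }

  # two equidistant drugs with opposite labels cancel to 0
  f2 <- rbind(c(1, rep(0, 13)), c(0, 1, rep(0, 12)))
  l2 <- rbind(rep(1, 14), rep(-1, 14))
  s2 <- decision_scores(mlgkr_model(f2, l2, 1), rep(0, 14))
  expect_equal(s2, rep(0, 14))

  # training (1,0,...) labelled +1 and (0,1,0,...) labelled -1 for class 1,
  # query (1,0,...), theta = 1: distances 0 and 2, so
  # Delta_1 = (1 - e^-1) / (1 + e^-1)
  l3 <- rbind(c(1, rep(-1, 13)), rep(-1, 14))
  s3 <- decision_scores(mlgkr_model(f2, l3, 1), c(1, rep(0, 13)))
  expect_equal(s3[[1L]], (1 - exp(-1)) / (1 + exp(-1)))

  expect_error(mlgkr_model(matrix(0, 0, 14), matrix(0, 0, 14), 1),
               class = "mlatc_model_error")
  expect_error(mlgkr_model(f2, l2, 0), class = "mlatc_model_error")
})

test_that("scores stay in [-1, 1] and match a naive extended-precision evaluation", {
  set.seed(21)
  for (rep in 1:20) {
    model <- random_mlgkr(n = sample(2:20, 1L), theta = stats::runif(1L, 0.2, 2))
    q <- stats::runif(14)
    s <- decision_scores(model, q)
    expect_true(all(s >= -1 & s <= 1))
    naive <- naive_decision_scores(model$features, model$labels, model$theta, q)
    expect_equal(s, naive, tolerance = 1e-10)
  }
})

test_that("the stability shift preserves scores where the naive form underflows", {
  set.seed(22)
  model <- random_mlgkr(n = 10L, theta = 1e-4)
  q <- stats::runif(14)
  s <- decision_scores(model, q)
  expect_true(all(is.finite(s)))
  expect_true(all(s >= -1 & s <= 1))
  # naive form underflows to 0/0 here
  naive <- naive_decision_scores(model$features, model$labels, model$theta, q)
  expect_true(any(is.nan(naive)))
})

test_that("theta limits: label mean at large theta, nearest neighbour at small theta", {
  set.seed(23)
  for (rep in 1:10) {
    model <- random_mlgkr(n = 20L, theta = 1e6)
    q <- stats::runif(14)
    s <- decision_scores(model, q)
    expect_equal(s, colMeans(model$labels), tolerance = 1e-6)
  }
  for (rep in 1:20) {
    model <- random_mlgkr(n = 15L)
    model$theta <- 1e-6
    q <- stats::runif(14)
    d2 <- apply(model$features, 1L, function(f) sum((f - q)^2))
    nn <- which.min(d2)
    if (sum(abs(d2 - d2[[nn]]) < 1e-9) > 1L) next  # need a unique neighbour
    pred <- predict_labels(decision_scores(model, q))
    expect_identical(as.integer(pred), which(model$labels[nn, ] == 1))
  }
})

test_that("predicted label sets follow the >= 0 rule and are never empty", {
  s <- c(0.2, -0.1, 0, rep(-1, 11))
  expect_identical(as.integer(predict_labels(s)), c(1L, 3L))
  expect_false(attr(predict_labels(s), "forced"))

  s2 <- rep(-1, 14); s2[[5L]] <- -0.2
  p2 <- predict_labels(s2)
  expect_identical(as.integer(p2), 5L)
  expect_true(attr(p2, "forced"))

  # all-negative tie broken toward the lowest class index
  expect_identical(as.integer(predict_labels(rep(-0.5, 14))), 1L)

  set.seed(24)
  for (rep in 1:50) {
    expect_gt(length(predict_labels(stats::runif(14, -1, 1))), 0L)
  }
})

test_that("model serialization round-trips through JSON", {
  set.seed(25)
  model <- random_mlgkr(n = 6L, theta = 1 / 36)
  path <- withr::local_tempfile(fileext = ".json")
  write_mlgkr_model(model, path)
  back <- read_mlgkr_model(path)
  expect_equal(back$features, model$features)
  expect_equal(back$labels, model$labels)
  expect_equal(back$theta, model$theta)
  q <- stats::runif(14)
  expect_equal(decision_scores(back, q), decision_scores(model, q))
  # schema tag is checked
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other"), bad, auto_unbox = TRUE)
  expect_error(read_mlgkr_model(bad), class = "mlatc_format_error")
})
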