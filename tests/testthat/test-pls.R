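test_that("column centering is exact, idempotent and guarded", {
  cc <- center_columns(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(drop(cc$centered), c(-1, 0, 1))
  expect_equal(unname(cc$means), 2)
  again <- center_columns(cc$centered)
  expect_equal(again$centered, cc$centered, ignore_attr = TRUE)
  expect_equal(unname(again$means), 0)
  expect_error(center_columns(matrix(1, 1, 3)),
               class = "gaitdose_invalid_input")
})

test_that("a noise-free univariate proportionality is fit exactly", {
  x <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  y <- 2 * x + 5
  m <- fit_pls(x, y, n_components = 1)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(m$coefficient_matrix[1, 1]), 2, tolerance = 1e-12)
  expect_equal(m$fitted, y, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("full-component PLS equals the normal-equations oracle", {
  set.seed(23)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 5), 20)
    Y <- matrix(rnorm(20 * 3), 20)
    m <- fit_pls(X, Y, n_components = 5)
    expect_lt(max(abs(m$fitted - ols_fitted(X, Y))) /
                max(abs(ols_fitted(X, Y))), 1e-8)
  }
})

test_that("planted coefficients are recovered as noise vanishes", {
  set.seed(31)
  n <- 40; p <- 6; q <- 4
  X <- matrix(rnorm(n * p), n)
  B <- matrix(rnorm(p * q), p)
  Y <- scale(X, scale = FALSE) %*% B + matrix(rnorm(n * q, 0, 1e-8), n)
  m <- fit_pls(X, Y, n_components = p)
  expect_equal(unname(m$coefficient_matrix), B, tolerance = 1e-5)
  expect_gt(m$r_squared, 1 - 1e-12)
})

test_that("variance explained is monotone and sums to 100 R^2 at full rank", {
  set.seed(57)
  X <- matrix(rnorm(18 * 6), 18)
  Y <- matrix(rnorm(18 * 5), 18)
  m <- fit_pls(X, Y, n_components = 6)
  ev <- explained_variance(m)
  expect_true(all(diff(ev$cum_pct_var_y) >= -1e-12))
  expect_true(all(ev$pct_var_y >= -1e-12))
  expect_lte(max(ev$cum_pct_var_y), 100 + 1e-9)
  expect_equal(ev$cum_pct_var_y[m$n_components], 100 * m$r_squared,
               tolerance = 1e-9)
  # successive X scores are mutually orthogonal
  G <- crossprod(m$x_scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
})

test_that("prediction honours centering and predictor-label alignment", {
  set.seed(77)
  X <- matrix(rnorm(15 * 4), 15,
              dimnames = list(NULL, paste0("lob", 1:4)))
  B <- matrix(rnorm(4 * 2), 4)
  Y <- scale(X, scale = FALSE) %*% B
  colnames(Y) <- c("p1", "p2")
  m <- fit_pls(X, Y, n_components = 4)
  expect_equal(predict_responses(m, X), Y, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(drop(predict_responses(m, t(m$x_means))),
               m$y_means, tolerance = 1e-12)
  perm <- X[, c(3, 1, 4, 2)]
  expect_equal(predict_responses(m, perm), predict_responses(m, X),
               tolerance = 1e-12)
  colnames(perm) <- paste0("other", 1:4)
  expect_error(predict_responses(m, perm), class = "gaitdose_schema_error")
})

test_that("response R^2 matches hand arithmetic and degenerate cases", {
  obs <- matrix(c(0, 0, 2, 2), 2, byrow = TRUE)
  fit <- matrix(1, 2, 2)
  expect_equal(response_r2(obs, fit), 0)
  expect_equal(response_r2(obs, obs), 1)
  expect_error(response_r2(matrix(3, 2, 1), matrix(3, 2, 1)),
               class = "gaitdose_invalid_input")
})

test_that("loadings are deterministic and rank-1 structure is recovered", {
  set.seed(91)
  n <- 30; p <- 5; q <- 4
  X <- matrix(rnorm(n * p), n)
  u <- rnorm(p); v <- rnorm(q)
  Y <- scale(X, scale = FALSE) %*% outer(u, v)
  m1 <- fit_pls(X, Y, n_components = 1)
  m2 <- fit_pls(X, Y, n_components = 1)
  expect_identical(m1$x_weights, m2$x_weights)
  # response loadings of component 1 are parallel to the planted v
  q1 <- m1$y_loadings[, 1]
  expect_equal(abs(sum(q1 * v)) / sqrt(sum(q1^2) * sum(v^2)), 1,
               tolerance = 1e-9)
  # weight vector is the dominant singular direction of t(Xc) Yc
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  w_oracle <- svd(crossprod(Xc, Yc), nu = 1)$u[, 1]
  w_oracle <- w_oracle * sign(w_oracle[which.max(abs(w_oracle))])
  expect_equal(unname(m1$x_weights[, 1]), w_oracle, tolerance = 1e-9)
})

test_that("montage contrast is zero for identical profiles", {
  co <- generate_cohort(4, seed = 13)
  labels <- default_lobule_labels()
  same <- list(
    a = montage_profile("a", labels, rep(0.1, length(labels)), 0),
    b = montage_profile("b", labels, rep(0.1, length(labels)), 0))
  ef_same <- generate_efield_matrix(same, co, seed = 13)
  ef_fit <- generate_efield_matrix(default_montage_profiles(), co, seed = 13)
  assoc <- planted_association(noise_sd = 1, seed = 13)
  ch <- plant_gait_change(ef_fit, assoc)
  m <- fit_pls(ef_fit[, labels], ch[, gait_parameter_names()],
               n_components = 3)
  loads <- extract_loadings(m, ef_same)
  expect_true(all(loads$contrast$difference == 0))
  expect_setequal(names(loads), c("predictor_loadings", "response_loadings",
                                  "contrast"))
  expect_equal(sort(unique(loads$predictor_loadings$component)), 1:3)
})

test_that("model truncates on rank-deficient cross-covariance", {
  set.seed(3)
  x1 <- rnorm(12)
  X <- cbind(x1, x1, x1)  # rank 1
  Y <- matrix(x1 + rnorm(12, 0, 1e-10), ncol = 1)
  expect_warning(m <- fit_pls(X, Y, n_components = 3),
                 class = "gaitdose_warning")
  expect_lt(m$n_components, 3)
})

test_that("model serialization writes the documented JSON structure", {
  set.seed(44)
  X <- matrix(rnorm(12 * 3), 12)
  Y <- matrix(rnorm(12 * 2), 12)
  m <- fit_pls(X, Y, n_components = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsr_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$r_squared, m$r_squared, tolerance = 1e-12)
  expect_equal(back$n_components, m$n_components)
  expect_equal(unlist(back$pct_var_y), m$pct_var_y, tolerance = 1e-12)
})
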