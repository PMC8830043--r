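# Empirical-Bayes site harmonization: effect removal, covariate preservation,
# error handling, idempotence, and agreement with the reference implementation.

simulate_site_data <- function(n = 60, V = 400, shift = 2, vscale = 2,
                               noise_sd = 0.05, beta_sd = 0.05, seed = 1) {
  set.seed(seed)
  site <- factor(rep(c("a", "b"), each = n / 2))
  grp <- rep(c(0, 1), n / 2)
  age <- rnorm(n, 65, 7)
  beta_true <- rnorm(V, 0.5, beta_sd)
  mu <- rnorm(V, 10, 1)
  eps <- matrix(rnorm(n * V, 0, noise_sd), n, V)
  eps[site == "b", ] <- eps[site == "b", ] * sqrt(vscale)
  Y <- outer(rep(1, n), mu) + grp %o% beta_true + 0.01 * age %o% rep(1, V) + eps
  Y[site == "b", ] <- Y[site == "b", ] + shift
  list(Y = Y, site = site, cov = cbind(group = grp, age = age),
       beta_true = beta_true)
}

test_that("additive and multiplicative site effects are removed", {
  d <- simulate_site_data(n = 60, V = 400, shift = 2, vscale = 2, seed = 21)
  mod <- combat_fit(d$Y, d$site, d$cov)
  Yh <- combat_apply(d$Y, mod, d$site, d$cov)
  X <- cbind(1, d$cov)
  res <- Yh - X %*% qr.coef(qr(X), Yh)
  ma <- colMeans(res[d$site == "a", ]); mb <- colMeans(res[d$site == "b", ])
  # harmonized site means agree (relative to the data scale of ~10)
  expect_lt(mean(abs(ma - mb)) / 10, 1e-3)
  va <- apply(res[d$site == "a", ], 2, var)
  vb <- apply(res[d$site == "b", ], 2, var)
  expect_lt(abs(mean(vb) / mean(va) - 1), 0.05)
  # estimated site location difference reflects the injected shift in
  # standardized units
  gap <- mod$gamma_star["b", ] - mod$gamma_star["a", ]
  expect_equal(mean(gap * mod$sigma), 2, tolerance = 0.05)
})

test_that("biological covariate effects are preserved and recovered", {
  d <- simulate_site_data(n = 60, V = 400, noise_sd = 0.05, seed = 22)
  mod <- combat_fit(d$Y, d$site, d$cov)
  # known group effect recovered within 5% (noise SD is 10% of the effect)
  expect_lt(mean(abs(mod$beta["group", ] - d$beta_true) / d$beta_true), 0.05)
  # the covariate-projected component is untouched by adjustment
  Yh <- combat_apply(d$Y, mod, d$site, d$cov)
  mod2 <- combat_fit(Yh, d$site, d$cov)
  expect_equal(mod2$beta["group", ], mod$beta["group", ], tolerance = 0.02)
})

test_that("null site effects leave the data essentially unchanged", {
  d <- simulate_site_data(n = 200, V = 300, shift = 0, vscale = 1,
                          noise_sd = 0.5, seed = 23)
  mod <- combat_fit(d$Y, d$site, d$cov)
  Yh <- combat_apply(d$Y, mod, d$site, d$cov)
  rms_change <- sqrt(mean((Yh - d$Y)^2)) / sqrt(mean((d$Y - mean(d$Y))^2))
  expect_lt(rms_change, 0.02)  # only EB shrinkage remains
})

test_that("harmonization is idempotent up to re-estimation", {
  d <- simulate_site_data(n = 60, V = 300, shift = 1, vscale = 1.5, seed = 24)
  mod <- combat_fit(d$Y, d$site, d$cov)
  Y1 <- combat_apply(d$Y, mod, d$site, d$cov)
  mod2 <- combat_fit(Y1, d$site, d$cov)
  Y2 <- combat_apply(Y1, mod2, d$site, d$cov)
  expect_lt(sqrt(mean((Y2 - Y1)^2)) / sqrt(mean((Y1 - mean(Y1))^2)), 1e-3)
  # re-fit on harmonized data: site locations near 0, scales near 1
  expect_lt(max(abs(mod2$gamma_star)), 0.1)
  expect_lt(max(abs(mod2$delta2_star - 1)), 0.2)
})

test_that("degenerate designs and unseen sites are hard errors", {
  d <- simulate_site_data(seed = 25)
  expect_error(combat_fit(d$Y, rep("one", nrow(d$Y))), "one site label")
  site1 <- as.character(d$site); site1[1] <- "c"
  expect_error(combat_fit(d$Y, site1, d$cov), "single subject")
  # covariate confounded with site
  sind <- as.numeric(d$site == "b")
  expect_error(combat_fit(d$Y, d$site, cbind(d$cov, dup = sind)),
               "rank deficient.*dup")
  mod <- combat_fit(d$Y, d$site, d$cov)
  expect_error(combat_apply(d$Y, mod, rep("new", nrow(d$Y)), d$cov),
               "not present")
})

test_that("our ComBat matches the reference implementation (sva)", {
  d <- simulate_site_data(n = 40, V = 150, shift = 1.5, vscale = 1.8, seed = 26)
  mod <- combat_fit(d$Y, d$site, d$cov)
  Yh <- combat_apply(d$Y, mod, d$site, d$cov)
  ref <- t(suppressMessages(
    sva::ComBat(t(d$Y), batch = d$site, mod = cbind(1, d$cov))))
  expect_lt(max(abs(Yh - ref)), 1e-4)
})

test_that("vertices with missing values are harmonized and flagged", {
  d <- simulate_site_data(n = 40, V = 100, seed = 27)
  Y <- d$Y
  Y[3, 7] <- NA
  mod <- combat_fit(Y, d$site, d$cov)
  expect_identical(mod$qc$incomplete_vertices, 7L)
  Yh <- combat_apply(Y, mod, d$site, d$cov)
  expect_true(is.na(Yh[3, 7]))
  expect_false(anyNA(Yh[-3, 7]))
  expect_false(anyNA(Yh[, -7]))
})

test_that("a serialized model round-trips through JSON", {
  d <- simulate_site_data(n = 40, V = 60, seed = 28)
  mod <- combat_fit(d$Y, d$site, d$cov)
  path <- tempfile(fileext = ".json")
  write_combat_model(mod, path)
  mod2 <- read_combat_model(path)
  expect_equal(combat_apply(d$Y, mod2, d$site, d$cov),
               combat_apply(d$Y, mod, d$site, d$cov), tolerance = 1e-12)
})
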