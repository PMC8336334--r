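test_that("Kaplan-Meier estimate matches the hand product-limit", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 1 / 3)
  expect_equal(km$surv[km$time == 3], 1 / 3) # censoring leaves S unchanged

  expect_warning(km0 <- km_fit(c(1, 2, 3), c(0, 0, 0)), "no events")
  expect_true(all(km0$surv == 1))

  # time rescaling changes the x-axis only
  km2 <- km_fit(c(2, 4, 6), c(1, 1, 0))
  expect_equal(km2$surv, km$surv)
  expect_equal(km2$time, 2 * km$time)
})

test_that("Kaplan-Meier equals a brute-force product over event times", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    tt <- round(rexp(n, 0.2), 1) # induce ties
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    km <- km_fit(tt, ev)
    ut <- sort(unique(tt))
    s <- 1
    brute <- sapply(ut, function(u) {
      d <- sum(tt == u & ev == 1)
      r <- sum(tt >= u)
      s <<- s * (1 - d / r)
      s
    })
    expect_equal(km$surv, brute[match(km$time, ut)], tolerance = 1e-12)
  }
})

test_that("log-rank behaves on identical groups and reports correct df", {
  lt <- logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2),
                     rep(c("a", "b"), each = 3))
  expect_equal(lt$chi2, 0, tolerance = 1e-12)
  expect_equal(lt$p, 1, tolerance = 1e-12)

  set.seed(52)
  lt4 <- logrank_test(rexp(40), rbinom(40, 1, 0.8),
                      sample(letters[1:4], 40, TRUE))
  expect_equal(lt4$df, 3L)
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), ">= 2 groups")
})

test_that("log-rank chi2 is invariant to monotone time transformations", {
  set.seed(53)
  tt <- rexp(30); ev <- rbinom(30, 1, 0.7); g <- rep(c("a", "b"), 15)
  l1 <- logrank_test(tt, ev, g)
  l2 <- logrank_test(tt^2, ev, g)       # strictly increasing transform
  expect_equal(l1$chi2, l2$chi2, tolerance = 1e-10)
})

test_that("multivariate Cox reduces to the univariate fit for one covariate", {
  set.seed(54)
  n <- 40
  clin <- data.frame(sample_id = paste0("s", 1:n),
                     os_time = rexp(n), os_event = rbinom(n, 1, 0.8),
                     x = rnorm(n))
  mv <- cox_multivariate(clin, "x")
  uv <- cox_univariate(setNames(clin$x, clin$sample_id), clin)
  expect_equal(mv$coefficients$beta, uv$beta, tolerance = 1e-10)
  expect_equal(mv$coefficients$se, uv$se, tolerance = 1e-10)

  clin$const <- 1
  expect_error(cox_multivariate(clin, "const"), "constant")
  expect_error(cox_multivariate(clin, "nope"), "missing")
})

test_that("multivariate Cox recovers planted coefficients within 2 SE", {
  # calibration across seeded replicates
  hits <- 0
  n_rep <- 30
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    n <- 150
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
    beta <- c(0.6, -0.5)
    tt <- rexp(n, rate = 0.1 * exp(beta[1] * x1 + beta[2] * x2))
    cens <- runif(n) < 0.25
    clin <- data.frame(sample_id = paste0("s", 1:n),
                       os_time = ifelse(cens, runif(n) * tt, tt),
                       os_event = as.integer(!cens), x1 = x1, x2 = x2)
    fit <- cox_multivariate(clin, c("x1", "x2"))
    co <- fit$coefficients
    if (all(abs(co$beta - beta) <= 2 * co$se)) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_rep - 2)
})

test_that("categorical covariates honor the declared reference level", {
  set.seed(55)
  n <- 60
  grp <- sample(c("HL", "LH", "HH"), n, TRUE)
  clin <- data.frame(sample_id = paste0("s", 1:n),
                     os_time = rexp(n, 0.1 * ifelse(grp == "LH", 3, 1)),
                     os_event = 1, grp = grp)
  fit <- cox_multivariate(clin, "grp", ref_levels = list(grp = "LH"))
  expect_true(all(grepl("^grp", fit$coefficients$term)))
  expect_false(any(grepl("LH$", fit$coefficients$term)))
  # against the LH reference the other groups are protective
  expect_true(all(fit$coefficients$hr < 1))
})

test_that("concordance index matches edge cases and the all-pairs oracle", {
  expect_equal(c_index(c(4, 3, 2, 1), c(1, 2, 3, 4), rep(1, 4)), 1)
  expect_equal(c_index(rep(1, 4), c(1, 2, 3, 4), rep(1, 4)), 0.5)

  brute_c <- function(risk, tt, ev) {
    num <- 0; den <- 0
    n <- length(risk)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      # the pair is usable if the smaller time is an event
      if (tt[i] == tt[j]) next
      a <- if (tt[i] < tt[j]) i else j
      b <- if (tt[i] < tt[j]) j else i
      if (ev[a] == 0) next
      den <- den + 1
      if (risk[a] > risk[b]) num <- num + 1
      else if (risk[a] == risk[b]) num <- num + 0.5
    }
    num / den
  }
  set.seed(56)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    tt <- sample(1:50, n, replace = FALSE) # unique times
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    risk <- sample(1:10, n, replace = TRUE) # risk ties likely
    expect_equal(c_index(risk, tt, ev), brute_c(risk, tt, ev),
                 tolerance = 1e-12)
  }
})

test_that("complementarity: c_index(risk) + c_index(-risk) = 1 without risk ties", {
  set.seed(57)
  n <- 25
  tt <- sample(1:100, n); ev <- rbinom(n, 1, 0.8); risk <- rnorm(n)
  if (sum(ev) == 0) ev[1] <- 1
  expect_equal(c_index(risk, tt, ev) + c_index(-risk, tt, ev), 1,
               tolerance = 1e-12)
})

test_that("restricted mean survival orders groups by survival", {
  set.seed(58)
  n <- 60
  g <- rep(c("good", "bad"), each = n / 2)
  tt <- rexp(n, ifelse(g == "good", 0.05, 0.4))
  r <- rmst_by_group(tt, rep(1, n), g)
  expect_gt(r[["good"]], r[["bad"]])
})
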