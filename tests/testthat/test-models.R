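test_that("rate model recovers crude ratios and arm symmetry", {
  # identical count vectors in both arms: RR exactly 1
  counts <- c(0, 1, 2, 0, 3, 1, 0, 2)
  arm <- rep(c("BFC", "FSC"), each = 4)
  counts <- c(counts[1:4], counts[1:4])
  est <- fit_rate_model(counts, arm)
  expect_equal(est$estimate, 1, tolerance = 1e-8)
  expect_equal(unname(est$arm_summaries["BFC"]), mean(counts[1:4]),
               tolerance = 1e-8)

  # crude ratio of means: 20 events/10py vs 10 events/10py -> RR 2
  counts2 <- c(rep(2, 10), rep(1, 10))
  arm2 <- rep(c("BFC", "FSC"), each = 10)
  est2 <- fit_rate_model(counts2, arm2, person_time = rep(1, 20))
  expect_equal(est2$estimate, 2, tolerance = 1e-6)

  # label swap inverts the ratio exactly
  est3 <- fit_rate_model(counts2, arm2, ref = "BFC")
  expect_equal(est3$estimate, 1 / est2$estimate, tolerance = 1e-8)

  # all-zero counts in one arm: flagged, ratio undefined
  est4 <- fit_rate_model(c(0, 0, 1, 2), rep(c("BFC", "FSC"), each = 2))
  expect_true(is.na(est4$estimate))
  expect_match(est4$notes, "all-zero", all = FALSE)
})

test_that("negative binomial with dispersion 0 reproduces Poisson", {
  set.seed(42)
  n <- 300
  arm <- rep(c("BFC", "FSC"), each = n / 2)
  x <- rnorm(n)
  counts <- rpois(n, exp(-0.5 + 0.3 * (arm == "BFC") + 0.2 * x))
  pt <- runif(n, 0.5, 1)
  nb0 <- fit_rate_model(counts, arm, covariates = data.frame(x = x),
                        person_time = pt, dispersion = 0)
  pois <- stats::glm(counts ~ I(arm == "BFC") + x + offset(log(pt)),
                     family = stats::poisson())
  expect_equal(unname(log(nb0$estimate)), unname(coef(pois)[2]),
               tolerance = 1e-6)
  # ML-dispersion fit on near-Poisson data stays close to the Poisson fit
  nbml <- fit_rate_model(counts, arm, covariates = data.frame(x = x),
                         person_time = pt)
  expect_equal(log(nbml$estimate), unname(coef(pois)[2]), tolerance = 0.02)
})

test_that("Cox model matches a brute-force partial likelihood and recovers effects", {
  # identical samples in both arms: HR = 1
  t0 <- c(5, 10, 20, 30)
  est <- fit_time_to_event(rep(t0, 2), rep(TRUE, 8),
                           rep(c("BFC", "FSC"), each = 4))
  expect_equal(est$estimate, 1, tolerance = 1e-6)

  # 4 subjects, no ties: maximize the enumerated partial likelihood
  times <- c(1, 2, 3, 4)
  arm <- c("FSC", "BFC", "FSC", "BFC")   # x = 1 for BFC
  x <- as.numeric(arm == "BFC")
  pl <- function(b) {
    ll <- 0
    for (i in order(times)) {
      risk <- which(times >= times[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  bhat <- stats::optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  est2 <- fit_time_to_event(times, rep(TRUE, 4), arm)
  expect_equal(log(est2$estimate), bhat, tolerance = 1e-4)
  # closed form for this configuration: exp(b) = (sqrt(17) - 1) / 8
  expect_equal(est2$estimate, (sqrt(17) - 1) / 8, tolerance = 1e-4)

  # large-sample recovery of a true hazard ratio of 2
  set.seed(7)
  n <- 5000
  arm2 <- rep(c("BFC", "FSC"), each = n)
  haz <- ifelse(arm2 == "BFC", 2, 1) * 0.01
  tt <- rexp(2 * n, haz)
  cens <- pmin(tt, 365)
  est3 <- fit_time_to_event(cens, tt <= 365, arm2)
  expect_gt(est3$estimate, 1.9)
  expect_lt(est3$estimate, 2.1)

  expect_error(fit_time_to_event(c(1, 2), c(FALSE, FALSE), c("BFC", "FSC")),
               "no events")
})

test_that("logistic, ordinal and linear models report the expected effects", {
  # 2x2 {{30,70},{15,85}}: OR = (30*85)/(70*15) = 2.428...
  flags <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 15), rep(FALSE, 85))
  arm <- rep(c("BFC", "FSC"), each = 100)
  est <- fit_binary_model(flags, arm)
  expect_equal(est$estimate, (30 * 85) / (70 * 15), tolerance = 1e-6)
  expect_equal(unname(est$arm_summaries), c(0.30, 0.15))

  # identical arms: OR = 1 and mean difference 0
  flags2 <- rep(c(TRUE, FALSE), 50)
  est2 <- fit_binary_model(rep(flags2, 2), rep(c("BFC", "FSC"), each = 100))
  expect_equal(est2$estimate, 1, tolerance = 1e-8)
  vals <- rnorm(100)
  est3 <- fit_linear_model(rep(vals, 2), rep(c("BFC", "FSC"), each = 100))
  expect_equal(est3$estimate, 0, tolerance = 1e-10)

  # ordinal: planted shift toward higher categories gives OR > 1;
  # label swap inverts it
  set.seed(11)
  n <- 400
  arm4 <- rep(c("BFC", "FSC"), each = n / 2)
  latent <- rnorm(n) + 0.8 * (arm4 == "BFC")
  cat4 <- cut(latent, c(-Inf, -0.5, 0.3, 1, Inf),
              labels = c("1", "2", "3", "4+"))
  est4 <- fit_ordinal_model(as.character(cat4), arm4)
  expect_gt(est4$estimate, 1.5)
  est4b <- fit_ordinal_model(as.character(cat4), arm4, ref = "BFC")
  expect_equal(est4b$estimate, 1 / est4$estimate, tolerance = 1e-4)

  # degenerate single-category input is flagged, not fitted
  est5 <- fit_ordinal_model(rep("1", 20), rep(c("BFC", "FSC"), 10))
  expect_true(is.na(est5$estimate))
  expect_match(est5$notes, "degenerate", all = FALSE)
})

test_that("sample size formula hits its anchors and is monotone", {
  expect_equal(sample_size_nb(0.5, 0.20, 0.05, 0.90, 1.2, 1), 1457L)
  expect_equal(sample_size_nb(0.5, 0.20, 0.05, 0.90, 0, 1), 950L)
  expect_error(sample_size_nb(0.5, 0), "rate_reduction")
  expect_error(sample_size_nb(0.5, 1), "rate_reduction")

  # monotonicity
  red <- seq(0.1, 0.5, by = 0.1)
  n_red <- vapply(red, function(r) sample_size_nb(0.5, r), integer(1))
  expect_true(all(diff(n_red) < 0))
  mu <- c(0.25, 0.5, 1, 2)
  n_mu <- vapply(mu, function(m) sample_size_nb(m, 0.2), integer(1))
  expect_true(all(diff(n_mu) < 0))
  pw <- c(0.7, 0.8, 0.9, 0.95)
  n_pw <- vapply(pw, function(p) sample_size_nb(0.5, 0.2, power = p),
                 integer(1))
  expect_true(all(diff(n_pw) > 0))
  k <- c(0, 0.5, 1.2, 2)
  n_k <- vapply(k, function(kk) sample_size_nb(0.5, 0.2, dispersion = kk),
                integer(1))
  expect_true(all(diff(n_k) > 0))
})
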