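test_that("agreement suite on identical and monotone pairs", {
  pre <- c(10, 20, 30, 40, 50)
  same <- agreement_suite(pre = pre, post = pre)
  expect_equal(same$spearman_rho, 1)
  expect_equal(same$mean_diff, 0)
  neg <- agreement_suite(pre = pre, post = -pre)
  expect_equal(neg$spearman_rho, -1)
  mono <- agreement_suite(pre = c(1, 2, 3, 4), post = c(2, 4, 6, 9))
  expect_equal(mono$spearman_rho, 1)
  expect_error(agreement_suite(pre = c(1, 2), post = c(1, 2)), "3 complete")
})

test_that("Bland-Altman mean difference carries a t-based CI", {
  set.seed(21)
  pre <- rnorm(30, 100, 10)
  post <- pre + rnorm(30, -16, 20)
  res <- agreement_suite(pre = pre, post = post)
  d <- post - pre
  expect_equal(res$mean_diff, mean(d))
  half <- qt(0.975, 29) * sd(d) / sqrt(30)
  expect_equal(res$ci_low, mean(d) - half)
  expect_equal(res$ci_high, mean(d) + half)
  expect_equal(res$bland_altman_p, t.test(post, pre, paired = TRUE)$p.value)
})

test_that("dichotomization labels around the per-type median with strict >", {
  rec <- tibble::tibble(sphere_type = rep("resin", 4), m = c(1, 2, 3, 4))
  di <- dichotomize(rec, "m")
  expect_equal(attr(di, "medians")$median, 2.5)
  expect_equal(as.character(di$label),
               c("inframedian", "inframedian", "supramedian", "supramedian"))
  # a value exactly at the median is inframedian
  rec2 <- tibble::tibble(sphere_type = rep("resin", 3), m = c(1, 2, 3))
  expect_equal(dichotomize(rec2, "m")$supramedian, c(FALSE, FALSE, TRUE))
})

test_that("dichotomization is stratified by sphere type", {
  rec <- tibble::tibble(
    sphere_type = c(rep("resin", 3), rep("glass", 3), "resin", "glass"),
    m = c(10, 20, 30, 100, 200, 300, 25, 150))
  di <- dichotomize(rec, "m")
  med <- attr(di, "medians")
  expect_equal(med$median[med$sphere_type == "resin"], 22.5)
  expect_equal(med$median[med$sphere_type == "glass"], 175)
  expect_true(di$supramedian[7])   # resin 25 > 22.5
  expect_false(di$supramedian[8])  # glass 150 < 175
})

test_that("dichotomization is invariant to patient order", {
  set.seed(22)
  rec <- tibble::tibble(id = sprintf("P%02d", 1:20),
                        sphere_type = rep(c("resin", "glass"), 10),
                        m = runif(20))
  di <- dichotomize(rec, "m")
  perm <- sample(20)
  di2 <- dichotomize(rec[perm, ], "m")
  expect_equal(di2$supramedian[order(perm)], di$supramedian)
})

test_that("logistic OR equals the cross-product ratio ad/bc", {
  v <- table_to_vectors(10, 5, 5, 10)
  fit <- logistic_univariate(v$label, v$outcome)
  expect_equal(fit$or, oracle_or(10, 5, 5, 10), tolerance = 1e-6)
  expect_equal(fit$or, 4.0, tolerance = 1e-6)
  expect_false(fit$separation)
  # covariate independent of outcome -> OR 1
  b <- table_to_vectors(8, 8, 8, 8)
  expect_equal(logistic_univariate(b$label, b$outcome)$or, 1, tolerance = 1e-6)
})

test_that("OR matches ad/bc across a random sample of 2x2 tables", {
  set.seed(23)
  for (i in 1:25) {
    tb <- sample(1:10, 4, replace = TRUE)
    v <- table_to_vectors(tb[1], tb[2], tb[3], tb[4])
    fit <- logistic_univariate(v$label, v$outcome)
    expect_equal(fit$or, oracle_or(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-6,
                 info = paste(tb, collapse = ","))
  }
})

test_that("a zero cell raises the separation flag with an unbounded CI", {
  v <- table_to_vectors(10, 0, 3, 7)
  fit <- logistic_univariate(v$label, v$outcome)
  expect_true(fit$separation)
  expect_equal(fit$ci, c(0, Inf))
  expect_error(logistic_univariate(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "both covariate classes")
})

test_that("tidy/glance on fitted objects return the broom-shaped tibbles", {
  v <- table_to_vectors(10, 5, 5, 10)
  fit <- logistic_univariate(v$label, v$outcome)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high", "p.value",
                     "separation"))
  expect_equal(glance(fit)$n, 30)
  sv <- survival_suite(c(2, 4, 6, 8, 3, 5, 7, 9), rep(TRUE, 8),
                       rep(c(FALSE, TRUE), each = 4))
  expect_named(tidy(sv), c("term", "estimate", "conf.low", "conf.high",
                           "p.value", "logrank_p"))
  expect_true(all(c("n", "events") %in% names(glance(sv))))
})

test_that("KM median uses the smallest time with survival <= 0.5", {
  sv <- survival_suite(c(2, 4, 6, 8), rep(TRUE, 4), rep(TRUE, 4))
  expect_equal(unname(sv$km_median["supramedian"]), 4)
})

test_that("KM with no censoring reproduces the empirical survivor function", {
  set.seed(24)
  times <- round(rexp(40, 0.1), 2)
  sv <- survival_suite(times, rep(TRUE, 40), rep(TRUE, 40))
  s <- summary(sv$survfit, censored = FALSE)
  expect_equal(s$surv, oracle_empirical_survival(times, s$time),
               tolerance = 1e-12)
})

test_that("identical groups give log-rank p near 1 and HR near 1", {
  set.seed(25)
  t0 <- rexp(60, 0.08)
  sv <- survival_suite(c(t0, t0), rep(TRUE, 120), rep(c(FALSE, TRUE), each = 60))
  expect_gt(sv$logrank_p, 0.9)
  expect_equal(sv$hr, 1, tolerance = 0.05)
})

test_that("groups without events are flagged and their median is undefined", {
  sv <- NULL
  w <- capture_warnings(
    sv <- survival_suite(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                         rep(c(FALSE, TRUE), each = 2)))
  expect_true(any(grepl("no events", w)))  # Cox may also warn: monotone likelihood
  expect_true(is.na(sv$km_median["supramedian"]))
})

test_that("the multivariate gate is strict at alpha and drops redundancy", {
  uni <- tibble::tibble(metric = c("A", "B", "C", "D"),
                        p.value = c(0.049, 0.050, 0.001, 0.2))
  expect_setequal(multivariate_gate(uni), c("A", "C"))
  expect_setequal(multivariate_gate(uni, redundant = list(c("C", "A"))), "C")
  none <- tibble::tibble(metric = "A", p.value = 0.5)
  expect_message(out <- multivariate_gate(none), "skipped")
  expect_length(out, 0)
})
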