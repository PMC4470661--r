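test_that("epoch labels: worked examples", {
  # no events -> all zeros
  e <- epoch_labels(make_events(numeric(0), numeric(0)), NULL, total_s = 100)
  expect_equal(e$labels, rep(0L, 10))

  # one event [12, 13) -> only epoch 1
  e <- epoch_labels(make_events(12, 1), NULL, total_s = 100)
  expect_equal(which(e$labels == 1L) - 1L, 1L)

  # event [9.5, 10.5) straddles epochs 0 and 1
  e <- epoch_labels(make_events(9.5, 1), NULL, total_s = 100)
  expect_equal(which(e$labels == 1L) - 1L, c(0L, 1L))

  # rejected events do not label
  ev <- make_events(12, 1, status = "rejected", reason = "wake")
  expect_equal(sum(epoch_labels(ev, NULL, 100)$labels), 0L)

  # epochs overlapping excluded intervals are dropped entirely
  mask <- build_mask(data.frame(start_s = 35, end_s = 55, reason = "wake",
                                stringsAsFactors = FALSE), 100)
  e <- epoch_labels(make_events(12, 1), mask, total_s = 100)
  expect_equal(e$dropped, c(3L, 4L, 5L))
  expect_true(all(is.na(e$labels[4:6])))
  # hiccup bouts do NOT drop epochs
  maskh <- build_mask(data.frame(start_s = 35, end_s = 55, reason = "hiccup_bout",
                                 stringsAsFactors = FALSE), 100)
  expect_length(epoch_labels(make_events(12, 1), maskh, 100)$dropped, 0L)
})

test_that("pabak: identities and the 183/200 worked example", {
  a <- c(1, 0, 1, 1, 0)
  expect_equal(pabak(a, a)$pabak, 1)
  expect_equal(pabak(a, 1 - a)$pabak, -1)

  # 183 agreements of 200 epochs -> po 0.915, pabak 0.83
  x <- rep(c(1L, 0L), 100)
  y <- x; y[1:17] <- 1L - y[1:17]
  res <- pabak(x, y)
  expect_equal(res$po, 0.915)
  expect_equal(res$pabak, 0.83)
  expect_equal(res$label, "almost perfect")

  expect_error(pabak(c(NA, NA), c(1, 0)), class = "fm_input_error")
  expect_error(pabak(c(1, 0, 1), c(1, 0)), class = "fm_input_error")
})

test_that("pabak == 2*po - 1 exactly and is rater-symmetric (property)", {
  set.seed(81)
  for (i in 1:200) {
    n <- sample(5:300, 1)
    a <- rbinom(n, 1, runif(1, 0.05, 0.95))
    b <- rbinom(n, 1, runif(1, 0.05, 0.95))
    r1 <- pabak(a, b); r2 <- pabak(b, a)
    expect_identical(r1$pabak, 2 * r1$po - 1)
    expect_gte(r1$pabak, -1); expect_lte(r1$pabak, 1)
    expect_equal(r1$pabak, r2$pabak)
    expect_equal(r1$kappa, r2$kappa)
  }
})

test_that("kappa labels follow the Landis-Koch bands", {
  expect_equal(kappa_label(0.83), "almost perfect")
  expect_equal(kappa_label(0.50), "moderate")
  expect_equal(kappa_label(-0.2), "poor")
  expect_equal(kappa_label(0), "poor")
  expect_equal(kappa_label(0.20), "slight")
  expect_equal(kappa_label(0.61), "substantial")
  expect_error(kappa_label(1.2), class = "fm_input_error")
})

test_that("session summary arithmetic", {
  ev <- make_events(seq(100, by = 10, length.out = 300), rep(1, 300))
  m <- build_mask(data.frame(start_s = numeric(0), end_s = numeric(0),
                             reason = character(0)), 3 * 3600)
  s <- session_summary(ev, m)
  expect_equal(s$movements_per_hour, 100)

  # 250 events over 8 h with a 0.5-h restroom exclusion -> 250 / 7.5
  ev <- make_events(seq(100, by = 20, length.out = 250), rep(1, 250))
  m <- build_mask(data.frame(start_s = 10000, end_s = 11800, reason = "restroom",
                             stringsAsFactors = FALSE), 8 * 3600)
  s <- session_summary(ev, m)
  expect_equal(s$movements_per_hour, 250 / 7.5, tolerance = 1e-12)

  # zero accepted events is legal; zero analysis time is not
  s0 <- session_summary(make_events(numeric(0), numeric(0)),
                        build_mask(data.frame(start_s = numeric(0),
                                              end_s = numeric(0),
                                              reason = character(0)), 8 * 3600))
  expect_equal(s0$movements_per_hour, 0)
  mz <- build_mask(data.frame(start_s = 0, end_s = 3600, reason = "wake",
                              stringsAsFactors = FALSE), 3600)
  expect_error(session_summary(ev, mz), class = "fm_degenerate_session")
})

test_that("mean/SD aggregation reproduces the printed six-subject report", {
  agg <- aggregate_mean_sd(c(0.83, 0.90, 0.79, 0.85, 0.81, 0.83))
  expect_equal(agg$mean_2dp, "0.83")
  expect_equal(agg$sd_2dp, "0.04")
  expect_equal(aggregate_mean_sd(c(5, 5, 5))$sd, 0)
  set.seed(91)
  agg <- aggregate_mean_sd(rnorm(1000))
  expect_lt(abs(agg$mean), 0.1)
  expect_lt(abs(agg$sd - 1), 0.1)
  expect_error(aggregate_mean_sd(numeric(0)), class = "fm_input_error")
})

test_that("rm_anova: degenerate and worked cases", {
  # identical session columns -> zero condition variance
  x <- matrix(rep(c(1, 5, 9), 4), nrow = 3)
  expect_equal(rm_anova(x)$F_condition, 0)

  # {(1,2),(2,3),(3,4)}: SS_cond = 1.5, SS_err = 0 -> F = Inf with a note
  x <- matrix(c(1, 2, 3, 2, 3, 4), nrow = 3)
  fit <- rm_anova(x)
  expect_equal(unname(fit$ss["conditions"]), 1.5)
  expect_equal(unname(fit$ss["error"]), 0)
  expect_identical(fit$F_condition, Inf)
  expect_false(is.null(fit$note))

  # incomplete designs refuse by default, drop on request
  xm <- matrix(rnorm(12), nrow = 4); xm[2, 1] <- NA
  expect_error(rm_anova(xm), class = "fm_incomplete_design")
  fit <- rm_anova(xm, drop_incomplete = TRUE)
  expect_equal(fit$n_subjects, 3L)
})

test_that("rm_anova matches an independent sequential-SS oracle on random tables", {
  set.seed(101)
  for (i in 1:25) {
    x <- matrix(rnorm(48, mean = 100, sd = 40), nrow = 12, ncol = 4)
    fit <- rm_anova(x)
    # independent decomposition via lm() on the long layout
    d <- data.frame(y = as.vector(x),
                    subject = factor(rep(seq_len(12), times = 4)),
                    session = factor(rep(seq_len(4), each = 12)))
    a <- anova(lm(y ~ subject + session, data = d))
    expect_equal(unname(fit$ss["subjects"]), a["subject", "Sum Sq"], tolerance = 1e-9)
    expect_equal(unname(fit$ss["conditions"]), a["session", "Sum Sq"], tolerance = 1e-9)
    expect_equal(unname(fit$ss["error"]), a["Residuals", "Sum Sq"], tolerance = 1e-9)
    expect_equal(fit$F_condition, a["session", "F value"], tolerance = 1e-9)
    expect_equal(fit$p_condition, a["session", "Pr(>F)"], tolerance = 1e-9)
    # SS conservation
    expect_equal(unname(sum(fit$ss[1:3])), unname(fit$ss["total"]), tolerance = 1e-9)
    expect_equal(fit$df_condition, 3L)
    expect_equal(fit$df_error, 33L)
  }
})

test_that("Scheffe post-hoc: significance, symmetry, conservativeness", {
  # identical columns: nothing significant
  x <- matrix(rep(c(1, 5, 9, 2), 4), nrow = 4) + 0
  fit <- rm_anova(x)
  sch <- scheffe_posthoc(x, fit)
  expect_false(any(sch$significant))

  # one session shifted by +10 SD of the noise: its pairs significant
  set.seed(111)
  x <- matrix(rnorm(48, 100, 5), nrow = 12)
  x[, 4] <- x[, 4] + 50
  fit <- rm_anova(x)
  sch <- scheffe_posthoc(x, fit, alpha = 0.05)
  with4 <- sch$session_a == "S4" | sch$session_b == "S4"
  expect_true(all(sch$significant[with4]))
  expect_false(any(sch$significant[!with4]))

  # column permutation only relabels pairs
  perm <- c(3, 1, 4, 2)
  xp <- x[, perm]
  fitp <- rm_anova(xp)
  schp <- scheffe_posthoc(xp, fitp)
  # map xp's labels back to x's session numbers: xp column i is x column perm[i]
  orig_a <- paste0("S", perm[as.integer(sub("S", "", schp$session_a))])
  orig_b <- paste0("S", perm[as.integer(sub("S", "", schp$session_b))])
  key <- function(a, b, sig) paste(pmin(a, b), pmax(a, b), sig)
  expect_equal(sort(sch$F_contrast), sort(schp$F_contrast), tolerance = 1e-12)
  expect_setequal(key(sch$session_a, sch$session_b, sch$significant),
                  key(orig_a, orig_b, schp$significant))

  # Scheffe p >= unadjusted paired-contrast p at the same MS_error
  sch <- scheffe_posthoc(x, fit)
  p_unadj <- pf(sch$F_contrast, 1, fit$df_error, lower.tail = FALSE)
  expect_true(all(sch$p >= p_unadj - 1e-12))
})
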