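factorial_frame <- function(reps = 3, a = 0, b = 0, c = 0, noise_sd = 0,
                            seed = NULL) {
  d <- expand.grid(replicate = seq_len(reps),
                   state = c("baseline", "stimulated"),
                   stimulus = c("comparator", "trainer"),
                   stringsAsFactors = FALSE)
  mu <- 8 + a * (d$state == "stimulated") + b * (d$stimulus == "trainer") +
    c * (d$state == "stimulated" & d$stimulus == "trainer")
  if (noise_sd > 0) {
    d$value <- withr::with_seed(seed, mu + rnorm(nrow(d), 0, noise_sd))
  } else {
    d$value <- mu
  }
  d
}

test_that("noiseless additive data yields a zero interaction", {
  d <- factorial_frame(a = 1, b = 0.5, c = 0)
  fit <- suppressWarnings(factorial_test(d))  # exact fit: zero residual variance
  expect_equal(fit$interaction_estimate, 0, tolerance = 1e-10)
  expect_equal(fit$beta_comparator, 1, tolerance = 1e-10)
  expect_equal(fit$beta_trainer, 1, tolerance = 1e-10)
})

test_that("the factorial fit matches lm/anova on noisy, unbalanced data", {
  withr::local_seed(14)
  for (rep in 1:10) {
    d <- factorial_frame(reps = 4, a = rnorm(1), b = rnorm(1), c = rnorm(1),
                         noise_sd = 0.5, seed = 1000 + rep)
    drop <- sample(nrow(d), sample(0:2, 1))  # mildly unbalanced
    if (length(drop) > 0) d <- d[-drop, ]
    keep_ok <- all(table(d$stimulus, d$state) >= 2)
    if (!keep_ok) next
    fit <- factorial_test(d)
    ref <- stats::lm(value ~ state * stimulus, data = d)
    ref0 <- stats::lm(value ~ state + stimulus, data = d)
    av <- stats::anova(ref0, ref)
    expect_equal(fit$statistic, av$F[2], tolerance = 1e-8)
    expect_equal(fit$p_interaction, av$`Pr(>F)`[2], tolerance = 1e-8)
    # betas: cell-mean responses
    cm <- tapply(d$value, list(d$stimulus, d$state), mean)
    expect_equal(fit$beta_trainer, cm["trainer", "stimulated"] - cm["trainer", "baseline"],
                 tolerance = 1e-8)
    expect_equal(fit$beta_comparator, cm["comparator", "stimulated"] - cm["comparator", "baseline"],
                 tolerance = 1e-8)
    # F equals the nested RSS formula computed independently
    rss1 <- sum(stats::resid(ref)^2)
    rss0 <- sum(stats::resid(ref0)^2)
    expect_equal(fit$statistic, ((rss0 - rss1) / 1) / (rss1 / (nrow(d) - 4)),
                 tolerance = 1e-8)
  }
})

test_that("interaction recovery: c = 2 with sd 0.1 is estimated within 0.5", {
  n_sim <- 1000
  es <- simulate_training_experiment(n_genes = n_sim, n_responders = n_sim,
                                     trainer_effect = 2, comparator_effect = 0,
                                     noise_sd = 0.1, replicates = 2,
                                     n_planted_sets = 0, n_decoy_sets = 0,
                                     seed = 77)$expression
  fit <- differential_test(es)
  expect_gte(mean(abs(fit$interaction_estimate - 2) < 0.5), 0.95)
})

test_that("degenerate zero-variance genes get the explicit p rule", {
  d_int <- factorial_frame(a = 1, c = 2)   # exact fit, interaction present
  expect_warning(fit <- factorial_test(d_int), "zero residual variance")
  expect_equal(fit$p_interaction, 0)
  d_add <- factorial_frame(a = 1, c = 0)   # exact fit, no interaction
  expect_warning(fit0 <- factorial_test(d_add), "zero residual variance")
  expect_equal(fit0$p_interaction, 1)
})

test_that("missing or under-replicated design cells are fatal and named", {
  d <- factorial_frame(reps = 3)
  d2 <- d[!(d$stimulus == "trainer" & d$state == "stimulated"), ]
  expect_error(factorial_test(d2), "trainer, stimulated")
  d3 <- d[-which(d$stimulus == "comparator" & d$state == "baseline")[1:2], ]
  expect_error(factorial_test(d3), "comparator, baseline")
})

test_that("bh_adjust follows the step-up formula on worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")
})

test_that("bh_adjust agrees with stats::p.adjust and is monotone when sorted", {
  withr::local_seed(15)
  for (rep in 1:50) {
    p <- runif(sample(1:100, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p))
  }
})

test_that("responder selection applies the significance and direction gates", {
  results <- tibble::tibble(
    gene = c("up_sig", "up_ns", "down_sig"),
    cluster = 1L,
    interaction_estimate = c(1.5, 1.5, -1.5),
    p_interaction = c(0.001, 0.20, 0.001)
  )
  sel <- select_responders(results, alpha = 0.05, per_cluster = FALSE)
  expect_equal(sel, "up_sig")
})

test_that("selection is monotone in alpha", {
  withr::local_seed(16)
  results <- tibble::tibble(
    gene = sprintf("g%03d", 1:200),
    cluster = rep(1:4, 50),
    interaction_estimate = rnorm(200),
    p_interaction = runif(200)
  )
  alphas <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  sels <- lapply(alphas, function(a) select_responders(results, alpha = a))
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(sels[[i]] %in% sels[[i + 1]]))
  }
})

test_that("per-cluster adjustment treats each cluster as its own family", {
  results <- tibble::tibble(
    gene = c("a1", "a2", "b1", "b2"),
    cluster = c(1L, 1L, 2L, 2L),
    interaction_estimate = 1,
    p_interaction = c(0.03, 0.04, 0.9, 0.95)
  )
  # within cluster 1 the family is size 2: q = (0.04, 0.04)
  expect_equal(bh_adjust(results$p_interaction[1:2]), c(0.04, 0.04))
  sel_per <- select_responders(results, alpha = 0.05, per_cluster = TRUE)
  sel_glob <- select_responders(results, alpha = 0.05, per_cluster = FALSE)
  expect_setequal(sel_per, c("a1", "a2"))
  # globally the large p-values of cluster 2 dilute the family: q = 0.08
  expect_length(sel_glob, 0)
})

test_that("differential_test wires clusters, adjustment and selection together", {
  sim <- simulate_training_experiment(n_genes = 300, n_responders = 50,
                                      noise_sd = 0.3, n_planted_sets = 0,
                                      n_decoy_sets = 0, seed = 19)
  pr <- response_profiles(sim$expression)
  cl <- cluster_profiles(pr, k = 3, seed = 1)
  res <- differential_test(sim$expression, cl)
  expect_equal(nrow(res), 300)
  expect_true(all(res$p_adjusted >= res$p_interaction - 1e-15))
  expect_true(all(res$selected == (res$p_adjusted < 0.05 & res$interaction_estimate > 0)))
  # the responder set should be strongly enriched for true responders
  expect_gt(mean(res$gene[res$selected] %in% sim$truth$responders), 0.9)
})
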