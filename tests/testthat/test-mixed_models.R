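sim_data <- function(effect, seed, cohort = cohort_spec(),
                     n_sentences = 20) {
  stimuli <- generate_stimuli(stimulus_spec(n_sentences = n_sentences),
                              seed = seed)
  participants <- generate_participants(cohort, seed = seed)
  simulate_sync_outcomes(participants, stimuli, cohort,
                         effect_weak_logodds = effect, seed = seed)
}

test_that("model specs enforce marginality and schema", {
  expect_error(model_spec("y", fixed = c("weight"),
                          interactions = "weight"),
               class = "speechsync_validation_error")
  expect_error(model_spec("y", fixed = c("group", "weight"),
                          interactions = "dprime"),
               class = "speechsync_validation_error")
  spec <- model_spec("synchronized", family = "binomial",
                     fixed = c("group", "weight"), interactions = "weight")
  expect_s3_class(spec, "model_spec")
  expect_error(fit_mixed_model(data.frame(x = 1), spec),
               class = "speechsync_validation_error")
})

test_that("a null group effect stays within sampling noise of zero", {
  dat <- sim_data(effect = 0, seed = 101)
  spec <- model_spec("synchronized", family = "binomial",
                     fixed = c("group", "weight"))
  fit <- fit_mixed_model(dat, spec)
  co <- fit$coefficients
  g <- co[co$term == "groupdyslexic", ]
  expect_lt(abs(g$estimate), 3 * g$se)
  expect_true(fit$converged)
  expect_true(is.finite(fit$aic))
})

test_that("a known weak-syllable group gap is recovered by the interaction", {
  covered <- vapply(1:8, function(i) {
    dat <- sim_data(effect = 0.61, seed = 200 + i)
    spec <- model_spec("synchronized", family = "binomial",
                       fixed = c("group", "weight"),
                       interactions = "weight")
    fit <- fit_mixed_model(dat, spec)
    co <- fit$coefficients
    b <- co[co$term == "groupdyslexic:weightweak", ]
    abs(b$estimate - (-0.61)) <= 1.96 * b$se
  }, logical(1))
  expect_gte(sum(covered), 6L)
})

test_that("backward reduction drops null interactions and keeps real ones", {
  withr::local_seed(33)
  dat <- sim_data(effect = 0.9, seed = 301)
  dat$noise_cov <- standardize(rnorm(nrow(dat)))
  spec <- model_spec("synchronized", family = "binomial",
                     fixed = c("group", "weight", "noise_cov"),
                     interactions = c("weight", "noise_cov"))
  red <- reduce_model(dat, spec)
  expect_true("weight" %in% red$spec$interactions)
  expect_false("noise_cov" %in% red$spec$interactions)
  expect_equal(nrow(red$lrt_table), 2L)
  expect_true(all(c("factor", "aic", "df", "chisq", "p", "kept") %in%
                    names(red$lrt_table)))
  expect_equal(red$lrt_table$df, c(1, 1))
  # a spec without candidate interactions reduces to itself
  spec0 <- model_spec("synchronized", family = "binomial",
                      fixed = c("group", "weight"))
  red0 <- reduce_model(dat, spec0)
  expect_equal(red0$spec$interactions, character(0))
  expect_equal(nrow(red0$lrt_table), 0L)
})

test_that("group contrasts localize the effect to weak syllables", {
  dat <- sim_data(effect = 1.2, seed = 401)
  spec <- model_spec("synchronized", family = "binomial",
                     fixed = c("group", "weight"), interactions = "weight")
  fit <- fit_mixed_model(dat, spec)
  ctr <- pairwise_group_contrasts(fit, by = "weight")
  expect_equal(sort(ctr$level), c("strong", "weak"))
  expect_lt(ctr$p[ctr$level == "weak"], 0.05)
  expect_gt(ctr$p[ctr$level == "strong"], 0.05)
  expect_error(pairwise_group_contrasts(fit, by = "granularity"),
               class = "speechsync_validation_error")
})

test_that("linear mixed models carry Satterthwaite-type p-values", {
  withr::local_seed(55)
  dat <- sim_data(effect = 0, seed = 501)
  dat$abs_asyn <- exp(rnorm(nrow(dat), log(40), 0.4) +
                        0.3 * (dat$weight == "weak"))
  spec <- model_spec("abs_asyn", family = "gaussian", transform = "log",
                     fixed = c("group", "weight"))
  fit <- fit_mixed_model(dat, spec)
  co <- fit$coefficients
  expect_true(all(is.finite(co$p)))
  expect_lt(co$p[co$term == "weightweak"], 0.001)
  expect_gt(co$estimate[co$term == "weightweak"], 0.2)
})

test_that("power simulation is seeded and calibrated at the extremes", {
  p_same <- replicate(2, power_by_simulation(effect_size = 3, n_sims = 3,
                                             seed = 99)$power)
  expect_equal(p_same[1], p_same[2])
  expect_equal(p_same[1], 1)  # an overwhelming effect is always detected
})
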