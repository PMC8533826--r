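# Mixed-effects model stage: declarative model specs, lme4 fitting with the
# optimizer settings used for this design, backward interaction reduction by
# likelihood-ratio test, pairwise group contrasts, simulation-based power.

#' Declare a mixed-effects model
#'
#' A declarative description of one analysis model: the response and its
#' family/transform, main-effect terms, the covariates whose two-way
#' interaction with the group factor is a candidate for inclusion, and the
#' random-effects terms.
#'
#' @param response Response column name.
#' @param family `"binomial"` (synchronization likelihood, hit/miss) or
#'   `"gaussian"` (asynchronies, log RT).
#' @param transform Response transform applied before fitting: `"none"`,
#'   `"log"` (natural log), or `"standardize"` (scale and center).
#' @param fixed Character vector of main-effect terms; must include
#'   `group_var`.
#' @param interactions Character vector of covariates whose `group x`
#'   interaction is tested (each must appear in `fixed`).
#' @param random Character vector of lme4 random-effects terms, e.g.
#'   `c("(1|participant_id)", "(1|stimulus_id)")`.
#' @param group_var Name of the two-level group factor (default `"group"`).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response, family = c("binomial", "gaussian"),
                       transform = c("none", "log", "standardize"),
                       fixed, interactions = character(0),
                       random = c("(1|participant_id)", "(1|stimulus_id)"),
                       group_var = "group") {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (!group_var %in% fixed) {
    stop_validation(sprintf("fixed terms must include the group factor '%s'",
                            group_var))
  }
  missing_main <- setdiff(interactions, fixed)
  if (length(missing_main) > 0L) {
    stop_validation(sprintf("interaction term(s) lack main effects: %s",
                            paste(missing_main, collapse = ", ")))
  }
  structure(list(response = response, family = family, transform = transform,
                 fixed = fixed, interactions = interactions, random = random,
                 group_var = group_var),
            class = "model_spec")
}

spec_formula <- function(spec, interactions = spec$interactions) {
  inter <- if (length(interactions) > 0L) {
    paste(spec$group_var, interactions, sep = ":")
  } else character(0)
  rhs <- paste(c(spec$fixed, inter, spec$random), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs))
}

apply_transform <- function(data, spec) {
  if (spec$transform == "log") {
    data[[spec$response]] <- log(data[[spec$response]])
  } else if (spec$transform == "standardize") {
    data[[spec$response]] <- standardize(data[[spec$response]],
                                         name = spec$response)
  }
  data
}

#' Fit the mixed-effects model described by a spec
#'
#' Delegates the numerical work to lme4: `glmer` with the bobyqa optimizer
#' and 100,000 function evaluations for binomial responses (the settings
#' needed for convergence on this design), `lmerTest::lmer` (REML,
#' Satterthwaite df for p-values) for gaussian responses. On a convergence
#' failure the fit is retried with fallback optimizers (Nelder-Mead, then
#' nloptwrap for linear models).
#'
#' @param data Model frame containing the response, all term columns and
#'   grouping factors.
#' @param spec A [model_spec()].
#' @param interactions Which of the spec's candidate interactions to
#'   include (default all).
#' @return Object of class `sms_fit`: list with the lme4 `model`, `spec`,
#'   `formula`, a `coefficients` table (term, estimate, se, statistic, p),
#'   `aic`, `loglik`, `converged`, `singular`.
#' @export
fit_mixed_model <- function(data, spec, interactions = spec$interactions) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- unique(c(spec$response, spec$fixed))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("data lacks model column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  data <- apply_transform(data, spec)
  form <- spec_formula(spec, interactions)
  fit <- NULL
  optimizers <- if (spec$family == "binomial") {
    c("bobyqa", "Nelder_Mead")
  } else {
    c("nloptwrap", "bobyqa")
  }
  for (opt in optimizers) {
    fit <- if (spec$family == "binomial") {
      suppressMessages(try(lme4::glmer(
        form, data = data, family = stats::binomial(),
        control = lme4::glmerControl(optimizer = opt,
                                     optCtrl = list(maxfun = 1e5))),
        silent = TRUE))
    } else {
      suppressMessages(try(lmerTest::lmer(
        form, data = data, REML = TRUE,
        control = lme4::lmerControl(optimizer = opt,
                                    optCtrl = list(maxeval = 1e5))),
        silent = TRUE))
    }
    if (!inherits(fit, "try-error") && converged_ok(fit)) break
  }
  if (inherits(fit, "try-error")) {
    stop_validation(paste("mixed-model fit failed:", as.character(fit)))
  }
  smry <- stats::coef(summary(fit))
  coefs <- data.frame(term = rownames(smry),
                      estimate = smry[, "Estimate"],
                      se = smry[, "Std. Error"],
                      statistic = smry[, grep("value$", colnames(smry))[1L]],
                      p = if (ncol(smry) >= 4L) smry[, ncol(smry)] else NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = fit, spec = spec, formula = form,
                 interactions = interactions, data = data,
                 coefficients = coefs,
                 aic = stats::AIC(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = converged_ok(fit),
                 singular = lme4::isSingular(fit)),
            class = "sms_fit")
}

converged_ok <- function(fit) {
  if (inherits(fit, "try-error")) return(FALSE)
  cc <- fit@optinfo$conv$lme4
  is.null(cc$code) || cc$code >= 0
}

#' @export
print.sms_fit <- function(x, ...) {
  cat(sprintf("<sms_fit> %s [%s]%s%s\n", deparse(x$formula), x$spec$family,
              if (!x$converged) " (NOT converged)" else "",
              if (x$singular) " (singular)" else ""))
  print(x$coefficients, digits = 3)
  cat(sprintf("AIC %.1f, logLik %.1f\n", x$aic, x$loglik))
  invisible(x)
}

#' Backward reduction of group-by-covariate interactions
#'
#' Starting from the model with all candidate interactions, repeatedly
#' drops the interaction whose removal is least supported: a term is
#' droppable when the likelihood-ratio test against the fuller model is
#' non-significant at `alpha` and removal does not worsen the AIC; among
#' droppable terms the one with the largest LRT p-value goes first.
#' Likelihood comparisons refit REML models with ML. The returned LRT
#' table lists every candidate interaction with the AIC of the model
#' lacking that term, the LRT df, chi-square and p computed against the
#' model containing it (all other terms at their final configuration).
#'
#' @param data Model frame.
#' @param spec A [model_spec()] with candidate interactions.
#' @param alpha LRT significance level for keeping a term (default 0.05).
#' @return List with `spec` (final interactions recorded), `fit` (final
#'   [fit_mixed_model()] result) and `lrt_table` (`data.frame` with
#'   `factor`, `aic`, `df`, `chisq`, `p`, `kept`).
#' @export
reduce_model <- function(data, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  current <- spec$interactions
  fit_cache <- new.env(parent = emptyenv())
  fit_with <- function(terms) {
    key <- paste0("k_", paste(sort(terms), collapse = "+"))
    if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
    f <- fit_mixed_model(data, spec, interactions = terms)
    fit_cache[[key]] <- f
    f
  }
  lrt <- function(full, reduced) {
    tab <- suppressMessages(suppressWarnings(
      stats::anova(reduced$model, full$model, refit = TRUE)))
    list(chisq = tab$Chisq[2L], df = tab$Df[2L],
         p = tab[["Pr(>Chisq)"]][2L], aic_reduced = tab$AIC[1L],
         aic_full = tab$AIC[2L])
  }
  repeat {
    if (length(current) == 0L) break
    full <- fit_with(current)
    cand <- lapply(current, function(term) {
      reduced <- fit_with(setdiff(current, term))
      c(lrt(full, reduced), list(term = term))
    })
    ps <- vapply(cand, function(z) z$p, numeric(1))
    aic_ok <- vapply(cand, function(z) z$aic_reduced <= z$aic_full,
                     logical(1))
    droppable <- which(ps > alpha & aic_ok)
    if (length(droppable) == 0L) break
    drop_term <- cand[[droppable[which.max(ps[droppable])]]]$term
    current <- setdiff(current, drop_term)
  }
  final <- fit_with(current)
  rows <- lapply(spec$interactions, function(term) {
    if (term %in% current) {
      with_term <- final
      without_term <- fit_with(setdiff(current, term))
    } else {
      with_term <- fit_with(union(current, term))
      without_term <- final
    }
    z <- lrt(with_term, without_term)
    data.frame(factor = paste(spec$group_var, term, sep = " x "),
               aic = z$aic_reduced, df = z$df, chisq = z$chisq, p = z$p,
               kept = term %in% current, stringsAsFactors = FALSE)
  })
  final_spec <- spec
  final_spec$interactions <- current
  lrt_table <- if (length(rows) == 0L) {
    data.frame(factor = character(0), aic = numeric(0), df = numeric(0),
               chisq = numeric(0), p = numeric(0), kept = logical(0))
  } else {
    do.call(rbind, rows)
  }
  list(spec = final_spec, fit = final, lrt_table = lrt_table)
}

#' Pairwise group contrasts from a fitted model
#'
#' Estimated marginal means of the group difference, computed with emmeans:
#' at each level of a factor moderator, or at the moderator mean plus/minus
#' one SD for a continuous moderator (both on the scale the model was fit
#' on).
#'
#' @param fit An [fit_mixed_model()] result.
#' @param by Moderator term name (must be in the model).
#' @param at_sd For continuous moderators, evaluate at mean +/- `at_sd` SD
#'   (default 1).
#' @return `data.frame` with `level`, `estimate`, `se`, `statistic`, `p`
#'   for the group contrast at each moderator setting.
#' @export
pairwise_group_contrasts <- function(fit, by, at_sd = 1) {
  stopifnot(inherits(fit, "sms_fit"))
  term_labels <- attr(stats::terms(lme4::nobars(fit$formula)), "term.labels")
  if (!by %in% unlist(strsplit(term_labels, ":"))) {
    stop_validation(sprintf("term '%s' is not in the fitted model", by))
  }
  g <- fit$spec$group_var
  x <- fit$data[[by]]
  if (is.numeric(x)) {
    at <- list(c(mean(x, na.rm = TRUE) - at_sd * stats::sd(x, na.rm = TRUE),
                 mean(x, na.rm = TRUE) + at_sd * stats::sd(x, na.rm = TRUE)))
    names(at) <- by
    emm <- emmeans::emmeans(fit$model, stats::as.formula(paste("~", g, "|", by)),
                            at = at, lmer.df = "satterthwaite")
  } else {
    emm <- emmeans::emmeans(fit$model, stats::as.formula(paste("~", g, "|", by)),
                            lmer.df = "satterthwaite")
  }
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise"))
  stat_col <- intersect(c("z.ratio", "t.ratio"), names(ctr))[1L]
  data.frame(level = as.character(ctr[[by]]),
             estimate = ctr$estimate, se = ctr$SE,
             statistic = ctr[[stat_col]], p = ctr$p.value,
             stringsAsFactors = FALSE)
}

#' Simulation-based power for a focal model term
#'
#' Simulates datasets from the package's synchronization-outcome generator
#' at a given group-by-weight effect size, fits the focal logistic mixed
#' model to each, and reports the fraction of replicates in which the focal
#' coefficient is significant at `alpha` (Wald test), with an exact
#' binomial confidence interval.
#'
#' @param effect_size Group difference for weak syllables on the log-odds
#'   scale (0 simulates the null).
#' @param cohort,stimulus Generator specs ([cohort_spec()],
#'   [stimulus_spec()]).
#' @param formula Model refit to each replicate (default
#'   `synchronized ~ group * weight + (1|participant_id) + (1|stimulus_id)`).
#' @param term Coefficient tested (default the group x weight interaction).
#' @param n_sims Number of replicates (>= 100 recommended for a stable
#'   estimate; smaller values are accepted).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed governing all replicates.
#' @return List with `power`, `ci` (95% exact binomial), `n_sims`,
#'   `n_significant`.
#' @export
power_by_simulation <- function(effect_size, cohort = cohort_spec(),
                                stimulus = stimulus_spec(),
                                formula = synchronized ~ group * weight +
                                  (1 | participant_id) + (1 | stimulus_id),
                                term = "groupdyslexic:weightweak",
                                n_sims = 100, alpha = 0.05, seed = 1) {
  assert_number(n_sims, "n_sims", lower = 1)
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  stimuli <- generate_stimuli(stimulus, seed = seed)
  participants <- generate_participants(cohort, seed = seed)
  seeds <- sample_sim_seeds(n_sims, seed)
  sig <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    dat <- simulate_sync_outcomes(participants, stimuli, cohort,
                                  effect_weak_logodds = effect_size,
                                  seed = seeds[i])
    if (length(unique(dat$synchronized)) < 2L) {
      stop_validation("degenerate generator: outcome has no variability")
    }
    fit <- suppressMessages(suppressWarnings(lme4::glmer(
      formula, data = dat, family = stats::binomial(),
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   optCtrl = list(maxfun = 1e5),
                                   calc.derivs = FALSE))))
    smry <- stats::coef(summary(fit))
    if (!term %in% rownames(smry)) {
      stop_validation(sprintf("focal term '%s' not in the fitted model", term))
    }
    sig[i] <- smry[term, "Pr(>|z|)"] < alpha
  }
  ci <- as.numeric(stats::binom.test(sum(sig), n_sims)$conf.int)
  list(power = mean(sig), ci = ci, n_sims = n_sims,
       n_significant = sum(sig))
}

# Derive per-replicate seeds from one master seed, all below 2^31.
sample_sim_seeds <- function(n, seed) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
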