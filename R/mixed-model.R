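#' Specification of the mixed-effects comparison
#'
#' The analysis model for one outcome: a linear mixed model on the
#' log10(X+1) scale with a fixed mean per treatment-arm x condition cell
#' and a random intercept per ovarian fragment. Significance is declared
#' at `alpha = 0.01`, the stricter level standing in for a multiplicity
#' correction; no further adjustment is applied.
#'
#' Two contrast families are reported: within each arm, the successive
#' condition pairs (F vs F-T, F-T vs D2, D2 vs D6, restricted to the
#' conditions present), and between arms at each condition. By default the
#' between-arm pairs are each drug against its vehicle control (S1P vs
#' CT_NaOH, ZVAD vs CT_DMSO) when those labels are present, otherwise all
#' arm pairs.
#'
#' @param response Outcome label the model is fitted to.
#' @param alpha Significance level in (0, 1); default 0.01.
#' @param df_method `"satterthwaite"` (default) for Satterthwaite
#'   denominator degrees of freedom, or `"normal"` for the large-sample
#'   normal approximation.
#' @param arm_pairs Optional list of 2-element character vectors naming the
#'   between-arm comparisons.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response = "total_primordial", alpha = 0.01,
                       df_method = c("satterthwaite", "normal"),
                       arm_pairs = NULL) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha must lie strictly between 0 and 1")
  structure(list(response = response, alpha = alpha,
                 df_method = match.arg(df_method), arm_pairs = arm_pairs),
            class = "model_spec")
}

#' Log-transform raw density observations
#'
#' Applies `log10(raw + 1)` to the `raw_per_mm2` column, writing
#' `log_value`. Idempotent: a table whose `log_value` column is already the
#' transform of `raw_per_mm2` is returned unchanged, so the transform can
#' sit safely in a pipeline re-run.
#'
#' @param observations Data.frame with a `raw_per_mm2` column.
#' @return The table with a consistent `log_value` column.
#' @export
log_transform_outcomes <- function(observations) {
  if (!"raw_per_mm2" %in% names(observations))
    stop_data("observations need a raw_per_mm2 column")
  observations$log_value <- log10p1(observations$raw_per_mm2)
  observations
}

default_arm_pairs <- function(arms) {
  pairs <- list(c("S1P", "CT_NaOH"), c("ZVAD", "CT_DMSO"))
  pairs <- Filter(function(p) all(p %in% arms), pairs)
  if (length(pairs) == 0 && length(arms) >= 2)
    pairs <- utils::combn(arms, 2, simplify = FALSE)
  pairs
}

# Enumerate the contrast family over the cells present in the data.
build_contrasts <- function(cells, arm_pairs = NULL) {
  arms <- unique(cells$arm)
  conditions <- intersect(CONDITION_LEVELS, unique(cells$condition))
  if (length(conditions) == 0) conditions <- unique(cells$condition)
  out <- list()
  cell_of <- function(a, co) which(cells$arm == a & cells$condition == co)
  for (a in arms) {
    for (i in seq_len(length(conditions) - 1)) {
      i1 <- cell_of(a, conditions[i]); i2 <- cell_of(a, conditions[i + 1])
      if (length(i1) == 1 && length(i2) == 1)
        out[[length(out) + 1]] <- list(
          pair = sprintf("%s: %s vs %s", a, conditions[i], conditions[i + 1]),
          plus = i1, minus = i2)
    }
  }
  if (is.null(arm_pairs)) arm_pairs <- default_arm_pairs(arms)
  for (p in arm_pairs) {
    for (co in conditions) {
      i1 <- cell_of(p[1], co); i2 <- cell_of(p[2], co)
      if (length(i1) == 1 && length(i2) == 1)
        out[[length(out) + 1]] <- list(
          pair = sprintf("%s vs %s @ %s", p[1], p[2], co),
          plus = i1, minus = i2)
    }
  }
  out
}

#' Fit the linear mixed model and compute the contrast family
#'
#' Fits, by REML, `log_value ~ 0 + cell + (1 | fragment_id)` where `cell`
#' is the treatment-arm x condition combination, on section-level density
#' observations; the random intercept absorbs between-fragment
#' heterogeneity. Cells present in the factor structure but empty of data
#' are dropped with a warning, so the analysis always uses the maximum
#' available data. Contrast p-values use Satterthwaite degrees of freedom
#' by default (or a normal approximation).
#'
#' @param observations Data.frame with columns `fragment_id`, `arm`,
#'   `condition`, `log_value` (and optionally `outcome`, filtered to
#'   `spec$response` when present).
#' @param spec A [model_spec()].
#' @return An `ov_mixed_fit`: `fixed_effects` (per-cell estimates and
#'   standard errors), `variance_components` (fragment and residual),
#'   `contrasts` (pair, estimate, se, df, p_value, significant), `alpha`,
#'   and the underlying `lmerMod` as `$model`.
#' @export
fit_mixed_model <- function(observations, spec = model_spec()) {
  if (!inherits(spec, "model_spec")) stop_config("spec must be a model_spec")
  d <- observations
  if ("outcome" %in% names(d)) d <- d[d$outcome == spec$response, , drop = FALSE]
  needed <- c("fragment_id", "arm", "condition", "log_value")
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stop_data("observations lack columns: %s", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop_data("no observations for response '%s'", spec$response)
  if (anyNA(d$log_value)) stop_data("log_value must not contain NAs")

  d$cell <- interaction(d$arm, d$condition, sep = "|", drop = FALSE)
  empty <- setdiff(levels(d$cell), unique(as.character(d$cell)))
  full_grid <- length(unique(d$arm)) * length(unique(d$condition))
  if (length(empty) && length(empty) < full_grid)
    warning(sprintf("dropping empty design cell(s): %s",
                    paste(empty, collapse = ", ")))
  d$cell <- droplevels(d$cell)
  cell_levels <- levels(d$cell)
  cells <- data.frame(cell = cell_levels,
                      arm = sub("\\|.*$", "", cell_levels),
                      condition = sub("^.*\\|", "", cell_levels),
                      stringsAsFactors = FALSE)

  # With a single observation per fragment the random intercept is not
  # separable from the residual; the model then reduces to ordinary least
  # squares on the fragment-level values.
  mixed <- max(table(d$fragment_id)) > 1L
  if (mixed) {
    form <- if (length(cell_levels) > 1L)
      log_value ~ 0 + cell + (1 | fragment_id)
    else log_value ~ 1 + (1 | fragment_id)  # degenerate single-cell design
    fit <- suppressMessages(lmerTest::lmer(
      form, data = d, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    beta <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_comp <- c(fragment = vc$vcov[vc$grp == "fragment_id"],
                  residual = vc$vcov[vc$grp == "Residual"])
    vcv <- as.matrix(stats::vcov(fit))
  } else {
    message("one observation per fragment; fragment variance absorbed into the residual")
    form <- if (length(cell_levels) > 1L) log_value ~ 0 + cell else log_value ~ 1
    fit <- stats::lm(form, data = d)
    beta <- stats::coef(fit)
    var_comp <- c(fragment = NA_real_,
                  residual = summary(fit)$sigma^2)
    vcv <- stats::vcov(fit)
  }
  fixed <- data.frame(cell = cell_levels, arm = cells$arm,
                      condition = cells$condition,
                      estimate = as.numeric(beta),
                      se = sqrt(diag(vcv)), stringsAsFactors = FALSE)

  specs <- build_contrasts(cells, spec$arm_pairs)
  contrasts <- do.call(rbind, lapply(specs, function(ctr) {
    L <- numeric(length(beta)); L[ctr$plus] <- 1; L[ctr$minus] <- -1
    est <- sum(L * beta); se <- sqrt(drop(t(L) %*% vcv %*% L))
    if (spec$df_method == "satterthwaite") {
      if (mixed) {
        ct <- lmerTest::contest1D(fit, L)
        df <- ct$df; p <- ct$`Pr(>|t|)`
      } else {
        df <- fit$df.residual
        p <- 2 * stats::pt(-abs(est / se), df)
      }
    } else {
      df <- Inf; p <- 2 * stats::pnorm(-abs(est / se))
    }
    data.frame(pair = ctr$pair, estimate = est, se = se, df = df,
               p_value = p, stringsAsFactors = FALSE)
  }))
  if (is.null(contrasts))
    contrasts <- data.frame(pair = character(), estimate = numeric(),
                            se = numeric(), df = numeric(),
                            p_value = numeric())
  contrasts$significant <- contrasts$p_value < spec$alpha

  structure(list(response = spec$response, fixed_effects = fixed,
                 variance_components = var_comp,
                 contrasts = contrasts, alpha = spec$alpha,
                 df_method = spec$df_method, n_obs = nrow(d),
                 n_fragments = length(unique(d$fragment_id)),
                 model = fit),
            class = "ov_mixed_fit")
}

#' Re-flag contrast significance at a new alpha
#'
#' Updates the `significant` flags of a fitted model for a different
#' significance level without refitting.
#'
#' @param fit An `ov_mixed_fit`.
#' @param alpha New significance level in (0, 1).
#' @export
update_alpha <- function(fit, alpha) {
  if (!inherits(fit, "ov_mixed_fit")) stop_config("fit must be an ov_mixed_fit")
  if (!is_number(alpha) || alpha < 0 || alpha >= 1)
    stop_config("alpha must lie in [0, 1)")
  fit$alpha <- alpha
  fit$contrasts$significant <- fit$contrasts$p_value < alpha
  fit
}

#' @export
print.ov_mixed_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model for '%s' (%d obs, %d fragments)\n",
              x$response, x$n_obs, x$n_fragments))
  cat(sprintf("variance components: fragment %.5f, residual %.5f\n",
              x$variance_components["fragment"],
              x$variance_components["residual"]))
  cat(sprintf("contrasts (alpha = %g, %s df):\n", x$alpha, x$df_method))
  print(format(x$contrasts, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Type-I error rate of the contrast family under the null
#'
#' Simulates complete studies from a null configuration (all arm x
#' condition effects equal), scores them, fits the mixed model, and
#' reports the fraction of contrast tests rejected at `spec$alpha`
#' (`per_contrast_rate`) together with the fraction of replicates showing
#' any rejection (`any_rejection_rate`). Seed-reproducible.
#'
#' @param spec A [model_spec()].
#' @param null_config A [study_gen_config()] whose effects matrix is
#'   constant.
#' @param n_reps Number of simulated studies (>= 1).
#' @param seed Integer master seed.
#' @return A list with the two rates, `n_tests`, `n_reps` and the vector of
#'   per-replicate rejection counts.
#' @export
type1_error_check <- function(spec, null_config, n_reps, seed = 1L) {
  if (!is_count(n_reps, 1)) stop_config("n_reps must be a count >= 1")
  validate_study_gen_config(null_config)
  eff <- null_config$arm_condition_effects
  if (diff(range(eff)) > 1e-12)
    stop_config("null_config must have all arm x condition effects equal")
  seeds <- derive_seeds(seed, n_reps)
  n_tests <- 0L
  rejections <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- null_config; cfg$seed <- seeds[r]
    ann <- generate_follicle_dataset(cfg)
    obs <- score_study(ann, outcomes = spec$response, level = "section")
    fit <- fit_mixed_model(obs, spec)
    n_tests <- n_tests + nrow(fit$contrasts)
    rejections[r] <- sum(fit$contrasts$significant)
  }
  list(per_contrast_rate = sum(rejections) / n_tests,
       any_rejection_rate = mean(rejections > 0),
       n_tests = n_tests, n_reps = n_reps, rejections = rejections)
}
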