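#' Fulton's condition factor
#'
#' K = 100 * mass / length^3 with mass in grams and fork length in
#' centimetres; an index of plumpness near 1 for salmonids.
#'
#' @param mass_g Body mass in grams (> 0; vectorised).
#' @param fork_length_cm Fork length in centimetres (> 0; vectorised).
#' @return Dimensionless condition factor.
#' @export
condition_factor <- function(mass_g, fork_length_cm) {
  if (any(mass_g <= 0) || any(fork_length_cm <= 0))
    domain_error("mass and fork length must be > 0")
  100 * mass_g / fork_length_cm^3
}

check_factorial <- function(data, factor_a, factor_b) {
  for (f in c(factor_a, factor_b)) {
    if (!f %in% names(data)) design_error(sprintf("factor `%s` not found", f))
    if (length(unique(data[[f]])) < 2)
      design_error(sprintf("factor `%s` needs at least 2 observed levels", f))
  }
  cells <- table(data[[factor_a]], data[[factor_b]])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    design_error(sprintf("empty design cell: (%s, %s)",
                         rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  invisible(NULL)
}

term_expr <- function(var, log10_flag) if (log10_flag) sprintf("log10(%s)", var) else var

build_model <- function(data, response, factor_a, factor_b, covariate = NULL,
                        log10_response = FALSE, log10_covariate = FALSE,
                        slope_interactions = FALSE, sum_contrasts = FALSE) {
  data[[factor_a]] <- factor(data[[factor_a]])
  data[[factor_b]] <- factor(data[[factor_b]])
  if (log10_response && any(data[[response]] <= 0))
    domain_error(sprintf("`%s` must be positive for a log10 transform", response))
  rhs <- sprintf("%s * %s", factor_a, factor_b)
  if (!is.null(covariate)) {
    if (log10_covariate && any(data[[covariate]] <= 0))
      domain_error(sprintf("`%s` must be positive for a log10 transform", covariate))
    if (stats::var(data[[covariate]]) == 0)
      trout_error("covariate is constant: covariate slope is not estimable",
                  "troutherm_rank_error")
    cov_term <- term_expr(covariate, log10_covariate)
    rhs <- if (slope_interactions) {
      sprintf("%s * %s * %s", cov_term, factor_a, factor_b)
    } else {
      sprintf("%s + %s", cov_term, rhs)
    }
  }
  form <- stats::as.formula(sprintf("%s ~ %s", term_expr(response, log10_response), rhs))
  contr <- if (sum_contrasts) {
    stats::setNames(list("contr.sum", "contr.sum"), c(factor_a, factor_b))
  } else NULL
  stats::lm(form, data = data, contrasts = contr)
}

anova_table_from_fit <- function(fit, ss_type) {
  tab <- if (ss_type == "I") {
    a <- stats::anova(fit)
    data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
               mean_sq = a$`Mean Sq`, F = a$`F value`, p = a$`Pr(>F)`,
               stringsAsFactors = FALSE)
  } else {
    a <- car::Anova(fit, type = 3)
    keep <- rownames(a) != "(Intercept)"
    data.frame(term = rownames(a)[keep], df = a$Df[keep], sum_sq = a$`Sum Sq`[keep],
               mean_sq = a$`Sum Sq`[keep] / a$Df[keep],
               F = a$`F value`[keep], p = a$`Pr(>F)`[keep],
               stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Two-factor analysis of variance
#'
#' Fits the full factorial model A + B + A:B and returns the term table.
#' Sums of squares are sequential (Type I, the default of `stats::anova()`)
#' with `factor_a` entered first; Type III with sum-to-zero contrasts is
#' available via `ss_type = "III"` and is near-identical for (nearly)
#' balanced designs. The response may be log10-transformed, the standard
#' variance-stabilising choice for metabolic rates and body mass.
#'
#' @param data Data frame with one row per fish.
#' @param response Name of the response column.
#' @param factor_a,factor_b Names of the two crossed factors (defaults
#'   `"population"` and `"acclimation_temp"`).
#' @param log10_response Log10-transform the response (default FALSE).
#' @param ss_type `"I"` (sequential) or `"III"` (partial).
#' @return An object of class `"troutherm_anova"`: list with `table` (term,
#'   df, sum_sq, mean_sq, F, p; last row `Residuals`), the underlying
#'   `model`, and metadata.
#' @export
two_way_anova <- function(data, response, factor_a = "population",
                          factor_b = "acclimation_temp",
                          log10_response = FALSE, ss_type = c("I", "III")) {
  ss_type <- match.arg(ss_type)
  check_factorial(data, factor_a, factor_b)
  fit <- build_model(data, response, factor_a, factor_b,
                     log10_response = log10_response,
                     sum_contrasts = ss_type == "III")
  tab <- anova_table_from_fit(fit, ss_type)
  structure(list(table = tab, model = fit, response = response,
                 factor_a = factor_a, factor_b = factor_b,
                 covariate = NULL, log10_response = log10_response,
                 log10_covariate = FALSE, ss_type = ss_type, data = data),
            class = "troutherm_anova")
}

#' Two-factor analysis of covariance with a body-mass covariate
#'
#' Fits covariate + A + B + A:B with the covariate entered first, so the
#' sequential (Type I) table tests the factors after adjusting for body
#' mass. When both response and covariate are log10-transformed (the
#' default), the fitted common covariate slope is the allometric mass
#' exponent of the response.
#'
#' @inheritParams two_way_anova
#' @param covariate Name of the covariate column (default `"mass_g"`).
#' @param log10_covariate Log10-transform the covariate; defaults to
#'   `log10_response`, which is what makes the slope a mass exponent.
#' @return An object of class `c("troutherm_ancova", "troutherm_anova")`;
#'   additionally carries `covariate_slope` (estimate and SE of the common
#'   slope).
#' @export
two_way_ancova <- function(data, response, factor_a = "population",
                           factor_b = "acclimation_temp", covariate = "mass_g",
                           log10_response = TRUE, log10_covariate = log10_response,
                           ss_type = c("I", "III")) {
  ss_type <- match.arg(ss_type)
  check_factorial(data, factor_a, factor_b)
  fit <- build_model(data, response, factor_a, factor_b, covariate,
                     log10_response, log10_covariate,
                     sum_contrasts = ss_type == "III")
  tab <- anova_table_from_fit(fit, ss_type)
  cov_name <- term_expr(covariate, log10_covariate)
  sm <- summary(fit)$coefficients
  slope <- c(estimate = unname(sm[cov_name, "Estimate"]),
             se = unname(sm[cov_name, "Std. Error"]))
  structure(list(table = tab, model = fit, response = response,
                 factor_a = factor_a, factor_b = factor_b,
                 covariate = covariate, covariate_slope = slope,
                 log10_response = log10_response,
                 log10_covariate = log10_covariate, ss_type = ss_type,
                 data = data),
            class = c("troutherm_ancova", "troutherm_anova"))
}

#' @export
print.troutherm_anova <- function(x, ...) {
  kind <- if (inherits(x, "troutherm_ancova")) "ANCOVA" else "ANOVA"
  cat(sprintf("Two-factor %s of %s%s (Type %s SS)\n", kind,
              if (x$log10_response) "log10 " else "", x$response, x$ss_type))
  print(x$table, digits = 4)
  if (!is.null(x$covariate_slope))
    cat(sprintf("Common covariate slope: %.4f (SE %.4f)\n",
                x$covariate_slope["estimate"], x$covariate_slope["se"]))
  invisible(x)
}

#' Test of homogeneity of regression slopes
#'
#' Extra-sum-of-squares F-test comparing the common-slope ANCOVA against
#' the model that additionally lets the covariate slope vary with the
#' factors (covariate x A, covariate x B, covariate x A:B). A large F
#' (small p) indicates the mass relationship differs between design cells,
#' violating the ANCOVA assumption.
#'
#' @inheritParams two_way_ancova
#' @return List with `F`, `p`, `df1`, `df2`.
#' @export
homogeneity_of_slopes <- function(data, response, factor_a = "population",
                                  factor_b = "acclimation_temp",
                                  covariate = "mass_g",
                                  log10_response = TRUE,
                                  log10_covariate = log10_response) {
  check_factorial(data, factor_a, factor_b)
  m0 <- build_model(data, response, factor_a, factor_b, covariate,
                    log10_response, log10_covariate)
  m1 <- build_model(data, response, factor_a, factor_b, covariate,
                    log10_response, log10_covariate, slope_interactions = TRUE)
  if (stats::df.residual(m1) < 1)
    design_error("insufficient residual degrees of freedom for the slope-heterogeneity model")
  cmp <- stats::anova(m0, m1)
  list(F = cmp$F[2], p = cmp$`Pr(>F)`[2],
       df1 = cmp$Df[2], df2 = stats::df.residual(m1))
}

#' Adjusted least-squares group means at a reference mass
#'
#' Model-predicted group means with the covariate fixed at
#' `reference_mass` (e.g. 108.6 g, a study-wide mean body mass), with
#' standard errors from the coefficient covariance. For log10-transformed
#' responses the default reporting scale is the back-transformed original
#' unit with a delta-method SEM. Means for one factor average over the
#' levels of the other with equal weights.
#'
#' @param x A `"troutherm_anova"`/`"troutherm_ancova"` object.
#' @param group_factor Factor whose adjusted means are wanted.
#' @param reference_mass Covariate value at which means are predicted
#'   (ignored for a covariate-free ANOVA). A warning is issued if it lies
#'   outside the observed mass range.
#' @param back_transform Report back-transformed means (default TRUE; only
#'   relevant for transformed responses).
#' @return Data frame `group`, `ls_mean`, `sem`, `df`, `back_transformed`,
#'   with attribute `reference_mass`.
#' @export
adjusted_means <- function(x, group_factor, reference_mass = 108.6,
                           back_transform = TRUE) {
  stopifnot(inherits(x, "troutherm_anova"))
  at <- NULL
  if (!is.null(x$covariate)) {
    if (reference_mass <= 0) domain_error("reference_mass must be > 0")
    rng <- range(x$data[[x$covariate]])
    if (reference_mass < rng[1] || reference_mass > rng[2])
      warning(sprintf("reference mass %.1f g lies outside the observed range [%.1f, %.1f]",
                      reference_mass, rng[1], rng[2]))
    at <- stats::setNames(list(reference_mass), x$covariate)
  }
  emm <- emmeans::emmeans(x$model, specs = group_factor, at = at)
  bt <- back_transform && x$log10_response
  sm <- summary(emm, type = if (bt) "response" else "lp")
  est_col <- intersect(c("response", "emmean"), names(sm))[1]
  out <- data.frame(group = as.character(sm[[group_factor]]),
                    ls_mean = sm[[est_col]], sem = sm$SE, df = sm$df,
                    back_transformed = bt, stringsAsFactors = FALSE)
  attr(out, "reference_mass") <- if (is.null(x$covariate)) NA_real_ else reference_mass
  out
}

#' Allometric mass exponent of a response
#'
#' The slope of log10(response) on log10(mass). The default (`method =
#' "ancova"`) is the common within-cell slope from the factorial ANCOVA,
#' which adjusts for population and acclimation-temperature structure;
#' `method = "pooled"` is the simple pooled regression across all fish.
#'
#' @param data Data frame with the response, covariate and the two factors.
#' @param response Name of the response column (positive values).
#' @param covariate Mass column (default `"mass_g"`).
#' @param method `"ancova"` or `"pooled"`.
#' @inheritParams two_way_anova
#' @return List with `exponent` and `se`.
#' @export
mass_exponent <- function(data, response, covariate = "mass_g",
                          method = c("ancova", "pooled"),
                          factor_a = "population", factor_b = "acclimation_temp") {
  method <- match.arg(method)
  if (nrow(data) < 3) data_error("at least 3 fish required")
  if (any(data[[response]] <= 0) || any(data[[covariate]] <= 0))
    domain_error("responses and masses must be positive for the log-log fit")
  if (method == "ancova") {
    fit <- two_way_ancova(data, response, factor_a, factor_b, covariate,
                          log10_response = TRUE, log10_covariate = TRUE)
    list(exponent = unname(fit$covariate_slope["estimate"]),
         se = unname(fit$covariate_slope["se"]))
  } else {
    fit <- stats::lm(log10(data[[response]]) ~ log10(data[[covariate]]))
    sm <- summary(fit)$coefficients
    list(exponent = unname(sm[2, "Estimate"]), se = unname(sm[2, "Std. Error"]))
  }
}

#' Tukey HSD pairwise comparisons of (adjusted) group means
#'
#' All pairwise comparisons within one factor using the studentized-range
#' distribution on the model's residual degrees of freedom; unbalanced
#' groups are handled by the Tukey-Kramer form. For ANCOVA fits the
#' comparisons are between covariate-adjusted means (differences are on the
#' model, i.e. possibly log10, scale). Intended to follow a significant
#' omnibus F for that factor.
#'
#' @param x A `"troutherm_anova"`/`"troutherm_ancova"` object, or a plain
#'   `lm` fit containing `group_factor`.
#' @param group_factor Factor to compare within.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame of class `"troutherm_tukey"`: `group_a`, `group_b`,
#'   `difference`, `se`, `q_statistic`, `adjusted_p`, `significant`.
#' @export
tukey_hsd <- function(x, group_factor, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) domain_error("alpha must be in (0, 1)")
  model <- if (inherits(x, "troutherm_anova")) x$model else x
  emm <- emmeans::emmeans(model, specs = group_factor)
  if (nrow(summary(emm)) < 2) design_error("Tukey HSD needs at least two groups")
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  labels <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  out <- data.frame(
    group_a = vapply(labels, `[`, "", 1),
    group_b = vapply(labels, `[`, "", 2),
    difference = prs$estimate,
    se = prs$SE,
    q_statistic = abs(prs$t.ratio) * sqrt(2),
    adjusted_p = prs$p.value,
    significant = prs$p.value < alpha,
    stringsAsFactors = FALSE)
  class(out) <- c("troutherm_tukey", "data.frame")
  out
}
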