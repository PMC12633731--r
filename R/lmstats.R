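#' Mixed-effects comparison tables
#'
#' Linear mixed-effects models with a random intercept per fish (REML, via
#' nlme), optional per-group residual variance weights for unequal
#' variances, ANOVA-type F tables with marginal and conditional R-squared,
#' estimated marginal means, and Bonferroni-corrected pairwise contrasts.
#'
#' @name lmstats
NULL

#' Fit a linear mixed-effects model with a random fish intercept
#'
#' @param data Data frame; must contain the variables in `fixed` and the
#'   grouping column named by `random`.
#' @param fixed Model formula for the fixed effects, e.g.
#'   `value ~ behaviour * muscle`.
#' @param random Name of the grouping column for the random intercept
#'   (default `"fish"`); `NULL` fits a plain fixed-effects linear model.
#' @param weights Optional column name: per-level residual variance
#'   weights (`nlme::varIdent`) for that stratification, the "correction
#'   for unequal variance".
#' @param method `"REML"` (default) or `"ML"`.
#' @return List of class `fin_lme`: `model`, `fixed`, `random`, `data`,
#'   `converged`, `fallback` (TRUE when a singular mixed fit was replaced
#'   by a fixed-effects model with the grouping factor as a block).
#' @export
fit_lme <- function(data, fixed, random = "fish", weights = NULL,
                    method = "REML") {
  fixed <- as.formula(fixed)
  if (!is.null(random)) {
    if (!random %in% names(data)) stop("no grouping column '", random, "'")
    if (length(unique(data[[random]])) < 2)
      stop("need at least 2 groups in '", random, "'")
    data[[random]] <- factor(data[[random]])
  }
  for (v in all.vars(fixed)[-1])
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  wgt <- if (!is.null(weights))
    nlme::varIdent(form = as.formula(paste0("~ 1 | ", weights))) else NULL

  if (is.null(random)) {
    model <- stats::lm(fixed, data = data)
    return(structure(list(model = model, fixed = fixed, random = NULL,
                          weights = weights, data = data, converged = TRUE,
                          fallback = FALSE),
                     class = "fin_lme"))
  }
  ranform <- as.formula(paste0("~ 1 | ", random))
  args <- list(fixed = fixed, random = ranform, data = data, method = method,
               control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                          opt = "optim"))
  if (!is.null(wgt)) args$weights <- wgt
  # do.call inlines the arguments into the recorded call, so downstream
  # tools (emmeans) can re-evaluate it outside this frame
  fit <- tryCatch(do.call(nlme::lme, args), error = function(e) e)
  if (inherits(fit, "error")) {
    warning("mixed fit failed (", conditionMessage(fit),
            "); falling back to a fixed-effects model with '", random,
            "' as a blocking factor")
    fb_form <- stats::update(fixed, as.formula(paste0(". ~ . + ", random)))
    model <- stats::lm(fb_form, data = data)
    return(structure(list(model = model, fixed = fixed, random = random,
                          weights = weights, data = data, converged = FALSE,
                          fallback = TRUE),
                     class = "fin_lme"))
  }
  structure(list(model = fit, fixed = fixed, random = random,
                 weights = weights, data = data, converged = TRUE,
                 fallback = FALSE),
            class = "fin_lme")
}

#' @export
print.fin_lme <- function(x, ...) {
  cat("Mixed-effects fit:", deparse(x$fixed),
      if (!is.null(x$random)) paste0("+ (1 | ", x$random, ")") else "",
      if (x$fallback) "[fixed-effects fallback]" else "", "\n")
  invisible(x)
}

# Mean residual variance across varIdent strata (weighted by stratum size);
# equals sigma^2 for a homoskedastic fit.
residual_variance <- function(fit) {
  s2 <- fit$sigma^2
  vs <- fit$modelStruct$varStruct
  if (is.null(vs)) return(s2)
  w <- nlme::varWeights(vs)        # 1 / delta_g per observation
  mean(s2 / w^2)
}

#' ANOVA-type table with marginal and conditional R-squared
#'
#' Marginal (type III style) F tests per fixed term with nlme's
#' containment denominator degrees of freedom, plus the
#' variance-decomposition R-squared pair: marginal `R2m` uses the fixed
#' effects only, conditional `R2c` adds the random intercept variance.
#'
#' @param fit A `fin_lme` from [fit_lme()].
#' @return Data frame with `term`, `F`, `df_num`, `df_den`, `p`, `R2m`,
#'   `R2c` (R2 values repeated on every row).
#' @export
anova_table <- function(fit) {
  stopifnot(inherits(fit, "fin_lme"))
  if (!fit$converged && !fit$fallback) stop("fit did not converge")
  if (inherits(fit$model, "lm")) {
    a <- anova(fit$model)
    terms <- setdiff(rownames(a), "Residuals")
    if (!is.null(fit$random)) terms <- setdiff(terms, fit$random)
    out <- data.frame(term = terms,
                      F = a[terms, "F value"],
                      df_num = a[terms, "Df"],
                      df_den = a["Residuals", "Df"],
                      p = a[terms, "Pr(>F)"])
    r2 <- summary(fit$model)$r.squared
    out$R2m <- r2; out$R2c <- r2
    rownames(out) <- NULL
    return(out)
  }
  a <- nlme::anova.lme(fit$model, type = "marginal")
  terms <- setdiff(rownames(a), "(Intercept)")
  var_f <- var(predict(fit$model, level = 0))
  var_a <- as.numeric(nlme::VarCorr(fit$model)["(Intercept)", "Variance"])
  var_e <- residual_variance(fit$model)
  tot <- var_f + var_a + var_e
  out <- data.frame(term = terms,
                    F = a[terms, "F-value"],
                    df_num = a[terms, "numDF"],
                    df_den = a[terms, "denDF"],
                    p = a[terms, "p-value"],
                    R2m = var_f / tot,
                    R2c = (var_f + var_a) / tot)
  rownames(out) <- NULL
  out
}

#' Estimated marginal means
#'
#' Model-based group means averaged over the levels of the other factors
#' with equal (balanced) reference weights, with standard errors from the
#' fixed-effect covariance. For a balanced design these equal the
#' arithmetic group means.
#'
#' @param fit A `fin_lme`.
#' @param specs Grouping, e.g. `~ behaviour` or `~ behaviour | muscle`
#'   (passed to `emmeans`).
#' @return Data frame with the grouping columns plus `emmean`, `sem`,
#'   `df`, `lower`, `upper`.
#' @export
emmeans_table <- function(fit, specs) {
  stopifnot(inherits(fit, "fin_lme"))
  em <- emmeans::emmeans(fit$model, specs, data = fit$data)
  s <- as.data.frame(em)
  names(s)[names(s) == "SE"] <- "sem"
  names(s)[names(s) == "lower.CL"] <- "lower"
  names(s)[names(s) == "upper.CL"] <- "upper"
  s
}

#' Bonferroni-corrected pairwise contrasts
#'
#' Pairwise contrasts of estimated marginal means with
#' `p_bonf = min(1, p * m)`, where the family size `m` defaults to the
#' total number of contrasts computed for the variable (across all `by`
#' groups, matching the layout of a muscle-by-behaviour comparison table).
#'
#' @param fit A `fin_lme`.
#' @param specs Factor(s) to compare, e.g. `~ muscle | behaviour` (pairwise
#'   within each behaviour) or `~ behaviour | muscle`.
#' @param m Family size for the correction; default: total number of rows.
#' @return Data frame with `contrast`, any `by` columns, `estimate`, `sem`,
#'   `df`, `p`, `p_bonf`.
#' @export
pairwise_bonferroni <- function(fit, specs, m = NULL) {
  stopifnot(inherits(fit, "fin_lme"))
  em <- emmeans::emmeans(fit$model, specs, data = fit$data)
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "none"))
  names(ct)[names(ct) == "SE"] <- "sem"
  names(ct)[names(ct) == "p.value"] <- "p"
  if (is.null(m)) m <- nrow(ct)
  ct$p_bonf <- pmin(1, ct$p * m)
  ct
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(x) - mean(y)) / pooled sd`.
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @return Scalar effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Evans Blue fluorescence analysis
#'
#' Background-subtracts the cell intensities, summarizes per-muscle means,
#' fits per size class a linear model
#' `intensity ~ pct_fin_length + treatment` (optionally with their
#' interaction), and computes Cohen's d for the treatment effect per
#' muscle. Background-subtracted intensities may be negative (dark cells);
#' no clipping is applied. Size classes with a single treatment are
#' skipped with a warning.
#'
#' @param table Data frame with `fish`, `size_class`, `treatment`
#'   (`walked` / `control`), `muscle`, `pct_fin_length`, `cell_intensity`,
#'   `background`.
#' @param interaction Include `pct_fin_length:treatment` (default FALSE).
#' @return List with `models` (per size class coefficient table),
#'   `effect_sizes` (per size class x muscle Cohen's d), `muscle_means`.
#' @export
evans_blue_analysis <- function(table, interaction = FALSE) {
  req <- c("fish", "size_class", "treatment", "muscle", "pct_fin_length",
           "cell_intensity", "background")
  stopifnot(all(req %in% names(table)))
  table$intensity <- table$cell_intensity - table$background
  table$treatment <- factor(table$treatment, levels = c("control", "walked"))

  muscle_means <- aggregate(intensity ~ size_class + treatment + muscle + fish,
                            data = table, FUN = mean)

  form <- if (interaction) intensity ~ pct_fin_length * treatment
  else intensity ~ pct_fin_length + treatment
  models <- list(); effects <- list()
  for (sc in unique(table$size_class)) {
    sub <- table[table$size_class == sc, , drop = FALSE]
    if (length(unique(sub$treatment)) < 2) {
      warning("size class '", sc, "' has a single treatment; skipped")
      next
    }
    fit <- stats::lm(form, data = sub)
    cf <- summary(fit)$coefficients
    models[[sc]] <- data.frame(size_class = sc, term = rownames(cf),
                               estimate = cf[, 1], se = cf[, 2],
                               t = cf[, 3], p = cf[, 4])
    effects[[sc]] <- do.call(rbind, lapply(unique(sub$muscle), function(mus) {
      w <- sub$intensity[sub$muscle == mus & sub$treatment == "walked"]
      c0 <- sub$intensity[sub$muscle == mus & sub$treatment == "control"]
      data.frame(size_class = sc, muscle = mus,
                 cohens_d = if (length(w) >= 2 && length(c0) >= 2)
                   cohens_d(w, c0) else NA_real_)
    }))
  }
  bind <- function(x) if (length(x))
    do.call(rbind, c(x, list(make.row.names = FALSE))) else NULL
  list(models = bind(models), effect_sizes = bind(effects),
       muscle_means = muscle_means)
}
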