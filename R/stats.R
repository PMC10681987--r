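#' Factorial ANOVA over a long table
#'
#' Fits a fully crossed fixed-factor linear model (e.g. time bin x exposure
#' environment on baseline-corrected LIs) and returns F tests for all main
#' effects and interactions. Factors are coded sum-to-zero and, by default,
#' tested with Type III sums of squares, which is well-defined on the
#' unbalanced tables that longitudinal recordings produce; Type II is
#' available.
#'
#' @param data long-format data frame.
#' @param response response column name (numeric).
#' @param factors character vector of factor column names (crossed).
#' @param covariates optional character vector of numeric covariate columns
#'   (entered additively).
#' @param ss_type `"III"` (default) or `"II"`.
#' @return a `lat_anova` object; see [tidy()] for the effect table
#'   (`effect`, `df`, `sumsq`, `statistic`, `p_value`, `significant` at
#'   alpha 0.05).
#' @export
factorial_anova <- function(data, response, factors, covariates = NULL,
                            ss_type = c("III", "II")) {
  ss_type <- match.arg(ss_type)
  stopifnot(all(c(response, factors, covariates) %in% names(data)))
  df <- as.data.frame(data)
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2)
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    stats::contrasts(df[[f]]) <- stats::contr.sum(nlevels(df[[f]]))
  }
  rhs <- paste(c(paste(factors, collapse = " * "), covariates),
               collapse = " + ")
  fit <- stats::lm(stats::reformulate(rhs, response), data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  an <- car::Anova(fit, type = ss_type)
  tab <- as.data.frame(an)
  keep <- !rownames(tab) %in% c("(Intercept)", "Residuals")
  res <- tibble::tibble(
    effect = rownames(tab)[keep],
    df = tab$Df[keep],
    df_error = tab$Df[rownames(tab) == "Residuals"],
    sumsq = tab$`Sum Sq`[keep],
    statistic = tab$`F value`[keep],
    p_value = tab$`Pr(>F)`[keep]) |>
    dplyr::mutate(significant = .data$p_value < 0.05)
  structure(list(model = fit, table = res, ss_type = ss_type,
                 response = response),
            class = "lat_anova")
}

#' @export
tidy.lat_anova <- function(x, ...) x$table

#' @export
glance.lat_anova <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
                 sigma = s$sigma, df_residual = x$model$df.residual,
                 n = length(stats::fitted(x$model)))
}

#' @export
print.lat_anova <- function(x, ...) {
  cat("<lat_anova> Type ", x$ss_type, " factorial ANOVA on '", x$response,
      "'\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Pairwise post-hoc t tests with Bonferroni correction
#'
#' Two-sided independent-samples t tests between two groups at each level of
#' a stratifying variable (e.g. Con-Env vs Het-Env at each time bin),
#' Bonferroni-corrected for the number of comparisons actually made:
#' `p_adjusted = min(1, p * n_pairs)`.
#'
#' By default each comparison uses only the two cells' own data with a
#' pooled-variance (Student) t. With `pooled_error = TRUE` the error term is
#' instead the residual mean square of the full two-way model over all
#' cells, giving every comparison the model's residual degrees of freedom.
#'
#' @param data long-format data frame.
#' @param response numeric response column name.
#' @param group column with the two groups to compare.
#' @param by optional stratifying column; one comparison per level. If
#'   omitted, a single comparison is made.
#' @param pooled_error use the two-way-model residual error term (default
#'   `FALSE`).
#' @return tibble: `by` level, group means, `statistic` (t), `df`,
#'   `p_value`, `p_adjusted`, `significant` (alpha 0.05 on adjusted p).
#' @export
posthoc_pairwise <- function(data, response, group, by = NULL,
                             pooled_error = FALSE) {
  stopifnot(all(c(response, group, by) %in% names(data)))
  g_levels <- sort(unique(data[[group]]))
  if (length(g_levels) != 2)
    stop("group column must have exactly 2 levels", call. = FALSE)
  strata <- if (is.null(by)) list(NULL) else sort(unique(data[[by]]))

  mse <- df_err <- NULL
  if (pooled_error) {
    df2 <- as.data.frame(data)
    rhs <- if (is.null(by)) group else paste(group, "*", by)
    fit <- stats::lm(stats::reformulate(rhs, response), data = df2)
    mse <- sum(stats::resid(fit)^2) / fit$df.residual
    df_err <- fit$df.residual
  }

  rows <- purrr::map(strata, function(lv) {
    d <- if (is.null(lv)) data else data[data[[by]] == lv, ]
    x <- d[[response]][d[[group]] == g_levels[1]]
    y <- d[[response]][d[[group]] == g_levels[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("fewer than 2 observations per group",
           if (!is.null(lv)) paste0(" at level ", lv), call. = FALSE)
    if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
      tt <- list(statistic = 0, parameter = length(x) + length(y) - 2,
                 p.value = 1)
      flag <- "degenerate_zero_variance"
    } else if (pooled_error) {
      se <- sqrt(mse * (1 / length(x) + 1 / length(y)))
      tval <- (mean(x) - mean(y)) / se
      tt <- list(statistic = tval, parameter = df_err,
                 p.value = 2 * stats::pt(-abs(tval), df_err))
      flag <- NA_character_
    } else {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      tt <- list(statistic = unname(ht$statistic),
                 parameter = unname(ht$parameter), p.value = ht$p.value)
      flag <- NA_character_
    }
    tibble::tibble(level = if (is.null(lv)) NA else lv,
                   mean_1 = mean(x), mean_2 = mean(y),
                   statistic = tt$statistic, df = tt$parameter,
                   p_value = tt$p.value, flag = flag)
  })
  out <- dplyr::bind_rows(rows)
  n_pairs <- nrow(out)
  out |>
    dplyr::mutate(n_comparisons = n_pairs,
                  p_adjusted = pmin(1, .data$p_value * n_pairs),
                  significant = .data$p_adjusted < 0.05)
}

#' Repeated-measures ANCOVA
#'
#' Mixed within/between analysis over recording sites: a within-unit
#' repeated factor (e.g. stimulus category, zebra finch vs canary songs),
#' between-unit factors (e.g. hemisphere, exposure environment), and an
#' optional numeric covariate (e.g. recording depth, since response
#' magnitudes decrease with depth). Fitted with `aov` using an
#' `Error(unit/within)` stratification; units missing any within-factor
#' level are dropped and reported.
#'
#' @param data long-format data frame, one row per (unit, within level).
#' @param response numeric response column name.
#' @param within repeated-factor column name.
#' @param between character vector of between-unit factor columns.
#' @param unit unit-identifier column (site/subject).
#' @param covariate optional numeric covariate column; silently dropped
#'   (with a warning) if constant.
#' @return a `lat_rm_ancova` object; [tidy()] gives `effect`, `stratum`,
#'   `df`, `df_error`, `statistic`, `p_value`, `significant`.
#' @export
rm_ancova <- function(data, response, within, between, unit,
                      covariate = NULL) {
  stopifnot(all(c(response, within, between, unit, covariate) %in%
                  names(data)))
  df <- as.data.frame(data)
  df[[unit]] <- factor(df[[unit]])
  df[[within]] <- factor(df[[within]])
  for (f in between) df[[f]] <- factor(df[[f]])

  complete <- tapply(df[[within]], df[[unit]],
                     function(w) all(levels(df[[within]]) %in% w))
  dropped <- names(complete)[!complete]
  if (length(dropped) > 0) {
    warning("units dropped for missing within-factor levels: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    df <- df[!df[[unit]] %in% dropped, ]
    df[[unit]] <- droplevels(df[[unit]])
  }
  if (!is.null(covariate) && stats::var(df[[covariate]]) == 0) {
    warning("covariate '", covariate, "' is constant; dropped",
            call. = FALSE)
    covariate <- NULL
  }
  rhs <- paste(c(covariate, paste(c(between, within), collapse = " * ")),
               collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs, "+ Error(", unit, "/",
                                  within, ")"))
  fit <- stats::aov(form, data = df)
  tabs <- summary(fit)
  rows <- purrr::imap(tabs, function(tab, stratum) {
    t1 <- as.data.frame(tab[[1]])
    eff <- trimws(rownames(t1))
    resid_df <- t1$Df[eff == "Residuals"]
    keep <- eff != "Residuals"
    if (!any(keep)) return(NULL)
    tibble::tibble(effect = eff[keep], stratum = stratum,
                   df = t1$Df[keep],
                   df_error = if (length(resid_df)) resid_df else NA_real_,
                   statistic = t1$`F value`[keep],
                   p_value = t1$`Pr(>F)`[keep])
  })
  res <- dplyr::bind_rows(rows) |>
    dplyr::filter(!is.na(.data$statistic)) |>
    dplyr::mutate(significant = .data$p_value < 0.05)
  structure(list(model = fit, table = res, dropped_units = dropped,
                 response = response),
            class = "lat_rm_ancova")
}

#' @export
tidy.lat_rm_ancova <- function(x, ...) x$table

#' @export
glance.lat_rm_ancova <- function(x, ...) {
  tibble::tibble(n_effects = nrow(x$table),
                 n_dropped_units = length(x$dropped_units))
}

#' @export
print.lat_rm_ancova <- function(x, ...) {
  cat("<lat_rm_ancova> repeated-measures ANCOVA on '", x$response, "'\n",
      sep = "")
  if (length(x$dropped_units))
    cat("  dropped units:", paste(x$dropped_units, collapse = ", "), "\n")
  print(x$table)
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Non-parametric comparison of a numeric response across groups (used for
#' baseline-RMS comparisons where normality is doubtful). Wraps
#' `stats::kruskal.test` (H statistic with tie correction, chi-squared
#' p value) into a tidy row.
#'
#' @param data data frame.
#' @param response numeric response column name.
#' @param group grouping column name.
#' @return one-row tibble: `statistic` (H), `df`, `p_value`, `significant`.
#' @export
kruskal_wallis <- function(data, response, group) {
  stopifnot(all(c(response, group) %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  x <- data[[response]]
  if (length(unique(x)) == 1)
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1, p_value = 1,
                          significant = FALSE))
  ht <- stats::kruskal.test(x, g)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 significant = ht$p.value < 0.05)
}
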