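#' Repeated-measures / split-plot ANOVA with Greenhouse-Geisser correction
#'
#' Fits the standard univariate repeated-measures ANOVA on a long
#' per-(subject, within-cell) table: within factors crossed within subject,
#' optional between-subject factors (subjects nested in between-group cells,
#' the split-plot layout used for "group x time" analyses of binned velocity
#' traces). Sphericity of each within effect is assessed with Mauchly's
#' test; when it is violated (p < `sphericity_alpha`) the Greenhouse-Geisser
#' epsilon rescales both numerator and denominator degrees of freedom and
#' the p-value is recomputed. A within factor with 2 levels is trivially
#' spherical (epsilon 1, no correction).
#'
#' The machinery is the multivariate-lm route of \pkg{car}
#' (`car::Anova`, Type III by default for unbalanced between factors); this
#' function arranges the data, runs it, and returns a tidy table in the
#' conventional reporting form `F[df1, df2]`.
#'
#' @param metrics Long data frame, one row per subject x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor column(s).
#' @param between Character vector of between-subject factor column(s)
#'   (optional).
#' @param subject Name of the subject identifier column.
#' @param sphericity_alpha Mauchly p-value below which the GG correction is
#'   applied (default 0.05).
#' @param ss_type Sum-of-squares type for between effects, 2 or 3
#'   (default 3).
#' @return A tibble of class `test_results`: one row per effect with
#'   `effect`, `statistic` ("F"), `value`, `df1`, `df2`, `p`, `correction`
#'   ("none" or "greenhouse_geisser"), `epsilon` (GG epsilon for within
#'   effects, NA otherwise).
#' @examples
#' d <- expand.grid(subject = factor(1:6), trial = factor(1:3))
#' d$y <- rnorm(nrow(d)) + as.numeric(d$trial)
#' rm_anova(d, "y", within = "trial")
#' @export
rm_anova <- function(metrics, dv, within, between = character(),
                     subject = "subject", sphericity_alpha = 0.05,
                     ss_type = 3) {
  metrics <- as.data.frame(metrics)
  needed <- c(dv, within, between, subject)
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols)) {
    stop(sprintf("metrics table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (f in c(within, between, subject)) metrics[[f]] <- factor(metrics[[f]])

  # balance check: every subject must have exactly one row per within-cell
  cell <- interaction(metrics[within], drop = FALSE, lex.order = TRUE)
  tab <- table(metrics[[subject]], cell)
  if (any(tab != 1L)) {
    stop(sprintf("missing cells: unbalanced within-factor structure for factor(s) %s",
                 paste(within, collapse = " x ")), call. = FALSE)
  }
  if (length(between)) {
    per_subj <- unique(metrics[c(subject, between)])
    grp_n <- table(interaction(per_subj[between], drop = FALSE))
    if (any(grp_n < 2L)) {
      stop("each between-group cell needs at least 2 subjects", call. = FALSE)
    }
  }

  # constant response: all effects have zero explained and zero residual SS;
  # report F = 0 by convention
  if (stats::var(metrics[[dv]]) < .Machine$double.eps) {
    effs <- c(between, within,
              if (length(between)) paste(rep(between, each = length(within)),
                                         within, sep = ":"))
    return(new_test_results(effect = effs, statistic = "F", value = 0,
                            df1 = NA_real_, df2 = NA_real_, p = 1,
                            correction = "none", epsilon = NA_real_))
  }

  # wide response matrix, one column per within-cell
  within_levels <- lapply(metrics[within], levels)
  idata <- rev(expand.grid(rev(within_levels), stringsAsFactors = TRUE))
  names(idata) <- within
  subj_ids <- levels(metrics[[subject]])
  key_all <- do.call(paste, c(metrics[within], sep = "\r"))
  key_cols <- do.call(paste, c(idata, sep = "\r"))
  y <- matrix(NA_real_, nrow = length(subj_ids), ncol = nrow(idata),
              dimnames = list(subj_ids, paste0("c", seq_len(nrow(idata)))))
  row_i <- match(metrics[[subject]], subj_ids)
  col_i <- match(key_all, key_cols)
  y[cbind(row_i, col_i)] <- metrics[[dv]]

  if (length(between)) {
    per_subj <- unique(metrics[c(subject, between)])
    per_subj <- per_subj[match(subj_ids, per_subj[[subject]]), , drop = FALSE]
    bdat <- per_subj[between]
    rhs <- paste(between, collapse = " * ")
    mod <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = bdat,
                     contrasts = stats::setNames(
                       rep(list(stats::contr.sum), length(between)), between))
  } else {
    mod <- stats::lm(y ~ 1)
  }
  idesign <- stats::as.formula(paste("~", paste(within, collapse = " * ")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = ss_type)
  # summary() warns when the Huynh-Feldt epsilon exceeds 1; HF is not used here
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  sph <- s$sphericity.tests
  pva <- s$pval.adjustments

  effects <- rownames(uni)
  effects <- effects[effects != "(Intercept)"]
  rows <- lapply(effects, function(e) {
    f_val <- uni[e, "F value"]
    df1 <- uni[e, "num Df"]
    df2 <- uni[e, "den Df"]
    p <- uni[e, "Pr(>F)"]
    eps <- NA_real_
    corr <- "none"
    involves_within <- any(vapply(within, function(w) grepl(w, e, fixed = TRUE),
                                  logical(1)))
    if (involves_within && df1 >= 2 && !is.null(sph) && e %in% rownames(sph)) {
      mauchly_p <- sph[e, "p-value"]
      eps <- pva[e, "GG eps"]
      if (is.finite(mauchly_p) && mauchly_p < sphericity_alpha) {
        corr <- "greenhouse_geisser"
        df1 <- df1 * eps
        df2 <- df2 * eps
        p <- stats::pf(f_val, df1, df2, lower.tail = FALSE)
      }
    } else if (involves_within) {
      eps <- 1
    }
    tibble::tibble(effect = e, statistic = "F", value = unname(f_val),
                   df1 = unname(df1), df2 = unname(df2), p = unname(p),
                   correction = corr, epsilon = unname(eps))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("test_results", class(out))
  out
}

new_test_results <- function(...) {
  out <- tibble::tibble(...)
  class(out) <- c("test_results", class(out))
  out
}

#' @export
print.test_results <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    lab <- if (!is.null(x$effect) && !is.na(x$effect[i])) paste0(x$effect[i], ": ") else ""
    dfs <- if (!is.na(x$df2[i])) sprintf("[%s, %s]", fmt_df(x$df1[i]), fmt_df(x$df2[i]))
           else sprintf("[%s]", fmt_df(x$df1[i]))
    corr <- if (x$correction[i] != "none") paste0(", ", x$correction[i]) else ""
    cat(sprintf("%s%s%s=%.4g, p=%.4g%s\n", lab, x$statistic[i], dfs,
                x$value[i], x$p[i], corr))
  }
  invisible(x)
}

fmt_df <- function(d) {
  if (is.na(d)) "NA" else if (abs(d - round(d)) < 1e-8) sprintf("%d", round(d))
  else sprintf("%.2f", d)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's W statistic with Welch-Satterthwaite fractional denominator
#' degrees of freedom, for comparing group means when variances are unequal
#' (e.g. dart magnitudes across stimulus types). With two groups, W equals
#' the square of Welch's t.
#'
#' @param values A named list of numeric vectors (one per group), or a
#'   numeric vector with `groups` giving labels.
#' @param groups Optional grouping vector when `values` is a single vector.
#' @return A one-row `test_results` tibble with statistic "W".
#' @export
welch_anova <- function(values, groups = NULL) {
  if (!is.null(groups)) values <- split(as.numeric(values), groups)
  if (!is.list(values) || length(values) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  ns <- lengths(values)
  if (any(ns < 2L)) stop("each group needs at least 2 values", call. = FALSE)
  vars <- vapply(values, stats::var, 1)
  if (any(vars <= 0)) {
    stop("zero within-group variance: Welch's ANOVA undefined", call. = FALSE)
  }
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(seq_along(values), ns))
  res <- stats::oneway.test(x ~ g, var.equal = FALSE)
  new_test_results(
    effect = "group", statistic = "W",
    value = unname(res$statistic),
    df1 = unname(res$parameter[1]), df2 = unname(res$parameter[2]),
    p = unname(res$p.value), correction = "none", epsilon = NA_real_)
}

#' Paired-sample t-test
#'
#' Two-sided t on the within-subject differences, `df = n - 1` (e.g. first
#' vs second dart magnitude within a CS presentation).
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A one-row `test_results` tibble with statistic "t".
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must be paired vectors of equal length >= 2", call. = FALSE)
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired t undefined", call. = FALSE)
  }
  res <- stats::t.test(x, y, paired = TRUE)
  new_test_results(
    effect = "pair", statistic = "t", value = unname(res$statistic),
    df1 = unname(res$parameter), df2 = NA_real_, p = unname(res$p.value),
    correction = "none", epsilon = NA_real_)
}

#' Pairwise post hoc comparisons
#'
#' All pairwise group comparisons following a significant omnibus effect.
#' `"bonferroni"` runs Welch two-sample t-tests with p multiplied by the
#' number of comparisons (capped at 1); `"tukey"` uses the studentized-range
#' reference via `TukeyHSD` on a one-way fit.
#'
#' @param values A named list of numeric vectors (one per group), or a
#'   numeric vector with `groups`.
#' @param method `"bonferroni"` or `"tukey"`.
#' @param groups Optional grouping vector when `values` is a single vector.
#' @return A `test_results` tibble, one row per pair, with `p` the adjusted
#'   p-value (`p_unadjusted` kept alongside for bonferroni).
#' @export
posthoc_pairwise <- function(values, method = c("bonferroni", "tukey"),
                             groups = NULL) {
  method <- match.arg(method)
  if (!is.null(groups)) values <- split(as.numeric(values), groups)
  if (!is.list(values) || length(values) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    names(values) <- paste0("g", seq_along(values))
  }
  k <- length(values)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)

  if (method == "bonferroni") {
    rows <- lapply(seq_len(m), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      res <- stats::t.test(values[[a]], values[[b]])
      tibble::tibble(
        effect = paste(names(values)[a], names(values)[b], sep = " vs "),
        statistic = "t", value = unname(res$statistic),
        df1 = unname(res$parameter), df2 = NA_real_,
        p_unadjusted = unname(res$p.value),
        p = min(1, m * unname(res$p.value)),
        correction = "bonferroni", epsilon = NA_real_)
    })
    out <- do.call(rbind, rows)
  } else {
    x <- unlist(values, use.names = FALSE)
    g <- factor(rep(names(values), lengths(values)), levels = names(values))
    tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
    out <- tibble::tibble(
      effect = gsub("-", " vs ", rownames(tk), fixed = TRUE),
      statistic = "t", value = NA_real_,
      df1 = NA_real_, df2 = NA_real_,
      p_unadjusted = NA_real_,
      p = unname(tk[, "p adj"]),
      correction = "tukey", epsilon = NA_real_)
  }
  class(out) <- c("test_results", class(out))
  out
}
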