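check_group_data <- function(data, group = "group", value = "value") {
  stopifnot(is.data.frame(data))
  if (!all(c(group, value) %in% names(data)))
    stop_invalid("data needs columns '", group, "' and '", value, "'")
  g <- factor(data[[group]])
  y <- data[[value]]
  if (any(!is.finite(y))) stop_invalid("values must be finite")
  if (nlevels(g) < 2L) stop_invalid("need at least 2 groups")
  n <- table(g)
  if (any(n < 2L)) stop_invalid("every group needs n >= 2")
  list(g = g, y = y, n = n)
}

#' One-way analysis of variance across current groups
#'
#' Standard between/within decomposition via [stats::aov()] on long-format
#' data (one row per corneal sample). When every group is a constant with
#' equal means (zero variance everywhere), F is reported as 0 and p as 1.
#'
#' @param data A data.frame in long format.
#' @param group,value Column names of the group label and the measured
#'   value (e.g. albumin concentration in mg/ml).
#' @return An object of class `anova_groups`: list with `F`, `df`, `p`,
#'   the ANOVA `table` and the underlying `aov` fit.
#' @examples
#' d <- data.frame(group = rep(c("a", "b"), each = 3),
#'                 value = c(1, 2, 3, 4, 5, 6))
#' one_way_anova(d)  # F = 13.5
#' @export
one_way_anova <- function(data, group = "group", value = "value") {
  gd <- check_group_data(data, group, value)
  df <- data.frame(y = gd$y, g = gd$g)
  fit <- stats::aov(y ~ g, data = df)
  tab <- summary(fit)[[1L]]
  Fv <- tab[["F value"]][1L]
  pv <- tab[["Pr(>F)"]][1L]
  ssb <- sum(tapply(gd$y, gd$g, function(v) length(v) *
                      (mean(v) - mean(gd$y))^2))
  ssw <- sum(tapply(gd$y, gd$g, function(v) sum((v - mean(v))^2)))
  if (ssw <= 1e-12 * (ssb + 1e-12)) {
    # zero within-group variance: constant groups
    if (ssb <= 1e-12) { Fv <- 0; pv <- 1 } else { Fv <- Inf; pv <- 0 }
  }
  structure(list(F = Fv, df = unname(tab[["Df"]]), p = pv, table = tab,
                 fit = fit, groups = levels(gd$g), n = as.vector(gd$n)),
            class = "anova_groups")
}

#' @export
print.anova_groups <- function(x, ...) {
  cat("One-way ANOVA: ", length(x$groups), " groups, n = ",
      paste(unique(x$n), collapse = "/"), " per group\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df[1L], x$df[2L],
              x$F, x$p))
  invisible(x)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range comparisons of all group pairs with pooled
#' within-group variance. The q statistic for pair (i, j) is
#' `|diff| / sqrt(MSE/2 * (1/n_i + 1/n_j))` and adjusted p-values come
#' from the studentized range distribution ([stats::ptukey()]); unequal
#' group sizes are handled by the Tukey-Kramer form of the standard
#' error.
#'
#' @param data,group,value As in [one_way_anova()].
#' @param alpha Familywise significance level for the `significant` flag.
#' @return An object of class `tukey_groups`: data.frame with one row per
#'   pair (`diff`, `se`, `q`, `p_adj`, `significant`).
#' @export
tukey_hsd <- function(data, group = "group", value = "value",
                      alpha = 0.05) {
  gd <- check_group_data(data, group, value)
  k <- nlevels(gd$g)
  means <- tapply(gd$y, gd$g, mean)
  n <- as.vector(gd$n)
  N <- length(gd$y)
  df_err <- N - k
  mse <- sum(tapply(gd$y, gd$g, function(v) sum((v - mean(v))^2))) / df_err
  pairs <- utils::combn(k, 2L)
  out <- data.frame(
    pair = apply(pairs, 2L, function(ij)
      paste(levels(gd$g)[ij[2L]], "-", levels(gd$g)[ij[1L]])),
    diff = apply(pairs, 2L, function(ij)
      unname(means[ij[2L]] - means[ij[1L]])),
    se = apply(pairs, 2L, function(ij)
      sqrt(mse / 2 * (1 / n[ij[1L]] + 1 / n[ij[2L]])))
  )
  out$q <- abs(out$diff) / out$se
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = df_err,
                             lower.tail = FALSE)
  out$significant <- out$p_adj < alpha
  structure(out, class = c("tukey_groups", "data.frame"),
            alpha = alpha, df_error = df_err, mse = mse, nmeans = k)
}

#' @export
print.tukey_groups <- function(x, ...) {
  cat("Tukey HSD pairwise comparisons (", attr(x, "nmeans"),
      " groups, error df = ", attr(x, "df_error"), ", alpha = ",
      attr(x, "alpha"), ")\n", sep = "")
  y <- x
  y$diff <- signif(y$diff, 4)
  y$se <- signif(y$se, 4)
  y$q <- signif(y$q, 4)
  y$p_adj <- signif(y$p_adj, 4)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
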