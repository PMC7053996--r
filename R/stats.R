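#' Bonferroni adjustment
#'
#' Multiplies raw p-values by the number of comparisons and caps at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values, `min(1, p * m)`.
#' @export
#' @examples
#' bonferroni_adjust(0.01, m = 5)  # 0.05
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1L) abort("m must be >= 1")
  pmin(1, p * m)
}

# Shapiro-Wilk p per group; groups with < 3 values or zero variance pass NA
shapiro_p <- function(groups) {
  vapply(groups, function(g) {
    g <- g[!is.na(g)]
    if (length(g) < 3L || sd(g) == 0) return(NA_real_)
    shapiro.test(g)$p.value
  }, numeric(1))
}

# Dunn's post hoc for the Friedman test: rank within each block (unit),
# compare mean ranks of treatments j vs reference with
# z = (Rbar_j - Rbar_ref) / sqrt(k (k + 1) / (6 n)).
dunn_friedman <- function(mat, ref_cols, test_cols) {
  n <- nrow(mat)
  k <- ncol(mat)
  ranks <- t(apply(mat, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  ref <- mean(rbar[ref_cols])
  purrr::map_dfr(test_cols, function(j) {
    z <- (rbar[j] - ref) / se
    tibble(comparison = colnames(mat)[j],
           statistic = z,
           p_raw = 2 * pnorm(-abs(z)))
  })
}

new_stat_result <- function(test, statistic, p_value, n, direction = NA_character_,
                            normality_p = NA_real_, routed = NA_character_,
                            post_hoc = NULL, alpha = 0.05) {
  structure(
    list(test = test, statistic = unname(statistic), p_value = p_value,
         n = n, direction = direction, normality_p = normality_p,
         routed = routed, post_hoc = post_hoc, alpha = alpha),
    class = "spinedyn_stat"
  )
}

#' @export
print.spinedyn_stat <- function(x, ...) {
  cat("<spinedyn_stat>", x$test, "(", x$routed, "branch )\n")
  cat("  statistic:", signif(x$statistic, 4), " p:", signif(x$p_value, 4),
      " n:", paste(x$n, collapse = "/"), "\n")
  if (!is.null(x$post_hoc) && nrow(x$post_hoc)) {
    cat("  post hoc (Bonferroni-adjusted):\n")
    print(as.data.frame(x$post_hoc), row.names = FALSE)
  }
  invisible(x)
}

#' @export
tidy.spinedyn_stat <- function(x, ...) {
  tibble(
    test = x$test, routed = x$routed,
    statistic = x$statistic, p_value = x$p_value,
    n = paste(x$n, collapse = "/"), direction = x$direction
  )
}

#' @export
glance.spinedyn_stat <- function(x, ...) {
  tibble(
    test = x$test, p_value = x$p_value, alpha = x$alpha,
    significant = x$p_value < x$alpha,
    n_post_hoc = if (is.null(x$post_hoc)) 0L else nrow(x$post_hoc)
  )
}

#' Normality-routed statistical comparisons
#'
#' The package's statistical dispatch: every group is first checked for
#' normality (Shapiro-Wilk at `alpha`); if all groups pass, the parametric
#' branch runs (Student's t-test, one-sample t-test, or repeated-measures
#' one-way ANOVA with a Bonferroni post hoc of each post-baseline session
#' against the pooled baseline); otherwise the non-parametric branch runs
#' (Mann-Whitney, Wilcoxon signed-rank, or Friedman with Dunn's post hoc).
#' The routing decision is reported alongside the result.
#'
#' Designs:
#' \describe{
#'   \item{`two_group`}{`x` vs `y`, unpaired.}
#'   \item{`one_sample_vs_1`}{`x` against `mu` (default 1, for ratios).}
#'   \item{`repeated_oneway`}{`data`: one row per unit x session (columns
#'     `unit`, `session`, `value`); sessions in `baseline` form the pooled
#'     reference for the post hoc.}
#'   \item{`repeated_twoway`}{`data`: one row per unit x session with an
#'     additional `group` column (e.g. dendritic compartment); two-way
#'     repeated-measures ANOVA on `group * session`, with a rank-transformed
#'     ANOVA as the non-normal fallback. The reported statistic and p-value
#'     are for the interaction term.}
#'   \item{`paired_nonparam`}{paired `x`, `y` via Wilcoxon signed-rank
#'     (always non-parametric).}
#' }
#'
#' @param design One of the designs above.
#' @param x,y Numeric vectors for the two-group / one-sample / paired
#'   designs.
#' @param data Long tibble for `repeated_oneway`.
#' @param baseline Character vector of baseline session labels
#'   (`repeated_oneway`).
#' @param mu Null value for `one_sample_vs_1` (default 1).
#' @param alpha Significance level for routing and reporting (default 0.05).
#' @return A `spinedyn_stat` object (see [tidy.spinedyn_stat()]).
#' @export
route_test <- function(design = c("two_group", "one_sample_vs_1",
                                  "repeated_oneway", "repeated_twoway",
                                  "paired_nonparam"),
                       x = NULL, y = NULL, data = NULL, baseline = NULL,
                       mu = 1, alpha = 0.05) {
  design <- match.arg(design)
  switch(design,
    two_group = {
      if (is.null(x) || is.null(y)) abort("two_group needs x and y")
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      np <- shapiro_p(list(x, y))
      normal <- all(is.na(np) | np > alpha)
      if (sd(c(x, y)) == 0) {
        # identical constant groups: no evidence of any difference
        return(new_stat_result("Student's t-test", 0, 1,
                               c(length(x), length(y)), direction = "x <= y",
                               normality_p = np, routed = "parametric",
                               alpha = alpha))
      }
      if (normal) {
        tt <- t.test(x, y, var.equal = TRUE)
        new_stat_result("Student's t-test", tt$statistic, tt$p.value,
                        c(length(x), length(y)),
                        direction = if (mean(x) > mean(y)) "x > y" else "x <= y",
                        normality_p = np, routed = "parametric", alpha = alpha)
      } else {
        wt <- suppressWarnings(wilcox.test(x, y))
        new_stat_result("Mann-Whitney U", wt$statistic, wt$p.value,
                        c(length(x), length(y)),
                        direction = if (median(x) > median(y)) "x > y" else "x <= y",
                        normality_p = np, routed = "nonparametric", alpha = alpha)
      }
    },
    one_sample_vs_1 = {
      if (is.null(x)) abort("one_sample_vs_1 needs x")
      x <- x[!is.na(x)]
      np <- shapiro_p(list(x))
      normal <- all(is.na(np) | np > alpha)
      if (sd(x) == 0 && x[1] == mu) {
        return(new_stat_result("one-sample t-test", 0, 1, length(x),
                               direction = "below", normality_p = np,
                               routed = "parametric", alpha = alpha))
      }
      if (normal) {
        tt <- t.test(x, mu = mu)
        new_stat_result("one-sample t-test", tt$statistic, tt$p.value,
                        length(x),
                        direction = if (mean(x) > mu) "above" else "below",
                        normality_p = np, routed = "parametric", alpha = alpha)
      } else {
        wt <- suppressWarnings(wilcox.test(x, mu = mu))
        new_stat_result("Wilcoxon signed-rank", wt$statistic, wt$p.value,
                        length(x),
                        direction = if (median(x) > mu) "above" else "below",
                        normality_p = np, routed = "nonparametric", alpha = alpha)
      }
    },
    repeated_oneway = {
      if (is.null(data)) abort("repeated_oneway needs data (unit, session, value)")
      stopifnot(all(c("unit", "session", "value") %in% names(data)))
      wide <- data %>%
        select("unit", "session", "value") %>%
        tidyr::pivot_wider(names_from = "session", values_from = "value") %>%
        filter(complete.cases(.))
      mat <- as.matrix(wide[, -1, drop = FALSE])
      rownames(mat) <- wide$unit
      if (nrow(mat) < 2L || ncol(mat) < 2L) {
        abort("repeated_oneway needs >= 2 complete units and >= 2 sessions")
      }
      if (is.null(baseline)) baseline <- colnames(mat)[1]
      ref_cols <- which(colnames(mat) %in% baseline)
      test_cols <- which(!colnames(mat) %in% baseline)
      np <- shapiro_p(asplit(mat, 2))
      normal <- all(is.na(np) | np > alpha)
      long <- data.frame(
        unit = factor(rep(rownames(mat), ncol(mat))),
        session = factor(rep(colnames(mat), each = nrow(mat)),
                         levels = colnames(mat)),
        value = as.vector(mat)
      )
      if (normal) {
        fit <- aov(value ~ session + Error(unit), data = long)
        s <- summary(fit)[["Error: Within"]][[1]]
        fstat <- s["session", "F value"]
        pval <- s["session", "Pr(>F)"]
        ph <- if (length(test_cols)) {
          ref_vals <- rowMeans(mat[, ref_cols, drop = FALSE])
          raw <- purrr::map_dfr(test_cols, function(j) {
            tt <- t.test(mat[, j], ref_vals, paired = TRUE)
            tibble(comparison = paste0(colnames(mat)[j], " vs baseline"),
                   statistic = unname(tt$statistic), p_raw = tt$p.value)
          })
          raw$p_adjusted <- bonferroni_adjust(raw$p_raw, m = nrow(raw))
          raw
        } else {
          NULL
        }
        new_stat_result("repeated-measures one-way ANOVA", fstat, pval,
                        nrow(mat), normality_p = np, routed = "parametric",
                        post_hoc = ph, alpha = alpha)
      } else {
        fr <- friedman.test(mat)
        ph <- if (length(test_cols)) {
          raw <- dunn_friedman(mat, ref_cols, test_cols)
          raw$comparison <- paste0(raw$comparison, " vs baseline")
          raw$p_adjusted <- bonferroni_adjust(raw$p_raw, m = nrow(raw))
          raw
        } else {
          NULL
        }
        new_stat_result("Friedman test", fr$statistic, fr$p.value,
                        nrow(mat), normality_p = np, routed = "nonparametric",
                        post_hoc = ph, alpha = alpha)
      }
    },
    repeated_twoway = {
      if (is.null(data)) {
        abort("repeated_twoway needs data (unit, group, session, value)")
      }
      stopifnot(all(c("unit", "group", "session", "value") %in% names(data)))
      df <- data %>%
        filter(!is.na(.data$value)) %>%
        mutate(
          unit = factor(.data$unit), group = factor(.data$group),
          session = factor(.data$session, levels = unique(.data$session))
        )
      np <- shapiro_p(split(df$value, interaction(df$group, df$session)))
      normal <- all(is.na(np) | np > alpha)
      if (!normal) df$value <- rank(df$value)
      fit <- aov(value ~ group * session + Error(unit), data = df)
      s <- summary(fit)[["Error: Within"]][[1]]
      row <- grep("group:session", rownames(s))
      new_stat_result(
        if (normal) "repeated-measures two-way ANOVA"
        else "rank-transformed two-way ANOVA",
        s[row, "F value"], s[row, "Pr(>F)"],
        length(unique(df$unit)), normality_p = np,
        routed = if (normal) "parametric" else "nonparametric", alpha = alpha
      )
    },
    paired_nonparam = {
      if (is.null(x) || is.null(y)) abort("paired_nonparam needs x and y")
      ok <- !is.na(x) & !is.na(y)
      wt <- suppressWarnings(wilcox.test(x[ok], y[ok], paired = TRUE))
      new_stat_result("Wilcoxon signed-rank (paired)", wt$statistic, wt$p.value,
                      sum(ok),
                      direction = if (median(x[ok]) > median(y[ok])) "x > y" else "x <= y",
                      routed = "nonparametric", alpha = alpha)
    }
  )
}
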