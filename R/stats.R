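#' Compare BP estimates across tissue groups
#'
#' One-way ANOVA with a Levene-gated post-hoc branch, mirroring a standard
#' SPSS workflow: homogeneity of variances is assessed by Levene's test
#' (centered on the mean); if variances are non-homogeneous
#' (\code{levene_P < alpha}) pairwise comparisons use Tamhane's T2
#' (Welch t tests with Sidak-type correction), otherwise Bonferroni
#' (pairwise t on the pooled ANOVA error term, P multiplied by the number
#' of pairs and capped at 1). Shapiro-Wilk normality is reported per
#' group.
#'
#' @param groups named list of numeric vectors (one per tissue group),
#'   each with at least 2 values (>= 3 for the normality test).
#' @param alpha significance level gating the post-hoc branch
#'   (default 0.05).
#' @return An object of class \code{"group_comparison"}: list with
#'   \code{anova_F}, \code{anova_P}, \code{df}, \code{levene_P},
#'   \code{shapiro_P} (named per group, NA when n < 3), \code{posthoc}
#'   (data frame: group1, group2, p_raw, p, method) and
#'   \code{posthoc_method}.
#' @examples
#' compare_groups(list(healthy = c(0.1, -0.1, 0.2, 0),
#'                     U251 = c(0.9, 1.2, 1.1, 0.8),
#'                     A431 = c(2.8, 3.3, 3.0, 2.6)))
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) {
    stop("degenerate input: every group needs at least 2 values",
         call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), n), levels = names(groups))

  fit <- stats::lm(values ~ fac)
  an <- stats::anova(fit)
  anova_F <- an[1L, "F value"]
  anova_P <- an[1L, "Pr(>F)"]
  df <- c(between = an[1L, "Df"], within = an[2L, "Df"])
  mse <- an[2L, "Mean Sq"]
  if (!is.finite(anova_F)) {        # all residuals zero, no spread at all
    anova_F <- 0
    anova_P <- 1
  }

  lev <- car::leveneTest(values ~ fac, center = mean)
  levene_P <- lev[1L, "Pr(>F)"]
  shapiro_P <- vapply(groups, function(g) {
    if (length(g) >= 3 && stats::var(g) > 0) stats::shapiro.test(g)$p.value
    else NA_real_
  }, numeric(1))

  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  use_tamhane <- is.finite(levene_P) && levene_P < alpha
  posthoc <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                        p_raw = NA_real_, p = NA_real_,
                        method = if (use_tamhane) "Tamhane" else "Bonferroni")
  for (j in seq_len(m)) {
    g1 <- groups[[pairs[1L, j]]]
    g2 <- groups[[pairs[2L, j]]]
    if (use_tamhane) {
      # Tamhane T2: Welch t with Sidak-type multiplicity correction
      p_raw <- stats::t.test(g1, g2, var.equal = FALSE)$p.value
      p_adj <- 1 - (1 - p_raw)^m
    } else {
      # pooled ANOVA error term, df = N - k (SPSS-style Bonferroni)
      se <- sqrt(mse * (1 / length(g1) + 1 / length(g2)))
      if (se == 0) {
        p_raw <- if (mean(g1) == mean(g2)) 1 else 0
      } else {
        tstat <- (mean(g1) - mean(g2)) / se
        p_raw <- 2 * stats::pt(-abs(tstat), df[["within"]])
      }
      p_adj <- min(1, m * p_raw)
    }
    posthoc$p_raw[j] <- p_raw
    posthoc$p[j] <- min(1, p_adj)
  }
  structure(list(anova_F = anova_F, anova_P = anova_P, df = df,
                 levene_P = levene_P, shapiro_P = shapiro_P,
                 posthoc = posthoc,
                 posthoc_method = if (use_tamhane) "Tamhane" else "Bonferroni",
                 alpha = alpha, n = n),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, P = %.3g\n",
              x$df[["between"]], x$df[["within"]], x$anova_F, x$anova_P))
  cat(sprintf("Levene (center = mean): P = %.3g -> %s post-hoc\n",
              x$levene_P, x$posthoc_method))
  cat("Shapiro-Wilk per group: ",
      paste(sprintf("%s %.3g", names(x$shapiro_P), x$shapiro_P),
            collapse = ", "), "\n", sep = "")
  print(x$posthoc, digits = 3)
  invisible(x)
}

#' Serialize a group comparison to JSON
#'
#' @param x a \code{"group_comparison"}.
#' @param path optional file to write to.
#' @return The JSON string, invisibly when written to file.
#' @export
group_comparison_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "group_comparison"))
  out <- jsonlite::toJSON(list(schema_version = 1L, anova_F = x$anova_F,
                               anova_P = x$anova_P, df = as.list(x$df),
                               levene_P = x$levene_P,
                               shapiro_P = as.list(x$shapiro_P),
                               posthoc_method = x$posthoc_method,
                               posthoc = x$posthoc, n = as.list(x$n)),
                          auto_unbox = TRUE, digits = NA, na = "null",
                          pretty = TRUE)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
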