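#' Two-sample Student t-test
#'
#' Pooled-variance (Student) two-sample t-test, the default comparison for
#' single-cell displacement metrics between control and stimulated cohorts;
#' the Welch unequal-variance form is available behind a flag.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param two_tailed Two-tailed p-value (default TRUE).
#' @param welch Use the Welch unequal-variance test instead of the pooled
#'   Student form (default FALSE).
#' @param labels Length-2 character vector naming the groups.
#' @return A one-row tibble: `contrast`, `estimate` (mean difference a - b),
#'   `statistic`, `df`, `p_value`, `stars`.
#' @export
two_sample_ttest <- function(a, b, two_tailed = TRUE, welch = FALSE,
                             labels = c("a", "b")) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs n >= 2", class = "spherotax_insufficient_data")
  }
  fit <- stats::t.test(a, b, var.equal = !welch,
                       alternative = "two.sided")
  p <- fit$p.value
  if (!two_tailed) p <- p / 2
  tibble(
    contrast = paste(labels, collapse = " vs "),
    estimate = mean(a) - mean(b),
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = p,
    stars = signif_stars(p)
  )
}

check_pvals <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]", class = "spherotax_domain_error")
  }
  invisible(p)
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak multiple-comparison adjustment: with the m p-values
#' sorted ascending, the k-th smallest is adjusted to
#' 1 - (1 - p_(k))^(m - k + 1), then adjusted values are made monotone
#' non-decreasing in rank. Returned in input order.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
holm_sidak_adjust <- function(pvals) {
  check_pvals(pvals)
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  ord <- order(pvals)
  adj <- 1 - (1 - pvals[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment: the k-th smallest of m p-values becomes
#' min over j >= k of p_(j) * m / j, capped at 1, returned in input order.
#'
#' @inheritParams holm_sidak_adjust
#' @return Adjusted p-values (q-values), same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  check_pvals(pvals)
  p.adjust(pvals, method = "BH")
}

#' Two-factor ANOVA over frontier shifts with Holm-Sidak post-hoc
#'
#' Fits a fixed-effects two-factor linear model (frontier x condition) to
#' per-aggregate frontier shifts and tests the main effects and interaction
#' with Type II sums of squares (appropriate for the unbalanced group sizes
#' typical of these assays). Pairwise condition contrasts within each
#' frontier are then tested on the model's estimated marginal means and
#' adjusted as a single Holm-Sidak family.
#'
#' @param data Tidy data frame with one row per aggregate x frontier:
#'   a numeric response plus two factors.
#' @param value,frontier,condition Names of the response, frontier-level and
#'   condition columns (defaults `"value"`, `"frontier"`, `"condition"`).
#' @param contrasts Compute the pairwise post-hoc contrasts (default TRUE;
#'   turn off when only the omnibus ANOVA is needed, e.g. in simulations).
#' @return An object of class `frontier_comparison` with elements `anova`
#'   (tibble of effects: term, df, sum_sq, statistic, p_value) and
#'   `contrasts` (tibble: frontier, contrast, estimate, statistic, p_value,
#'   adj_p_value, stars, adjustment). [tidy()] returns the contrasts,
#'   [glance()] the ANOVA table.
#' @export
frontier_comparison <- function(data, value = "value", frontier = "frontier",
                                condition = "condition", contrasts = TRUE) {
  req <- c(value, frontier, condition)
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort(paste0("`data` must contain columns: ", paste(req, collapse = ", ")),
          class = "spherotax_invalid_input")
  }
  df <- tibble(
    value = data[[value]],
    frontier = factor(data[[frontier]]),
    condition = factor(data[[condition]])
  )
  cell_n <- df %>% dplyr::count(.data$frontier, .data$condition)
  if (nrow(cell_n) < nlevels(df$frontier) * nlevels(df$condition) ||
      any(cell_n$n < 2)) {
    abort("every frontier x condition cell needs n >= 2",
          class = "spherotax_insufficient_data")
  }
  fit <- lm(value ~ frontier * condition, data = df)
  an <- car::Anova(fit, type = 2)
  anova_tbl <- tibble(
    term = rownames(an),
    df = an$Df,
    sum_sq = an$`Sum Sq`,
    statistic = an$`F value`,
    p_value = an$`Pr(>F)`
  ) %>% filter(.data$term != "Residuals")

  contr_tbl <- NULL
  if (contrasts) {
    emm <- emmeans::emmeans(fit, ~ condition | frontier)
    pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "none"))
    adj <- holm_sidak_adjust(pr$p.value)
    contr_tbl <- tibble(
      frontier = as.character(pr$frontier),
      contrast = as.character(pr$contrast),
      estimate = pr$estimate,
      statistic = pr$t.ratio,
      p_value = pr$p.value,
      adj_p_value = adj,
      stars = signif_stars(adj),
      adjustment = "holm-sidak (one family across all frontiers)"
    )
  }
  structure(
    list(anova = anova_tbl, contrasts = contr_tbl, model = fit),
    class = "frontier_comparison"
  )
}

#' @export
print.frontier_comparison <- function(x, ...) {
  cat("Two-factor ANOVA (Type II):\n")
  print(x$anova)
  if (!is.null(x$contrasts)) {
    cat("\nPairwise condition contrasts within frontier (Holm-Sidak):\n")
    print(x$contrasts)
  }
  invisible(x)
}

#' @rdname frontier_comparison
#' @param x A `frontier_comparison` object.
#' @param ... Unused.
#' @method tidy frontier_comparison
#' @export
tidy.frontier_comparison <- function(x, ...) {
  if (is.null(x$contrasts)) x$anova else x$contrasts
}

#' @rdname frontier_comparison
#' @method glance frontier_comparison
#' @export
glance.frontier_comparison <- function(x, ...) x$anova
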