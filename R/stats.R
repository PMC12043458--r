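# Inferential machinery implemented from closed forms: one-way ANOVA sums
# of squares, Fisher's LSD pairwise decisions with an insert-and-absorb
# compact letter display, descriptive statistics, and Pearson correlation.
# p-values always come from distribution functions (pf, pt), never tables.
# Base R aov()/cor.test() are used only as independent oracles in the test
# suite.

#' Descriptive statistics of a numeric sample
#'
#' Mean, sample standard deviation (n-1 denominator), median, range and
#' coefficient of variation `100 * sd / mean`.
#'
#' @param x Numeric vector with at least 2 values.
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `min`, `max`,
#'   `cv_percent`.
#' @export
#' @examples
#' describe(c(1, 2, 3))
describe <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2 || anyNA(x)) {
    stop("describe() needs at least 2 non-missing values", call. = FALSE)
  }
  tibble::tibble(
    n = length(x), mean = mean(x), sd = stats::sd(x),
    median = stats::median(x), min = min(x), max = max(x),
    cv_percent = 100 * stats::sd(x) / mean(x)
  )
}

#' Descriptive summary of a trial (per-variable)
#'
#' Plot-level descriptives for yield and each grain analyte, plus the range
#' of site means ("regional variation").
#'
#' @param plots A plot table.
#' @param variables Columns to summarize.
#' @return A tibble with one row per variable.
#' @export
trial_descriptives <- function(plots,
                               variables = c("yield", "grain_fe", "grain_mn",
                                             "grain_cu", "grain_zn",
                                             "phytic_acid")) {
  plots <- validate_plot_table(plots)
  purrr::map_dfr(variables, function(v) {
    d <- describe(plots[[v]])
    site_means <- tapply(plots[[v]], plots$site, mean)
    dplyr::bind_cols(
      tibble::tibble(variable = v), d,
      tibble::tibble(site_min = min(site_means), site_max = max(site_means))
    )
  })
}

.pull_groups <- function(data, value, group) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  g <- data[[group]]
  if (!is.factor(g)) g <- factor(g, levels = unique(g))
  split(as.numeric(data[[value]]), droplevels(g))
}

# Core sums-of-squares decomposition on a list of numeric vectors.
.anova_closed_form <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  n_tot <- length(y)
  k <- length(groups)
  grand <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- n_tot - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ss_between <= .Machine$double.eps * ss_within ||
      (ss_between == 0 && ss_within == 0)) {
    f <- 0; p <- 1
  } else if (ms_w == 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_b / ms_w
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(
    f_statistic = f, df_between = df_b, df_within = df_w, p_value = p,
    ss_between = ss_between, ss_within = ss_within,
    ss_total = sum((y - grand)^2),
    ms_between = ms_b, ms_within = ms_w,
    group_stats = tibble::tibble(
      group = names(groups), n = as.integer(n_i), mean = means,
      sd = vapply(groups, stats::sd, numeric(1))
    )
  )
}

#' One-way analysis of variance (closed form)
#'
#' Textbook between/within sums-of-squares decomposition with
#' `F = MS_between / MS_within` and an upper-tail p-value from the F
#' distribution. Groups with no between-group variation return `F = 0`,
#' `p = 1`; zero within-group variance with unequal means returns
#' `F = Inf`, `p = 0`.
#'
#' @param data A data frame.
#' @param value Unquoted column holding the response.
#' @param group Unquoted column holding group labels.
#' @return An object of class `ofs_anova`; see [tidy.ofs_anova()] and
#'   [glance.ofs_anova()].
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                 g = rep(c("a", "b", "c"), each = 3))
#' glance(one_way_anova(d, y, g))
one_way_anova <- function(data, value, group) {
  groups <- .pull_groups(data, {{ value }}, {{ group }})
  res <- .anova_closed_form(groups)
  structure(res, class = "ofs_anova")
}

#' @export
print.ofs_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4f\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Tidy a one-way ANOVA
#'
#' @param x An `ofs_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per stratum (between, within), in the
#'   usual ANOVA-table layout.
#' @export
tidy.ofs_anova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ms_between, x$ms_within),
    statistic = c(x$f_statistic, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' Glance at a one-way ANOVA
#'
#' @param x An `ofs_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df_between`, `df_within`,
#'   `p.value`, `ms_within`.
#' @export
glance.ofs_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$f_statistic, df_between = x$df_between,
    df_within = x$df_within, p.value = x$p_value, ms_within = x$ms_within
  )
}

# Drop any letter column whose member set is contained in another's
# (duplicates keep their first occurrence).
.absorb_columns <- function(cols) {
  keep <- rep(TRUE, length(cols))
  for (a in seq_along(cols)) {
    for (b in seq_along(cols)) {
      if (a == b || !keep[a]) next
      if (all(!cols[[a]] | cols[[b]])) {           # a subset of b
        if (!identical(cols[[a]], cols[[b]]) || a > b) keep[a] <- FALSE
      }
    }
  }
  cols[keep]
}

# Insert-and-absorb compact letter display. `diff_mat` is a logical matrix
# (ordered by descending mean) where TRUE marks a significant pair. Returns
# one letter string per group such that two groups share a letter iff they
# are NOT significantly different.
.compact_letters <- function(diff_mat) {
  k <- nrow(diff_mat)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!diff_mat[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          new_cols <- c(new_cols, list(a, b))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      cols <- .absorb_columns(new_cols)
    }
  }
  # order columns by their top-most (highest-mean) member, assign a, b, c...
  first <- vapply(cols, function(c) which(c)[1], integer(1))
  cols <- cols[order(first)]
  lab <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- character(k)
  for (g in seq_len(k)) {
    mem <- vapply(cols, `[`, logical(1), g)
    out[g] <- paste(lab[which(mem)], collapse = "")
  }
  out
}

#' Fisher's LSD post hoc test with compact letter display
#'
#' After a one-way ANOVA, declares groups `i` and `j` different iff
#' `|mean_i - mean_j| > t(1 - alpha/2, df_within) *
#' sqrt(MS_within * (1/n_i + 1/n_j))`, then encodes the full pairwise
#' decision matrix as significance letters by the insert-and-absorb
#' procedure: two groups share a letter iff they are not declared
#' different. Letters start at "a" for the highest mean; ties in means are
#' broken by the group factor's level order.
#'
#' @param data A data frame.
#' @param value,group Unquoted response and group columns.
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @param protected If `TRUE`, pairwise tests are only performed when the
#'   ANOVA itself is significant at `alpha`; otherwise all groups share
#'   letter "a". Default `FALSE` (unprotected LSD).
#' @return An object of class `ofs_lsd` with elements `summary` (tibble:
#'   group, n, mean, sd, letters), `pairwise` (tibble of all pairs with the
#'   LSD threshold and decision), `anova` (the `ofs_anova`), and `alpha`.
#' @export
#' @examples
#' plots <- generate_trial(generator_config(), seed = 1)
#' fisher_lsd(plots, grain_zn, treatment)$summary
fisher_lsd <- function(data, value, group, alpha = 0.05, protected = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  groups <- .pull_groups(data, {{ value }}, {{ group }})
  an <- structure(.anova_closed_form(groups), class = "ofs_anova")
  gs <- an$group_stats
  # descending mean; ties broken by original (factor level) order
  ord <- order(-gs$mean, seq_len(nrow(gs)))
  gs <- gs[ord, ]
  k <- nrow(gs)
  tcrit <- stats::qt(1 - alpha / 2, an$df_within)

  pairs <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(
      group1 = gs$group[.data$i], group2 = gs$group[.data$j],
      diff = gs$mean[.data$i] - gs$mean[.data$j],
      lsd = tcrit * sqrt(an$ms_within * (1 / gs$n[.data$i] + 1 / gs$n[.data$j])),
      significant = abs(.data$diff) > .data$lsd
    )
  if (protected && an$p_value >= alpha) {
    pairs$significant <- FALSE
  }
  diff_mat <- matrix(FALSE, k, k)
  diff_mat[cbind(pairs$i, pairs$j)] <- pairs$significant
  diff_mat <- diff_mat | t(diff_mat)
  gs$letters <- .compact_letters(diff_mat)

  structure(
    list(summary = gs,
         pairwise = dplyr::select(pairs, "group1", "group2", "diff", "lsd",
                                  "significant"),
         anova = an, alpha = alpha),
    class = "ofs_lsd"
  )
}

#' @export
print.ofs_lsd <- function(x, ...) {
  cat(sprintf("Fisher LSD (alpha = %g), F(%d, %d) = %.4g, p = %.4f\n",
              x$alpha, x$anova$df_between, x$anova$df_within,
              x$anova$f_statistic, x$anova$p_value))
  print(x$summary)
  invisible(x)
}

#' Tidy a Fisher LSD result
#'
#' @param x An `ofs_lsd` object.
#' @param ... Unused.
#' @return The per-group summary tibble (group, n, mean, sd, letters).
#' @export
tidy.ofs_lsd <- function(x, ...) x$summary

#' Glance at a Fisher LSD result
#'
#' @param x An `ofs_lsd` object.
#' @param ... Unused.
#' @return One row: the underlying ANOVA summary plus `alpha` and the
#'   number of significant pairs.
#' @export
glance.ofs_lsd <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$anova),
    tibble::tibble(alpha = x$alpha,
                   n_significant_pairs = sum(x$pairwise$significant))
  )
}

#' Pearson correlation with two-tailed p-value
#'
#' `r` from the closed-form product-moment formula and a two-tailed
#' p-value from the `t = r * sqrt((n - 2) / (1 - r^2))` transform with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return A one-row tibble: `r`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' pearson(1:10, (1:10)^2)
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance input", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    tstat <- Inf * sign(r); p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  tibble::tibble(r = r, statistic = tstat, df = n - 2, p_value = p)
}

#' Treatment summaries with significance letters
#'
#' For each requested variable, pools all sites and replicates per
#' treatment, runs the closed-form ANOVA and Fisher LSD, and returns
#' mean, SD and significance letters per treatment (the layout of the
#' field-trial tables: same letter = not significantly different). With a
#' single treatment present, letters are `NA` (not applicable).
#'
#' @param plots A plot table.
#' @param variables Columns to summarize.
#' @param alpha Significance level, default 0.05.
#' @param protected Passed to [fisher_lsd()].
#' @return A tibble: `variable`, `treatment`, `n`, `mean`, `sd`, `letters`.
#' @export
#' @examples
#' plots <- generate_trial(generator_config(), seed = 1)
#' treatment_summaries(plots, variables = "yield")
treatment_summaries <- function(plots,
                                variables = c("yield", "grain_fe", "grain_mn",
                                              "grain_cu", "grain_zn",
                                              "phytic_acid"),
                                alpha = 0.05, protected = FALSE) {
  plots <- validate_plot_table(plots)
  single <- dplyr::n_distinct(plots$treatment) < 2
  purrr::map_dfr(variables, function(v) {
    if (single) {
      plots |>
        dplyr::group_by(treatment = .data$treatment) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data[[v]]),
                         sd = stats::sd(.data[[v]]), .groups = "drop") |>
        dplyr::mutate(variable = v, letters = NA_character_, .before = 1)
    } else {
      res <- fisher_lsd(plots, !!rlang::sym(v), treatment, alpha = alpha,
                        protected = protected)
      dplyr::mutate(res$summary, variable = v, .before = 1) |>
        dplyr::rename(treatment = "group")
    }
  }) |>
    dplyr::select("variable", "treatment", "n", "mean", "sd", "letters")
}
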