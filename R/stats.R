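# Group statistics behind the lettered figure panels: one-way ANOVA,
# Tukey-Kramer all-pairs comparisons on the studentized-range
# distribution, a compact letter display, and ordinary least-squares
# regression. Studentized-range tail probabilities come from
# stats::ptukey(); the letter assignment (insert-and-absorb) is
# implemented here because the letters are the reported surface.

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition of total sum of squares into
#' between-group and within-group components;
#' `F = (SSB/(k-1)) / (SSW/(N-k))` with the p-value from the F
#' distribution. Degenerate all-equal input yields F = 0, p = 1.
#'
#' @param groups Named list of numeric vectors, one per group; each group
#'   needs at least two observations.
#' @return List with `F`, `df_between`, `df_within`, `p`, `ms_within`,
#'   `means` (named), `n` (named).
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L))
    stop("every group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) stop("non-finite values in input")
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(values)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i)
    sum((groups[[i]] - means[i])^2), numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  msw <- ssw / df_w
  F <- if (ssb == 0) 0 else if (ssw == 0) Inf else (ssb / df_b) / msw
  p <- stats::pf(F, df_b, df_w, lower.tail = FALSE)
  list(F = F, df_between = df_b, df_within = df_w, p = p,
       ms_within = msw, means = means, n = n)
}

#' Tukey-Kramer honestly-significant-difference comparisons
#'
#' All-pairs comparisons after a one-way ANOVA. For groups i, j the
#' studentized-range statistic is
#' \deqn{q_{ij} = |\bar x_i - \bar x_j| / \sqrt{(MSW/2)(1/n_i + 1/n_j)}}
#' with adjusted p-value from the studentized range distribution with k
#' groups and the ANOVA's within degrees of freedom (the Kramer
#' generalization to unequal n; with equal n it is the classic Tukey HSD).
#' Compact letters are assigned so two groups share a letter if and only
#' if their adjusted p >= alpha. If MSW = 0, pairs with unequal means are
#' declared significant and identical-mean pairs not.
#'
#' @param groups Named list of numeric vectors (as [one_way_anova()]).
#' @param alpha Significance level for the letter display, default 0.05.
#' @return List with `anova` (the [one_way_anova()] result), `pairwise`
#'   (data frame: `group_i`, `group_j`, `diff`, `se`, `q`, `p_adj`,
#'   `significant`) and `letters` (named character vector).
#' @examples
#' tukey_kramer(list(a = c(0, 0.1, -0.1), b = c(10, 10.1, 9.9),
#'                   c = c(20, 20.1, 19.9)))$letters
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  fit <- one_way_anova(groups)
  k <- length(fit$means)
  labels <- names(fit$means)
  pairs <- utils::combn(k, 2)
  pw <- data.frame(group_i = labels[pairs[1, ]], group_j = labels[pairs[2, ]],
                   stringsAsFactors = FALSE)
  pw$diff <- fit$means[pairs[2, ]] - fit$means[pairs[1, ]]
  pw$se <- sqrt(fit$ms_within / 2 *
                  (1 / fit$n[pairs[1, ]] + 1 / fit$n[pairs[2, ]]))
  if (fit$ms_within > 0) {
    pw$q <- abs(pw$diff) / pw$se
    pw$p_adj <- stats::ptukey(pw$q, nmeans = k, df = fit$df_within,
                              lower.tail = FALSE)
  } else {
    pw$q <- ifelse(pw$diff == 0, 0, Inf)
    pw$p_adj <- ifelse(pw$diff == 0, 1, 0)
  }
  pw$significant <- pw$p_adj < alpha
  rownames(pw) <- NULL

  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (r in seq_len(nrow(pw)))
    sig[pw$group_i[r], pw$group_j[r]] <- sig[pw$group_j[r], pw$group_i[r]] <-
      pw$significant[r]
  list(anova = fit, pairwise = pw,
       letters = compact_letters(sig, order(-fit$means)), alpha = alpha)
}

#' Compact letter display from a significance matrix
#'
#' Insert-and-absorb algorithm: starting from a single letter column
#' holding all groups, every significantly different pair splits each
#' column that still contains both of its members into two copies (one
#' without each member); columns that end up as subsets of another are
#' absorbed. The result satisfies: two groups share a letter iff they are
#' not significantly different.
#'
#' @param sig Square logical matrix with dimnames; `sig[i, j]` is `TRUE`
#'   when groups i and j differ significantly.
#' @param order Integer ranking of the groups (typically by descending
#'   mean); controls which column is lettered "a". Defaults to input
#'   order.
#' @return Named character vector of letter strings.
#' @export
compact_letters <- function(sig, order = seq_len(nrow(sig))) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig),
            !is.null(rownames(sig)), !any(diag(sig)))
  labels <- rownames(sig)
  k <- length(labels)
  columns <- list(seq_len(k))
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    new_cols <- list()
    for (col in columns) {
      if (i %in% col && j %in% col)  # insert: duplicate minus each member
        new_cols <- c(new_cols, list(setdiff(col, i), setdiff(col, j)))
      else
        new_cols <- c(new_cols, list(col))
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) for (b in seq_along(new_cols))
      if (a != b && keep[a] &&
          all(new_cols[[a]] %in% new_cols[[b]]) &&
          (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b))
        keep[a] <- FALSE
    columns <- new_cols[keep]
  }
  # letter columns in rank order of their best-ranked member
  rank_of <- match(seq_len(k), order)
  columns <- columns[order(vapply(columns, function(col)
    min(rank_of[col]), numeric(1)))]
  out <- stats::setNames(rep("", k), labels)
  for (ci in seq_along(columns))
    for (g in columns[[ci]])
      out[g] <- paste0(out[g], letters[ci])
  out
}

#' Ordinary least-squares simple linear regression
#'
#' Fits `y = intercept + slope * x` by least squares using the closed-form
#' moment estimators, with r-squared and the two-sided t-test p-value for
#' the slope.
#'
#' @param x,y Numeric vectors of equal length, n >= 3; x must not be
#'   constant.
#' @return List with `slope`, `intercept`, `r_squared`, `p_slope`, `n`.
#' @examples
#' fit_linear(1:5, 2 * (1:5) + 1)
#' @export
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant; slope undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- syy - slope * sxy
  r_squared <- if (syy == 0) 1 else 1 - ss_res / syy
  se_slope <- sqrt(max(ss_res, 0) / (n - 2) / sxx)
  p_slope <- if (se_slope == 0) 0 else
    2 * stats::pt(abs(slope) / se_slope, df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r_squared,
       p_slope = p_slope, n = n)
}

#' Group a table column and compute Tukey-Kramer letters
#'
#' Convenience wrapper used by the `stats` pipeline stage: splits `value`
#' by `group`, runs [tukey_kramer()], and returns a per-group table with
#' mean, sd, n and letter.
#'
#' @param data A data frame.
#' @param value Name of the numeric column to compare.
#' @param group Name of the grouping column.
#' @param alpha Significance level.
#' @return Data frame with `group`, `mean`, `sd`, `n`, `letter`; the full
#'   pairwise table is attached as attribute `"pairwise"`.
#' @export
group_letters <- function(data, value, group, alpha = 0.05) {
  stopifnot(value %in% names(data), group %in% names(data))
  groups <- split(data[[value]], data[[group]])
  tk <- tukey_kramer(groups, alpha = alpha)
  out <- data.frame(group = names(groups),
                    mean = vapply(groups, mean, numeric(1)),
                    sd = vapply(groups, stats::sd, numeric(1)),
                    n = vapply(groups, length, integer(1)),
                    letter = unname(tk$letters[names(groups)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pairwise") <- tk$pairwise
  out
}
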