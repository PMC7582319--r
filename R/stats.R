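# Induction-factor statistics, replicate SNR, group tests, dose-response.

#' Induction factor Bi / Bc
#'
#' The headline biosensor statistic: the treated sample's signal readout
#' divided by the control's. For plate-reader traces the readout is the
#' trace maximum; for smartphone/CMOS measurements it is the window-mean net
#' intensity. The ratio itself is agnostic to how the readouts were made and
#' is invariant to detector gain.
#'
#' @param bi Treated readout (>= 0).
#' @param bc Control readout (> 0).
#' @return `bi / bc`.
#' @export
induction_factor <- function(bi, bc) {
  if (any(bc <= 0)) stop("control signal Bc must be positive")
  if (any(bi < 0)) stop("treated signal Bi must be non-negative")
  bi / bc
}

#' Replicate signal-to-noise ratio
#'
#' Mean induction factor across replicates divided by their sample standard
#' deviation (n - 1 denominator). Requires at least three replicates; zero
#' replicate variance is reported as an error (the ratio is undefined, not
#' infinite).
#'
#' @param replicate_factors Numeric vector of per-replicate induction
#'   factors (length >= 3).
#' @return Mean / SD.
#' @examples
#' signal_noise_ratio(c(2, 4, 6))  # 2
#' @export
signal_noise_ratio <- function(replicate_factors) {
  if (length(replicate_factors) < 3)
    stop("signal-to-noise ratio requires at least three replicates")
  s <- stats::sd(replicate_factors)
  if (s == 0)
    stop("replicate variance is zero; signal-to-noise ratio undefined")
  mean(replicate_factors) / s
}

#' Fold difference between two induction factors
#'
#' @param factor_a,factor_b Positive ratios.
#' @return `factor_a / factor_b`.
#' @examples
#' fold_difference(3.2, 2.0)  # 1.6
#' @export
fold_difference <- function(factor_a, factor_b) {
  if (any(c(factor_a, factor_b) <= 0))
    stop("induction factors must be positive")
  factor_a / factor_b
}

#' Two-group comparison (paired or two-sample t-test)
#'
#' Two-sided Student t-test between two groups, paired when replicates
#' correspond. Degenerate inputs (zero variance of the paired differences,
#' or of both groups) are rejected with an explicit error rather than an
#' infinite statistic.
#'
#' @param group_a,group_b Numeric vectors, n >= 2 each; equal lengths when
#'   `paired`.
#' @param paired Logical.
#' @return List: `statistic` (t), `p_value`, `df`, `method`.
#' @export
two_group_test <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least two observations per group")
  if (paired && length(group_a) != length(group_b))
    stop("paired test requires equal group lengths")
  if (paired && stats::sd(group_a - group_b) == 0) {
    if (all(group_a == group_b))
      return(list(statistic = 0, p_value = 1,
                  df = length(group_a) - 1, method = "paired t-test"))
    stop("paired differences have zero variance; t statistic undefined")
  }
  ht <- tryCatch(
    stats::t.test(group_a, group_b, paired = paired, var.equal = FALSE),
    error = function(e) stop("degenerate groups: ", conditionMessage(e),
                             call. = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       method = if (paired) "paired t-test" else "Welch two-sample t-test")
}

#' One-way ANOVA with Fisher's LSD letters
#'
#' One-way ANOVA F test across three or more groups, followed by Fisher's
#' Least Significant Difference pairwise comparisons: unadjusted t-tests
#' using the pooled mean-square error and its residual degrees of freedom,
#' `t = (mi - mj) / sqrt(MSE * (1/ni + 1/nj))`. Group means are summarized
#' by a compact-letter display, assigned from the largest mean downward;
#' groups sharing a letter are not significantly different at `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return List (class `wcb_anova_lsd`): `f_statistic`, `p_value`,
#'   `df_between`, `df_within`, `mse`, `pairwise` (data frame `group_a,
#'   group_b, diff, t, p_value, significant`), `letters` (named character),
#'   `means`.
#' @export
anova_lsd <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups))
  if (length(groups) < 3) stop("need at least three groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least two values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups)),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- stats::anova(fit)
  mse <- tab["Residuals", "Mean Sq"]
  dfe <- tab["Residuals", "Df"]
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ])
  pw$diff <- means[pw$group_a] - means[pw$group_b]
  pw$t <- pw$diff / sqrt(mse * (1 / ns[pw$group_a] + 1 / ns[pw$group_b]))
  pw$p_value <- 2 * stats::pt(-abs(pw$t), dfe)
  pw$significant <- pw$p_value < alpha
  rownames(pw) <- NULL
  structure(list(f_statistic = tab["group", "F value"],
                 p_value = tab["group", "Pr(>F)"],
                 df_between = tab["group", "Df"], df_within = dfe, mse = mse,
                 pairwise = pw,
                 letters = .lsd_letters(means, pw),
                 means = means, alpha = alpha),
            class = "wcb_anova_lsd")
}

# Compact-letter display: sweep groups sorted by decreasing mean; each
# letter covers a maximal run of consecutive groups that are pairwise
# not significantly different.
.lsd_letters <- function(means, pairwise) {
  ord <- names(sort(means, decreasing = TRUE))
  k <- length(ord)
  sig <- function(a, b) {
    row <- (pairwise$group_a == a & pairwise$group_b == b) |
           (pairwise$group_a == b & pairwise$group_b == a)
    any(pairwise$significant[row])
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(vapply(i:j, function(m) sig(ord[m], ord[j + 1]),
                                logical(1))))
      j <- j + 1
    runs[[length(runs) + 1]] <- i:j
  }
  # keep only maximal runs (drop runs nested in an earlier one)
  maximal <- Filter(function(r) !any(vapply(runs, function(s)
    !identical(s, r) && all(r %in% s), logical(1))), runs)
  letters_out <- stats::setNames(rep("", k), ord)
  for (li in seq_along(maximal))
    for (i in maximal[[li]])
      letters_out[ord[i]] <- paste0(letters_out[ord[i]], letters[li])
  letters_out[names(means)]
}

#' @export
print.wcb_anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  out <- data.frame(mean = x$means, letters = x$letters)
  print(out)
  invisible(x)
}

#' Dose-response table of induction factors
#'
#' Converts per-replicate window readouts at each toxicant concentration
#' into induction factors relative to the mean control readout, and
#' tabulates mean +/- SEM per concentration. The control appears as the
#' concentration-0 row with induction 1. A monotonicity flag records
#' whether mean induction is non-decreasing with concentration (the
#' expected dose-dependent pattern).
#'
#' @param treated Data frame with columns `concentration` (> 0, % v/v) and
#'   `readout` (one row per replicate).
#' @param control Numeric vector of control readouts (required; mean > 0).
#' @return Data frame (class `wcb_dose_table`): `concentration, induction,
#'   sem, n`, sorted by concentration, with attribute `monotone`.
#' @export
dose_response <- function(treated, control) {
  if (missing(control) || length(control) == 0)
    stop("control readouts are required")
  stopifnot(is.data.frame(treated),
            all(c("concentration", "readout") %in% names(treated)))
  bc <- mean(control)
  if (bc <= 0) stop("mean control readout must be positive")
  ctrl_factors <- control / bc
  rows <- list(data.frame(
    concentration = 0, induction = 1,
    sem = stats::sd(ctrl_factors) / sqrt(length(control)),
    n = length(control)))
  for (conc in sort(unique(treated$concentration))) {
    f <- induction_factor(treated$readout[treated$concentration == conc], bc)
    rows[[length(rows) + 1]] <- data.frame(
      concentration = conc, induction = mean(f),
      sem = if (length(f) > 1) stats::sd(f) / sqrt(length(f)) else NA_real_,
      n = length(f))
  }
  out <- do.call(rbind, rows)
  attr(out, "monotone") <- !is.unsorted(out$induction)
  class(out) <- c("wcb_dose_table", "data.frame")
  out
}
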