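#' Per-feature fold change between case and control
#'
#' Fold change is the ratio of group means of the (linear-scale) relative
#' quantification values, case over control, using present values only.
#' Features with fewer than `min_per_group` present values in either group
#' are flagged untestable; their fold change is still reported when both
#' group means are computable.
#'
#' @param tab A corrected [intensity_table()].
#' @param min_per_group Minimum present values required per group for a
#'   feature to be testable. Default 2.
#' @return data.frame with `feature`, `fc`, `log2fc`, `n_control`, `n_case`,
#'   `testable`.
#' @export
compute_fold_change <- function(tab, min_per_group = 2L) {
  stopifnot(inherits(tab, "intensity_table"))
  ctrl <- group_columns(tab, "control")
  case <- group_columns(tab, "case")
  n_c <- rowSums(!is.na(ctrl))
  n_m <- rowSums(!is.na(case))
  fc <- rowMeans(case, na.rm = TRUE) / rowMeans(ctrl, na.rm = TRUE)
  fc[n_c == 0L | n_m == 0L] <- NA_real_
  data.frame(feature = rownames(tab$values), fc = unname(fc),
             log2fc = unname(log2(fc)), n_control = unname(n_c),
             n_case = unname(n_m),
             testable = unname(n_c >= min_per_group & n_m >= min_per_group),
             stringsAsFactors = FALSE)
}

#' Gate the choice between Student's and Welch's t-test
#'
#' Assesses normality of each group's log2 values with the Shapiro-Wilk test
#' and homogeneity of variances with the Brown-Forsythe (median-centered
#' Levene) test. Student's t-test is selected only when neither assumption
#' is rejected at `gate_alpha`; otherwise Welch's. Shapiro-Wilk needs at
#' least 3 distinct values per group; groups too small or constant cannot
#' reject normality and pass that gate. Features with zero variance in both
#' groups are untestable.
#'
#' @param control,case Numeric vectors of present linear-scale values
#'   (length >= 2 each).
#' @param gate_alpha Gate significance level. Default 0.05.
#' @return List: `shapiro_p` (length-2, control/case), `levene_p`,
#'   `decision` (`"student"`, `"welch"` or `"untestable"`).
#' @export
select_test <- function(control, case, gate_alpha = 0.05) {
  lc <- log2(control)
  lm_ <- log2(case)
  if (length(lc) < 2L || length(lm_) < 2L) {
    return(list(shapiro_p = c(control = NA_real_, case = NA_real_),
                levene_p = NA_real_, decision = "untestable"))
  }
  if (sd(lc) == 0 && sd(lm_) == 0) {
    return(list(shapiro_p = c(control = NA_real_, case = NA_real_),
                levene_p = NA_real_, decision = "untestable"))
  }
  sw <- function(x) {
    if (length(x) < 3L || sd(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }
  sp <- c(control = sw(lc), case = sw(lm_))
  ## perfect fits (e.g. groups of 2) make the Levene F unreliable; its
  ## NaN p is treated as "cannot reject equal variances" below
  lev <- tryCatch({
    y <- c(lc, lm_)
    g <- factor(rep(c("control", "case"), c(length(lc), length(lm_))))
    suppressWarnings(
      as.numeric(car::leveneTest(y, g, center = median)[1, "Pr(>F)"]))
  }, error = function(e) NA_real_)
  normal_ok <- all(is.na(sp) | sp >= gate_alpha)
  var_ok <- is.na(lev) || lev >= gate_alpha
  list(shapiro_p = sp, levene_p = lev,
       decision = if (normal_ok && var_ok) "student" else "welch")
}

#' Two-sided t-test p-value on log2 values
#'
#' Applies the gated test (`"student"` = equal-variance, `"welch"` =
#' unequal-variance) to the log2-transformed group values. Untestable
#' features get p = 1.
#'
#' @inheritParams select_test
#' @param decision Gate decision from [select_test()].
#' @return Two-sided p-value.
#' @export
test_feature <- function(control, case, decision) {
  if (decision == "untestable") return(1)
  lc <- log2(control)
  lm_ <- log2(case)
  out <- tryCatch(
    t.test(lm_, lc, var.equal = (decision == "student"))$p.value,
    error = function(e) NA_real_)
  if (is.na(out)) 1 else out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate control: the adjusted value of the i-th
#' order statistic is `min over j >= i of p_(j) * m / j`, clipped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order; empty input gives empty output.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop_validation("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call significance from fold change and p-value
#'
#' A feature is `"up"` when `fc > up_threshold` and `p < alpha`, `"down"`
#' when `fc < down_threshold` and `p < alpha`, otherwise `"ns"`.
#'
#' @param fc Linear-scale fold change (> 0); may be `NA`.
#' @param p p-value; may be `NA`.
#' @param up_threshold,down_threshold Fold-change cutoffs; defaults 1.5 and
#'   1/1.5.
#' @param alpha Significance level on the (raw) p-value. Default 0.05.
#' @return Character vector of calls (`"up"`, `"down"`, `"ns"`), vectorized
#'   over `fc`/`p`.
#' @export
call_significant <- function(fc, p, up_threshold = 1.5,
                             down_threshold = 1 / up_threshold,
                             alpha = 0.05) {
  call <- rep("ns", length(fc))
  ok <- !is.na(fc) & !is.na(p)
  call[ok & fc > up_threshold & p < alpha] <- "up"
  call[ok & fc < down_threshold & p < alpha] <- "down"
  call
}

#' Full two-group differential analysis of a corrected table
#'
#' For every feature: fold change (ratio of linear-scale group means),
#' assumption-gated t-test on log2 values, BH q-value across all tested
#' features, and an up/down/ns call from the fold-change cutoffs and raw
#' p-value (q-values are reported alongside).
#'
#' @param tab A corrected [intensity_table()].
#' @param up_threshold,down_threshold,alpha Calling thresholds; see
#'   [call_significant()].
#' @param gate_alpha Gate level for [select_test()]. Default 0.05.
#' @param min_per_group Minimum present values per group. Default 2.
#' @return data.frame with one row per feature: `feature`, `fc`, `log2fc`,
#'   `p`, `q`, `neg_log10_p`, `shapiro_p_control`, `shapiro_p_case`,
#'   `levene_p`, `test_used`, `call`. Untestable features carry
#'   `test_used = "untestable"`, `p = NA`, `call = "ns"`.
#' @export
run_differential <- function(tab, up_threshold = 1.5,
                             down_threshold = 1 / up_threshold,
                             alpha = 0.05, gate_alpha = 0.05,
                             min_per_group = 2L) {
  stopifnot(inherits(tab, "intensity_table"))
  fcs <- compute_fold_change(tab, min_per_group = min_per_group)
  ctrl <- group_columns(tab, "control")
  case <- group_columns(tab, "case")
  n <- nrow(fcs)
  p <- rep(NA_real_, n)
  test_used <- rep("untestable", n)
  sp_c <- sp_m <- lev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!fcs$testable[i]) next
    cv <- ctrl[i, !is.na(ctrl[i, ])]
    mv <- case[i, !is.na(case[i, ])]
    gate <- select_test(cv, mv, gate_alpha = gate_alpha)
    sp_c[i] <- gate$shapiro_p[["control"]]
    sp_m[i] <- gate$shapiro_p[["case"]]
    lev[i] <- gate$levene_p
    test_used[i] <- gate$decision
    p[i] <- test_feature(cv, mv, gate$decision)
  }
  q <- rep(NA_real_, n)
  tested <- test_used != "untestable"
  q[tested] <- adjust_bh(p[tested])
  res <- data.frame(feature = fcs$feature, fc = fcs$fc, log2fc = fcs$log2fc,
                    p = p, q = q, neg_log10_p = -log10(p),
                    shapiro_p_control = sp_c, shapiro_p_case = sp_m,
                    levene_p = lev, test_used = test_used,
                    stringsAsFactors = FALSE)
  res$call <- call_significant(res$fc, res$p, up_threshold = up_threshold,
                               down_threshold = down_threshold, alpha = alpha)
  res$call[test_used == "untestable"] <- "ns"
  res
}

#' Summarize differential calls
#'
#' @param result data.frame from [run_differential()].
#' @return Named integer vector: `n_features`, `n_tested`, `n_untestable`,
#'   `n_up`, `n_down`, `n_ns`.
#' @export
summarize_differential <- function(result) {
  c(n_features = nrow(result),
    n_tested = sum(result$test_used != "untestable"),
    n_untestable = sum(result$test_used == "untestable"),
    n_up = sum(result$call == "up"),
    n_down = sum(result$call == "down"),
    n_ns = sum(result$call == "ns"))
}
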