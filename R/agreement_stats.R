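#' Intraclass correlation coefficient with exact F confidence interval
#'
#' ICC for a complete subjects-by-raters matrix, from the two-way (or
#' one-way) ANOVA mean squares, with the exact F-based 95% confidence
#' interval of Shrout & Fleiss / McGraw & Wong. The default form is
#' ICC(2,1): two-way random effects, single measures, absolute agreement -
#' the standard choice for inter-observer reliability of continuous
#' radiographic measurements. The form used is always recorded in the result
#' so that reported reliabilities cannot be silently mismatched.
#'
#' The p value tests ICC = 0 via F = MSR/MSE (MSR/MSW for the one-way form),
#' as conventional reliability software reports it.
#'
#' @param x Numeric matrix or data frame, subjects in rows, raters in
#'   columns; at least 3 subjects and 2 raters, no missing cells (apply
#'   listwise deletion upstream and log the count).
#' @param model ICC form: `"ICC(2,1)"` (default), `"ICC(2,k)"`,
#'   `"ICC(3,1)"`, `"ICC(3,k)"`, `"ICC(1,1)"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci95 = c(low, high)`,
#'   `p_value`, `model`, `n_subjects`, `n_raters`, and the mean squares
#'   `MSR`, `MSC`, `MSE`, `MSW`.
#' @references Shrout, P.E. & Fleiss, J.L. (1979) Intraclass correlations:
#'   uses in assessing rater reliability. Psychological Bulletin 86, 420-428.
#'   McGraw, K.O. & Wong, S.P. (1996) Forming inferences about some
#'   intraclass correlation coefficients. Psychological Methods 1, 30-46.
#' @export
icc <- function(x, model = c("ICC(2,1)", "ICC(2,k)", "ICC(3,1)", "ICC(3,k)",
                             "ICC(1,1)"),
                conf_level = 0.95) {
  model <- match.arg(model)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("ratings must be numeric", call. = FALSE)
  if (anyNA(x))
    stop("ratings matrix has missing cells; apply listwise deletion upstream",
         call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("at least 3 subjects are required", call. = FALSE)
  if (k < 2) stop("at least 2 raters are required", call. = FALSE)

  g <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  SST <- sum((x - g)^2)
  if (SST <= 0)
    stop("undefined ICC: the ratings have zero total variance",
         call. = FALSE)
  SSR <- k * sum((rm_ - g)^2)
  SSC <- n * sum((cm - g)^2)
  SSE <- SST - SSR - SSC
  SSW <- SST - SSR
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- max(SSE / ((n - 1) * (k - 1)), 0)
  MSW <- SSW / (n * (k - 1))

  alpha <- 1 - conf_level
  qU <- function(df1, df2) stats::qf(1 - alpha / 2, df1, df2)

  if (model == "ICC(1,1)") {
    val <- (MSR - MSW) / (MSR + (k - 1) * MSW)
    Fo <- if (MSW > 0) MSR / MSW else Inf
    FL <- Fo / qU(n - 1, n * (k - 1))
    FU <- Fo * qU(n * (k - 1), n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
    p <- stats::pf(Fo, n - 1, n * (k - 1), lower.tail = FALSE)
  } else if (model %in% c("ICC(3,1)", "ICC(3,k)")) {
    single <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fo <- if (MSE > 0) MSR / MSE else Inf
    FL <- Fo / qU(n - 1, (n - 1) * (k - 1))
    FU <- Fo * qU((n - 1) * (k - 1), n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
    p <- stats::pf(Fo, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    if (model == "ICC(3,k)") {
      sb <- function(r) r * k / (1 + (k - 1) * r)
      val <- sb(single); lo <- sb(lo); hi <- sb(hi)
    } else val <- single
  } else {  # ICC(2,1) / ICC(2,k)
    single <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    # Satterthwaite df for the agreement interval (McGraw & Wong)
    r <- single
    if (r < 1 && (MSC > 0 || MSE > 0)) {
      a <- k * r / (n * (1 - r))
      b <- 1 + k * r * (n - 1) / (n * (1 - r))
      num <- (a * MSC + b * MSE)^2
      den <- (a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1))
      v <- if (den > 0) num / den else Inf
      F1 <- qU(n - 1, v)
      F2 <- qU(v, n - 1)
      lo <- n * (MSR - F1 * MSE) /
        (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (F2 * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
    } else {
      lo <- hi <- 1
    }
    Fo <- if (MSE > 0) MSR / MSE else Inf
    p <- stats::pf(Fo, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    if (model == "ICC(2,k)") {
      sb <- function(r) r * k / (1 + (k - 1) * r)
      val <- sb(single); lo <- sb(lo); hi <- sb(hi)
    } else val <- single
  }

  structure(list(icc = val, ci95 = c(low = min(lo, val), high = max(hi, val)),
                 p_value = p, model = model, n_subjects = n, n_raters = k,
                 MSR = MSR, MSC = MSC, MSE = MSE, MSW = MSW,
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f, %g%% CI [%.3f, %.3f], p = %.3g (n = %d subjects, %d raters)\n",
              x$model, x$icc, 100 * x$conf_level, x$ci95[["low"]],
              x$ci95[["high"]], x$p_value, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Pearson correlation matrix across indices
#'
#' Pairwise Pearson correlations over the measured indices of a set of
#' same-phase panels, in the conventional ordering PTS, AP, jAP, IS, mIS,
#' CD, BP, JLH. Constant columns have undefined correlations; those cells
#' are `NA` and the affected indices are listed in the `"constant"`
#' attribute.
#'
#' @param panels List of `index_panel` objects, or a data frame as produced
#'   by [panel_table()].
#' @param phase Optional phase filter (`"pre"` or `"post"`).
#' @return Symmetric correlation matrix with attribute `"constant"`.
#' @export
pearson_matrix <- function(panels, phase = NULL) {
  df <- if (is.data.frame(panels)) panels else panel_table(panels)
  if (!is.null(phase)) df <- df[df$phase == phase, , drop = FALSE]
  if (nrow(df) < 3)
    stop("at least 3 cases are required for a correlation matrix",
         call. = FALSE)
  cols <- c(PTS = "PTS_deg", AP = "AP", jAP = "jAP", IS = "IS", mIS = "mIS",
            CD = "CD", BP = "BP", JLH = "JLH_mm")
  cols <- cols[cols %in% names(df) | names(cols) %in% names(df)]
  m <- sapply(cols, function(cn)
    if (cn %in% names(df)) df[[cn]] else df[[names(cols)[cols == cn]]])
  colnames(m) <- names(cols)
  constant <- names(cols)[apply(m, 2, function(v) stats::sd(v) == 0)]
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  if (length(constant)) r[constant, ] <- r[, constant] <- NA_real_
  diag(r)[!(names(cols) %in% constant)] <- 1
  attr(r, "constant") <- constant
  r
}

#' Paired t test on pre/post values
#'
#' Differences are `post - pre`. The degenerate case of zero-variance
#' differences is handled by convention: mean zero gives t = 0, p = 1; a
#' nonzero mean gives t = +/-Inf, p = 0, with `degenerate = TRUE`.
#'
#' @param pre,post Equal-length paired numeric vectors, n >= 2.
#' @return List: `mean_diff`, `sd_diff`, `t`, `df`, `p_value`, `n`,
#'   `degenerate`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(pre)
  if (n < 2) stop("at least 2 pairs are required", call. = FALSE)
  d <- post - pre
  md <- mean(d); sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    return(list(mean_diff = md, sd_diff = 0, t = t, df = n - 1, p_value = p,
                n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(mean_diff = md, sd_diff = sdd, t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, n = n,
       degenerate = FALSE)
}

#' Bland-Altman limits of agreement
#'
#' Differences are first argument minus second (`m1 - m2`: observer 1 minus
#' observer 2, or first reading minus second reading). Reversing the
#' arguments negates the bias and swaps/negates the limits.
#'
#' @param m1,m2 Equal-length paired numeric vectors, n >= 3.
#' @return Object of class `bland_altman`: `bias`, `sd_diff` (sample SD,
#'   n - 1 denominator), `loa_low = bias - 1.96 sd`, `loa_high = bias +
#'   1.96 sd`, `n`, plus `means` and `diffs` for plotting.
#' @export
bland_altman <- function(m1, m2) {
  if (length(m1) != length(m2))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(m1)
  if (n < 3) stop("at least 3 pairs are required", call. = FALSE)
  d <- m1 - m2
  bias <- mean(d); sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = n, means = (m1 + m2) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (m1 - m2): bias %.4f, SD %.4f, 95%% LoA [%.4f, %.4f], n = %d\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Means versus differences with the bias line and the two limits of
#' agreement, in the conventional layout.
#'
#' @param x A [bland_altman()] result.
#' @param main,xlab,ylab Plot annotations.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, main = "Bland-Altman plot",
                              xlab = "Mean of the two measurements",
                              ylab = "Difference (m1 - m2)", ...) {
  graphics::plot(x$means, x$diffs, main = main, xlab = xlab, ylab = ylab,
                 pch = 19, col = "grey30",
                 ylim = range(c(x$diffs, x$loa_low, x$loa_high)), ...)
  graphics::abline(h = x$bias, col = "blue", lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  invisible(x)
}

#' Cohort summary of paired pre/post panels
#'
#' Per-index mean and SD pre and post with the paired-t p value, plus a
#' final `JLH (post-pre)` row summarising the joint-line elevation, in the
#' layout of a pre/post arthroplasty baseline table.
#'
#' @param pairs List of [paired_deltas()] results.
#' @return Data frame with columns `index`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`, `p_value`, `n`. A single pair gives an `NA` p
#'   value (undefined).
#' @export
cohort_summary <- function(pairs) {
  if (inherits(pairs, "paired_case")) pairs <- list(pairs)
  if (!length(pairs)) stop("at least 1 pair is required", call. = FALSE)
  n <- length(pairs)
  rows <- lapply(PANEL_INDICES, function(nm) {
    pre <- vapply(pairs, function(p) p$pre[[nm]], numeric(1))
    post <- vapply(pairs, function(p) p$post[[nm]], numeric(1))
    p <- if (n >= 2) paired_t(pre, post)$p_value else NA_real_
    data.frame(index = nm, pre_mean = mean(pre), pre_sd = stats::sd(pre),
               post_mean = mean(post), post_sd = stats::sd(post),
               p_value = p, n = n)
  })
  djlh <- vapply(pairs, function(p) p$deltas[["JLH"]], numeric(1))
  rows[[length(rows) + 1L]] <- data.frame(
    index = "JLH (post-pre)", pre_mean = NA_real_, pre_sd = NA_real_,
    post_mean = mean(djlh), post_sd = stats::sd(djlh), p_value = NA_real_,
    n = n)
  do.call(rbind, rows)
}

#' Reliability table over a long-format ratings set
#'
#' Computes one ICC per index from a long ratings table, the layout of an
#' inter/intra-observer agreement table (ICC, CI bounds, p, n).
#'
#' @param ratings Data frame with columns `subject_id`, `rater`, and one
#'   column per index.
#' @param indices Index columns to analyse (default: all columns except
#'   `subject_id` and `rater`).
#' @param model ICC form, see [icc()].
#' @return Data frame: `index`, `icc`, `ci_low`, `ci_high`, `p_value`,
#'   `n_subjects`, `n_raters`, `model`.
#' @export
reliability_table <- function(ratings, indices = NULL, model = "ICC(2,1)") {
  for (key in c("subject_id", "rater"))
    if (!key %in% names(ratings))
      stop(sprintf("ratings table lacks column '%s'", key), call. = FALSE)
  if (is.null(indices))
    indices <- setdiff(names(ratings), c("subject_id", "rater"))
  do.call(rbind, lapply(indices, function(nm) {
    wide <- stats::reshape(
      ratings[, c("subject_id", "rater", nm)],
      idvar = "subject_id", timevar = "rater", direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 3)
      stop(sprintf("index '%s': fewer than 3 complete subjects", nm),
           call. = FALSE)
    r <- icc(m, model = model)
    data.frame(index = nm, icc = r$icc, ci_low = r$ci95[["low"]],
               ci_high = r$ci95[["high"]], p_value = r$p_value,
               n_subjects = r$n_subjects, n_raters = r$n_raters,
               model = r$model)
  }))
}
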