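#' Fit an RMS match/non-match threshold
#'
#' Fits the decision threshold separating matching from non-matching RMS
#' values. In `midpoint` mode, when the classes separate perfectly the cutoff
#' is the midpoint between the largest matching and smallest non-matching
#' RMS (accuracy 1); otherwise the threshold maximising training accuracy is
#' chosen (ties resolve to the smaller threshold). In `logistic` mode a
#' univariate logistic regression is fitted; perfect separation makes the
#' maximum-likelihood coefficient diverge, so separation is detected
#' explicitly, flagged via `separable`, and the cutoff falls back to the
#' midpoint rule rather than reporting a numerically unstable coefficient.
#' Otherwise the cutoff is the RMS at predicted probability 0.5.
#'
#' Classification uses the convention of [classify_match()]: match iff
#' `rms < cutoff`.
#'
#' @param rms numeric RMS values (mm).
#' @param is_match logical, same length; both classes must be present.
#' @param mode `"midpoint"` or `"logistic"`.
#' @return A list of class `cutoff_result`: `cutoff` (mm), `accuracy`,
#'   `mode`, `separable`.
#' @examples
#' fit_rms_cutoff(c(0.1, 0.2, 0.4, 0.5), c(TRUE, TRUE, FALSE, FALSE))
#' @export
fit_rms_cutoff <- function(rms, is_match, mode = c("midpoint", "logistic")) {
  mode <- match.arg(mode)
  ok <- is.finite(rms) & !is.na(is_match)
  rms <- rms[ok]
  is_match <- as.logical(is_match[ok])
  if (!any(is_match) || all(is_match))
    stopf("both matching and non-matching values are required")
  mmax <- max(rms[is_match])
  nmin <- min(rms[!is_match])
  perfectly_sep <- mmax < nmin
  midpoint_fit <- function() {
    if (perfectly_sep) {
      list(cutoff = (mmax + nmin) / 2, separable = TRUE)
    } else {
      cand <- sort(unique(c(rms, max(rms) * (1 + 1e-9) + 1e-12)))
      acc <- vapply(cand, function(t) mean((rms < t) == is_match), numeric(1))
      list(cutoff = cand[which.max(acc)], separable = FALSE)
    }
  }
  if (mode == "midpoint") {
    f <- midpoint_fit()
  } else {
    sep_warned <- FALSE
    fit <- withCallingHandlers(
      glm(is_match ~ rms, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    b <- coef(fit)
    diverged <- sep_warned || !all(is.finite(b)) || abs(b[2]) > 1e3
    if (perfectly_sep || diverged) {
      f <- midpoint_fit()
      f$separable <- TRUE
    } else {
      f <- list(cutoff = as.numeric(-b[1] / b[2]), separable = FALSE)
    }
  }
  acc <- mean((rms < f$cutoff) == is_match)
  structure(list(cutoff = f$cutoff, accuracy = acc, mode = mode,
                 separable = f$separable),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("RMS cutoff %.4f mm (%s mode%s), training accuracy %.1f%%\n",
              x$cutoff, x$mode, if (x$separable) ", perfectly separable" else "",
              100 * x$accuracy))
  invisible(x)
}

#' Classify an RMS value against a cutoff
#'
#' Match iff `rms < cutoff`. An RMS exactly at the cutoff is classified
#' non-match — the fail-safe convention for identification (never assert an
#' identity on a boundary value).
#'
#' @param rms numeric RMS value(s), must be non-negative.
#' @param cutoff positive cutoff (mm).
#' @return Character vector `"match"`/`"non-match"`.
#' @export
classify_match <- function(rms, cutoff) {
  if (!is_scalar_number(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  if (any(rms < 0)) stopf("RMS values must be non-negative")
  ifelse(rms < cutoff, "match", "non-match")
}

#' Box-Cox power parameter by profile likelihood
#'
#' Profiles the Box-Cox family `(x^lambda - 1)/lambda` (log at `lambda = 0`)
#' over a grid, maximising the normal profile log-likelihood including the
#' Jacobian term `(lambda - 1) * sum(log x)`. Used as the transformation
#' diagnostic for RMS regression modelling.
#'
#' @param x positive numeric values, `n >= 3`.
#' @param grid lambda grid searched.
#' @return A list of class `boxcox_result`: `lambda`, `loglik` (at the
#'   optimum), `grid`, `loglik_grid`.
#' @export
boxcox_lambda <- function(x, grid = seq(-3, 3, by = 0.01)) {
  if (any(!is.finite(x)) || any(x <= 0)) stopf("Box-Cox requires positive values")
  n <- length(x)
  if (n < 3) stopf("need at least 3 values")
  slx <- sum(log(x))
  ll <- vapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(x) else (x^lam - 1) / lam
    v <- mean((z - mean(z))^2)
    -n / 2 * log(v) + (lam - 1) * slx
  }, numeric(1))
  i <- which.max(ll)
  structure(list(lambda = grid[i], loglik = ll[i], grid = grid,
                 loglik_grid = ll),
            class = "boxcox_result")
}

#' @export
print.boxcox_result <- function(x, ...) {
  cat(sprintf("Box-Cox lambda %.2f (profile log-likelihood %.2f)\n",
              x$lambda, x$loglik))
  invisible(x)
}

#' Pairwise method contrasts with Bonferroni adjustment
#'
#' Welch two-sample comparisons of cell means between every pair of
#' segmentation methods, computed separately within the matching and
#' non-matching strata; raw p-values are multiplied by the number of pairwise
#' comparisons (capped at 1). With `response = "sd"` the observations are the
#' within-pairing replicate SDs (precision rather than level).
#'
#' @param table comparison table from [run_study()].
#' @param response `"rms"` or `"sd"`.
#' @return A data frame with one row per stratum and method pair:
#'   `is_match, method_a, method_b, mean_a, mean_b, diff, statistic, df,
#'   p_value, p_adjusted`.
#' @export
pairwise_bonferroni <- function(table, response = c("rms", "sd")) {
  response <- match.arg(response)
  tab <- table[!is.na(table$rms), , drop = FALSE]
  methods <- sort(unique(tab$method))
  if (length(methods) < 2) stopf("need at least 2 methods to compare")
  obs <- if (response == "rms") {
    tab[, c("method", "is_match", "rms")]
  } else {
    key <- interaction(tab$participant_a, tab$participant_b, tab$arch,
                       tab$method, tab$session, tab$operator, drop = TRUE)
    sds <- tapply(tab$rms, key, function(x)
      if (length(x) < 2) NA_real_ else sd(x))
    first <- tab[!duplicated(key), , drop = FALSE]
    data.frame(method = first$method, is_match = first$is_match,
               rms = as.numeric(sds[as.character(unique(key))]),
               stringsAsFactors = FALSE)
  }
  cmb <- utils::combn(methods, 2)
  m <- ncol(cmb)
  rows <- list()
  for (stratum in c(TRUE, FALSE)) {
    sub <- obs[obs$is_match == stratum & !is.na(obs$rms), , drop = FALSE]
    if (nrow(sub) == 0) next
    for (k in seq_len(m)) {
      a <- sub$rms[sub$method == cmb[1, k]]
      b <- sub$rms[sub$method == cmb[2, k]]
      row <- data.frame(is_match = stratum, method_a = cmb[1, k],
                        method_b = cmb[2, k], mean_a = mean(a), mean_b = mean(b),
                        diff = mean(a) - mean(b), statistic = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        p_adjusted = NA_real_, stringsAsFactors = FALSE)
      if (length(a) >= 2 && length(b) >= 2 &&
          (stats::var(a) + stats::var(b)) > 0) {
        tt <- t.test(a, b)
        row$statistic <- unname(tt$statistic)
        row$df <- unname(tt$parameter)
        row$p_value <- tt$p.value
        row$p_adjusted <- min(1, tt$p.value * m)
      } else if (length(a) >= 2 && length(b) >= 2) {
        # degenerate zero-variance samples: Welch statistic undefined
        row$statistic <- 0
        row$p_value <- if (row$diff == 0) 1 else 0
        row$p_adjusted <- row$p_value
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
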