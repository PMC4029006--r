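# Brain-behavior and brain-practice association statistics: partial
# correlation with covariate residualization, log transforms, and the
# practice-hours outlier exclusion rule.

#' Partial correlation with covariate residualization
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed (with intercept) on the covariates; with `k` covariates the
#' degrees of freedom are `n - 2 - k` and the p-value comes from
#' `t = r * sqrt(df / (1 - r^2))`. An empty covariate set reduces to the
#' plain Pearson correlation.
#'
#' @param x,y numeric vectors, one value per subject.
#' @param covariates optional data.frame/matrix of per-subject covariates
#'   (binary covariates such as gender enter as 0/1 regressors).
#' @return list with `r`, `df`, `p`, `n`, `k`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  k <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    z <- as.matrix(as.data.frame(covariates))
    storage.mode(z) <- "double"
    if (nrow(z) != n) stop("covariate rows must match subjects")
    k <- ncol(z)
    if (n < k + 3L) stop("need n >= k + 3 subjects")
    design <- cbind(1, z)
    qrz <- qr(design)
    if (qrz$rank < ncol(design)) {
      stop("rank-deficient covariate matrix")
    }
    x <- qr.resid(qrz, x)
    y <- qr.resid(qrz, y)
  } else if (n < 3L) {
    stop("need at least 3 subjects")
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  if (abs(r) >= 1 - 1e-15) {
    warning("|r| = 1; p-value is 0")
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  }
  list(r = r, df = df, p = p, n = n, k = k)
}

#' Apply log transforms and the practice-hours outlier rule
#'
#' Removes subjects at or above the absolute practice-hours threshold
#' (default 30 h/week, the conventional cutoff for an implausible weekly
#' load), or — with `rule = "iqr"` — beyond 3 interquartile ranges of the
#' quartiles. Natural-log transforms are then applied to the flagged
#' columns, which must be strictly positive.
#'
#' @param table data.frame of per-subject variables (must contain
#'   `subject_id` and, when the outlier rule applies, `practice_hours`).
#' @param logVars character vector of column names to log-transform.
#' @param hoursThreshold absolute exclusion threshold on `practice_hours`
#'   (subjects with `practice_hours >= hoursThreshold` are removed); NA
#'   disables the rule.
#' @param rule `"absolute"` (default) or `"iqr"` (Tukey 3 x IQR fences).
#' @return list with `table` (filtered, transformed) and `excluded`
#'   (data.frame of removed subjects with the reason).
#' @export
applyTransformsAndOutliers <- function(table, logVars = character(),
                                       hoursThreshold = 30,
                                       rule = c("absolute", "iqr")) {
  rule <- match.arg(rule)
  excluded <- data.frame(subject_id = character(), reason = character())
  if (!is.na(hoursThreshold) || rule == "iqr") {
    if (!"practice_hours" %in% names(table)) {
      stop("outlier rule needs a 'practice_hours' column")
    }
    h <- table$practice_hours
    drop <- if (rule == "absolute") {
      if (is.na(hoursThreshold)) rep(FALSE, nrow(table)) else {
        if (hoursThreshold <= 0) stop("'hoursThreshold' must be positive")
        !is.na(h) & h >= hoursThreshold
      }
    } else {
      q <- stats::quantile(h, c(0.25, 0.75), na.rm = TRUE)
      iqr <- q[[2L]] - q[[1L]]
      !is.na(h) & (h > q[[2L]] + 3 * iqr | h < q[[1L]] - 3 * iqr)
    }
    if (any(drop)) {
      excluded <- data.frame(
        subject_id = as.character(table$subject_id[drop]),
        reason = sprintf("practice_hours = %g flagged by %s rule",
          h[drop], rule)
      )
      table <- table[!drop, , drop = FALSE]
    }
  }
  for (v in logVars) {
    if (!v %in% names(table)) stop("no column named '", v, "'")
    bad <- which(!is.na(table[[v]]) & table[[v]] <= 0)
    if (length(bad)) {
      stop(sprintf(
        "cannot log-transform '%s': non-positive value for subject %s",
        v, table$subject_id[bad[[1L]]]
      ))
    }
    table[[v]] <- log(table[[v]])
  }
  list(table = table, excluded = excluded)
}

#' Run a table of partial-correlation associations
#'
#' Convenience wrapper joining per-subject variables: for each (x, y) pair
#' requested, applies the outlier/log rules and computes the partial
#' correlation controlling for the covariates.
#'
#' @param table data.frame of per-subject variables.
#' @param pairs data.frame with columns `x`, `y` naming variables in
#'   `table`; optional `log_x`, `log_y` logical columns.
#' @param covariates character vector of covariate column names (default
#'   gender, age, education).
#' @param hoursThreshold passed to [applyTransformsAndOutliers()]; applied
#'   only when the table has a `practice_hours` column.
#' @param adjust p-value adjustment method (`"none"`, default, or any
#'   method of [stats::p.adjust()], e.g. `"BH"`).
#' @return data.frame: x, y, covariates, n, r, df, p, (p_adjusted),
#'   excluded_subjects.
#' @export
associationTable <- function(table, pairs,
                             covariates = c("gender", "age", "education"),
                             hoursThreshold = 30, adjust = "none") {
  if (!"practice_hours" %in% names(table)) hoursThreshold <- NA
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    xv <- pairs$x[[i]]
    yv <- pairs$y[[i]]
    logs <- c(
      if (isTRUE(pairs$log_x[[i]])) xv,
      if (isTRUE(pairs$log_y[[i]])) yv
    )
    prep <- applyTransformsAndOutliers(table,
      logVars = logs, hoursThreshold = hoursThreshold
    )
    d <- prep$table[, c(xv, yv, covariates), drop = FALSE]
    keep <- stats::complete.cases(d)
    d <- d[keep, , drop = FALSE]
    pc <- partialCorrelation(d[[xv]], d[[yv]], d[, covariates, drop = FALSE])
    data.frame(
      x = xv, y = yv, covariates = paste(covariates, collapse = "+"),
      n = pc$n, r = pc$r, df = pc$df, p = pc$p,
      excluded_subjects = paste(prep$excluded$subject_id, collapse = ";")
    )
  })
  out <- do.call(rbind, rows)
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  }
  out
}
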