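#' Per-symptom endorsement frequencies
#'
#' @param data A [symptom_dataset].
#' @return Named vector of proportions (column means of the binary matrix).
#' @export
symptom_frequencies <- function(data) {
  stopifnot(inherits(data, "symptom_dataset"))
  colMeans(data$matrix)
}

# Firth bias-reduced logistic regression (Jeffreys-prior penalized
# likelihood), used as the fallback under separation. Small and standard:
# modified score U*(b) = X'(y - p + h (1/2 - p)), h = hat diagonals.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    Wv <- p * (1 - p)
    XW <- X * Wv
    info <- crossprod(X, XW)
    h <- rowSums((X %*% solve(info)) * XW)
    score <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, se = sqrt(diag(solve(info))))
}

#' Severity-adjusted symptom frequency comparison
#'
#' For each symptom, fits a multiple logistic regression of symptom presence
#' on a group indicator plus the participant's total symptom count (the
#' severity adjustment), and reports the group odds ratio with a 95% Wald
#' confidence interval and two-sided p-value. By default the adjustment
#' count excludes the modeled symptom, avoiding a deterministic component;
#' `adjust = "include"` uses the raw total. Under (quasi-)separation the fit
#' falls back to Firth bias-reduced penalized likelihood with a warning.
#'
#' @param data_a,data_b Two [symptom_dataset]s with identical labels; the
#'   odds ratio is for membership in `data_b` relative to `data_a`.
#' @param adjust `"exclude"` (default) or `"include"`: whether the symptom
#'   count covariate includes the modeled symptom.
#' @param conf_level Confidence level of the Wald interval.
#' @return Data frame of class `frequency_comparison` with columns
#'   `symptom`, `freq_a`, `freq_b`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `method`.
#' @export
adjusted_comparison <- function(data_a, data_b,
                                adjust = c("exclude", "include"),
                                conf_level = 0.95) {
  stopifnot(inherits(data_a, "symptom_dataset"),
            inherits(data_b, "symptom_dataset"))
  if (!identical(data_a$labels, data_b$labels))
    stop("both datasets must share the same symptom labels and ordering")
  adjust <- match.arg(adjust)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  m <- rbind(data_a$matrix, data_b$matrix)
  grp <- rep(c(0, 1), c(data_a$n, data_b$n))
  total <- rowSums(m)

  rows <- lapply(seq_along(data_a$labels), function(j) {
    y <- m[, j]
    count <- if (adjust == "exclude") total - y else total
    method <- "ml"
    fit <- suppressWarnings(
      stats::glm(y ~ grp + count, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    b <- stats::coef(fit)[["grp"]]
    se <- sqrt(diag(stats::vcov(fit)))[["grp"]]
    mu <- stats::fitted(fit)
    separated <- !fit$converged || abs(b) > 15 || se > 50 ||
      any(mu < 1e-8) || any(mu > 1 - 1e-8)
    if (separated) {
      warning("possible separation for symptom '", data_a$labels[j],
              "'; using Firth bias-reduced fit")
      method <- "firth"
      ff <- firth_logistic(cbind(1, grp, count), y)
      b <- ff$coef[2]
      se <- ff$se[2]
    }
    data.frame(symptom = data_a$labels[j],
               freq_a = mean(data_a$matrix[, j]),
               freq_b = mean(data_b$matrix[, j]),
               odds_ratio = exp(b),
               ci_low = exp(b - zq * se),
               ci_high = exp(b + zq * se),
               p_value = 2 * stats::pnorm(-abs(b / se)),
               method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("frequency_comparison", "data.frame")
  out
}

#' Write a frequency comparison table as CSV
#'
#' @param table A `frequency_comparison`.
#' @param path Output path.
#' @export
write_frequency_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
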