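#' Rater score matrix
#'
#' Subjects in rows, raters in columns; integer severity scores in 0..6,
#' no missing cells.
#'
#' @param x numeric matrix (or coercible) of scores.
#' @param subjects,raters optional label vectors.
#' @return a validated numeric matrix of class \code{rater_matrix}.
#' @export
rater_matrix <- function(x, subjects = NULL, raters = NULL) {
  x <- as.matrix(x)
  check_that(nrow(x) >= 2L && ncol(x) >= 2L,
             "rater_matrix: need at least 2 subjects and 2 raters")
  check_that(!anyNA(x), "rater_matrix: missing cells are not allowed")
  check_that(all(x >= 0 & x <= 6), "rater_matrix: scores must lie in [0, 6]")
  rownames(x) <- subjects %||% rownames(x) %||% paste0("S", seq_len(nrow(x)))
  colnames(x) <- raters %||% colnames(x) %||% paste0("R", seq_len(ncol(x)))
  class(x) <- c("rater_matrix", class(x))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a rater matrix as CSV
#'
#' Comma-separated, UTF-8, header row of rater labels, first column of
#' subject labels.
#' @param path CSV file path.
#' @param x a [rater_matrix()].
#' @export
read_rater_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rater_matrix(as.matrix(df[, -1, drop = FALSE]), subjects = df[[1]])
}

#' @rdname read_rater_matrix
#' @export
write_rater_matrix <- function(x, path) {
  df <- data.frame(subject = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Two-way ANOVA mean squares for a subjects x raters matrix, via
# stats::aov on the crossed factors (rows = subjects, columns = raters).
anova_mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(value = as.vector(x),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  list(msr = ms[["subject"]], msc = ms[["rater"]], mse = ms[["Residuals"]],
       n = n, k = k)
}

#' Intraclass correlation coefficient with confidence interval
#'
#' Two-way ANOVA ICC in the Shrout-Fleiss / McGraw-Wong formulary, for
#' rows = subjects (random) and columns = raters. Supported models:
#' \describe{
#'   \item{two_way_random_absolute_single}{ICC(2,1) / ICC(A,1): raters a
#'     random sample, absolute agreement, single measurement — the
#'     default for inter-rater reliability of a single rating.}
#'   \item{two_way_random_absolute_average}{ICC(2,k) / ICC(A,k):
#'     reliability of the k-rater average.}
#'   \item{two_way_consistency_single}{ICC(3,1) / ICC(C,1): consistency,
#'     ignoring systematic rater offsets.}
#' }
#' Confidence bounds use the standard F-based constructions for each
#' model. A matrix with zero variance everywhere (all cells identical)
#' has an undefined ICC: the estimate is \code{NA} with
#' \code{undefined = TRUE}, not an error.
#'
#' @param x a [rater_matrix()] or plain matrix.
#' @param model one of the three model strings above.
#' @param alpha 1 - confidence level (default 0.05 for a 95\% CI).
#' @return a list: \code{icc}, \code{ci_low}, \code{ci_high},
#'   \code{icc_model}, \code{undefined}.
#' @export
icc <- function(x, model = c("two_way_random_absolute_single",
                             "two_way_random_absolute_average",
                             "two_way_consistency_single"),
                alpha = 0.05) {
  model <- match.arg(model)
  x <- as.matrix(x)
  check_that(nrow(x) >= 2L && ncol(x) >= 2L, "icc: degenerate matrix dimensions")
  check_that(!anyNA(x), "icc: missing cells are not allowed")
  if (stats::var(as.vector(x)) == 0) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                icc_model = model, undefined = TRUE))
  }
  ms <- anova_mean_squares(x)
  n <- ms$n; k <- ms$k; msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  est <- switch(model,
    two_way_random_absolute_single =
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    two_way_random_absolute_average =
      (msr - mse) / (msr + (msc - mse) / n),
    two_way_consistency_single =
      (msr - mse) / (msr + (k - 1) * mse))
  ci <- icc_confint(model, est, msr, msc, mse, n, k, alpha)
  list(icc = est, ci_low = ci[1], ci_high = ci[2], icc_model = model,
       undefined = FALSE)
}

# F-based confidence bounds (Shrout & Fleiss 1979; McGraw & Wong 1996).
icc_confint <- function(model, est, msr, msc, mse, n, k, alpha) {
  single_absolute_ci <- function(r) {
    if (mse == 0) return(c(1, 1))  # perfect agreement: interval collapses
    fj <- msc / mse
    a <- k * r / (n * (1 - r)); b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * fj + b)^2 / (a^2 * fj^2 / (k - 1) + b^2 / (n - 1))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    c(lower, upper)
  }
  ci <- switch(model,
    two_way_random_absolute_single = single_absolute_ci(est),
    two_way_random_absolute_average = {
      r1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
      s <- single_absolute_ci(r1)
      k * s / (1 + (k - 1) * s)  # Spearman-Brown step-up of the single bounds
    },
    two_way_consistency_single = {
      if (mse == 0) c(1, 1) else {
        fo <- msr / mse
        fl <- fo / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
        fu <- fo * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
        c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
      }
    })
  pmin(pmax(ci, -1), 1)
}

# All permutations of 1..n as an n! x n matrix (iterative insertion).
all_permutations <- function(n) {
  perms <- matrix(1L, 1, 1)
  for (m in 2:n) {
    out <- matrix(0L, nrow(perms) * m, m)
    row <- 0L
    for (i in seq_len(nrow(perms))) {
      for (pos in seq_len(m)) {
        row <- row + 1L
        out[row, ] <- append(perms[i, ], m, after = pos - 1L)
      }
    }
    perms <- out
  }
  perms
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of average (tie-adjusted) ranks. The
#' two-sided p-value against rho = 0 is computed by full enumeration of
#' the n! rank permutations for n <= 9 — exact even in the presence of
#' ties — and by the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 degrees of
#' freedom otherwise. A constant input vector leaves rho undefined
#' (\code{undefined = TRUE}).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a list: \code{rho}, \code{p}, \code{method} ("exact" or
#'   "t_approx"), \code{undefined}.
#' @export
spearman_rank <- function(x, y) {
  check_that(length(x) == length(y), "spearman_rank: x and y lengths differ")
  n <- length(x)
  check_that(n >= 3L, "spearman_rank: need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, method = "none", undefined = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    obs <- abs(sum(cx * cy))
    perms <- all_permutations(n)
    # row i holds cx in permuted order; %*% cy gives the permuted products
    stat <- abs(as.vector(matrix(cx[perms], nrow(perms)) %*% cy))
    p <- mean(stat >= obs - 1e-12 * denom)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t_approx"
  }
  list(rho = rho, p = p, method = method, undefined = FALSE)
}

#' Simulate noisy ordinal raters
#'
#' Each rater independently reports the true 0-6 score perturbed by
#' plus or minus one point with probability \code{error_prob} (direction
#' equiprobable), clipped to [0, 6]. Deterministic given the seed.
#'
#' @param true_scores integer vector of true scores in 0..6.
#' @param n_raters number of raters (columns).
#' @param error_prob per-cell perturbation probability in [0, 1].
#' @param seed integer seed.
#' @return a [rater_matrix()].
#' @export
simulate_raters <- function(true_scores, n_raters, error_prob, seed) {
  check_that(error_prob >= 0 && error_prob <= 1,
             "simulate_raters: error_prob must lie in [0, 1]")
  check_that(all(true_scores >= 0 & true_scores <= 6),
             "simulate_raters: true scores must lie in [0, 6]")
  n <- length(true_scores)
  m <- with_seed(seed, {
    perturb <- stats::runif(n * n_raters) < error_prob
    direction <- sample(c(-1L, 1L), n * n_raters, replace = TRUE)
    matrix(rep(as.integer(true_scores), n_raters) + perturb * direction,
           nrow = n, ncol = n_raters)
  })
  m <- pmin(pmax(m, 0L), 6L)
  rater_matrix(m, subjects = paste0("S", seq_len(n)),
               raters = paste0("R", seq_len(n_raters)))
}

#' Combined agreement statistics
#'
#' The study-style analysis in one call: inter-rater ICC on the score
#' matrix, and Spearman correlation between the per-subject mean rater
#' score (arithmetic mean, possibly fractional) and a companion
#' continuous measure such as a calcium score.
#'
#' @param raters a [rater_matrix()].
#' @param calcium numeric vector, one value per subject.
#' @param icc_model passed to [icc()].
#' @param alpha passed to [icc()].
#' @return a list: the [icc()] fields plus \code{rho}, \code{rho_p}.
#' @export
agreement_stats <- function(raters, calcium,
                            icc_model = "two_way_random_absolute_single",
                            alpha = 0.05) {
  check_that(length(calcium) == nrow(raters),
             "agreement_stats: calcium length must equal subject count")
  ic <- icc(raters, model = icc_model, alpha = alpha)
  sp <- spearman_rank(rowMeans(raters), calcium)
  c(ic, list(rho = sp$rho, rho_p = sp$p, rho_method = sp$method))
}
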