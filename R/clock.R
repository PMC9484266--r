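## Mitotic epigenetic clock: cumulative stem-cell division estimates
## from methylation gains at clock CpGs, and derived division rates.

#' Expected clock-CpG methylation after T divisions
#'
#' Under the per-division gain model, a clock CpG with ground-state
#' methylation `delta` and per-division gain probability `p` has
#' expected methylation `delta + (1 - delta) * (1 - (1 - p)^T)` after
#' `T` cumulative divisions.
#'
#' @param model A [clock_model()].
#' @param T_div Cumulative division count (scalar).
#' @return Expected beta per clock CpG.
#' @export
clock_expected_beta <- function(model, T_div) {
  stopifnot(inherits(model, "clock_model"), T_div >= 0)
  model$delta + (1 - model$delta) * (1 - (1 - model$p)^T_div)
}

#' Per-CpG closed-form inversion of the clock model
#'
#' Diagnostic inverse: `T_i = log(1 - (beta_i - delta_i)+ / (1 -
#' delta_i)) / log(1 - p_i)`, with negative gains clamped to zero.
#' Saturated CpGs (`beta = 1`) invert to `Inf`.
#'
#' @param beta_values Observed beta per clock CpG.
#' @param model A [clock_model()] aligned to `beta_values`.
#' @return Per-CpG division estimates.
#' @export
clock_invert <- function(beta_values, model) {
  gain <- pmax(beta_values - model$delta, 0) / (1 - model$delta)
  log(1 - gain) / log(1 - model$p)
}

#' Estimate mitotic age per sample
#'
#' For each sample, minimizes the sum of squared deviations between
#' observed clock-CpG beta values and the model curve over `T >= 0`
#' (bounded one-dimensional optimization). When every observed beta
#' lies at or below its ground state the estimate is 0 and flagged as
#' floor-reached.
#'
#' @param beta_clock A [beta_matrix()] restricted to clock CpGs
#'   (rownames must match `model$cpg_id`).
#' @param model A [clock_model()].
#' @param min_cpgs Minimum non-missing clock CpGs per sample
#'   (default 10).
#' @return A `mitotic_age` data.frame: `sample_id`, `T_hat`,
#'   `residual` (root mean squared deviation), `n_cpgs`,
#'   `floor_reached`.
#' @export
fit_mitotic_age <- function(beta_clock, model, min_cpgs = 10) {
  stopifnot(inherits(model, "clock_model"))
  x <- beta_clock$values
  idx <- match(rownames(x), model$cpg_id)
  if (anyNA(idx)) stop("clock parameters missing for some probes")
  mod <- model[idx, ]
  out <- data.frame(sample_id = colnames(x), T_hat = NA_real_,
                    residual = NA_real_, n_cpgs = NA_integer_,
                    floor_reached = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x))) {
    b <- x[, j]
    use <- !is.na(b)
    if (sum(use) < min_cpgs)
      stop("sample ", colnames(x)[j], " has fewer than ", min_cpgs,
           " usable clock CpGs")
    bj <- b[use]; dj <- mod$delta[use]; pj <- mod$p[use]
    out$n_cpgs[j] <- sum(use)
    if (all(bj <= dj)) {
      out$T_hat[j] <- 0
      out$floor_reached[j] <- TRUE
      out$residual[j] <- sqrt(mean((bj - dj)^2))
      next
    }
    ## bracket from the per-CpG inversions
    ti <- log(1 - pmax(bj - dj, 0) / (1 - dj)) / log(1 - pj)
    upper <- 2 * max(ti[is.finite(ti)], 1) + 10
    sse <- function(T_div) {
      mu <- dj + (1 - dj) * (1 - (1 - pj)^T_div)
      sum((bj - mu)^2)
    }
    opt <- optimize(sse, c(0, upper), tol = 1e-8)
    ## Newton polish of the bounded search (analytic derivatives)
    T_hat <- opt$minimum
    lq <- log(1 - pj)
    for (it in 1:30) {
      q_T <- (1 - pj)^T_hat
      mu <- dj + (1 - dj) * (1 - q_T)
      mu1 <- -(1 - dj) * q_T * lq
      mu2 <- mu1 * lq
      g <- sum(2 * (mu - bj) * mu1)
      h <- sum(2 * (mu1^2 + (mu - bj) * mu2))
      if (!is.finite(g) || !is.finite(h) || h <= 0) break
      step <- g / h
      T_new <- max(0, T_hat - step)
      if (sse(T_new) <= sse(T_hat)) T_hat <- T_new
      if (abs(step) < 1e-10 * max(1, T_hat)) break
    }
    out$T_hat[j] <- T_hat
    out$residual[j] <- sqrt(sse(T_hat) / sum(use))
  }
  class(out) <- c("mitotic_age", "data.frame")
  out
}

#' Stem-cell division rate
#'
#' Divides each sample's estimated cumulative divisions by its
#' chronological age; a group's division rate is summarized by the
#' median over its samples (robust to the right-skew of mitotic ages).
#'
#' @param estimate A `mitotic_age` table from [fit_mitotic_age()].
#' @param age_years Named numeric vector of chronological ages.
#' @param groups Optional named group per sample; when given, a
#'   `group_scdr` median summary is attached.
#' @return Named per-sample rates (divisions per stem cell and year);
#'   with `groups`, a list with `scdr` and `group_scdr`.
#' @export
scdr <- function(estimate, age_years, groups = NULL) {
  stopifnot(inherits(estimate, "mitotic_age"))
  ages <- age_years[estimate$sample_id]
  if (anyNA(ages)) stop("ages missing for some samples")
  if (any(ages <= 0)) stop("ages must be positive")
  rates <- setNames(estimate$T_hat / ages, estimate$sample_id)
  if (is.null(groups)) return(rates)
  g <- groups[names(rates)]
  list(scdr = rates,
       group_scdr = tapply(rates, g, median))
}
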