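#' Luria-Delbruck probability mass function (Ma-Sandri-Sarkar recursion)
#'
#' Probabilities of observing `0..k_max` mutant colonies in a culture when the
#' expected number of mutations per culture is `m`, under the classical
#' Luria-Delbruck model with exponential growth and no differential mutant
#' fitness:
#' \deqn{p_0 = e^{-m}, \qquad p_k = \frac{m}{k} \sum_{i=0}^{k-1}
#'   \frac{p_i}{k-i+1}.}
#'
#' @param m Expected mutations per culture (> 0).
#' @param k_max Largest mutant count to evaluate.
#' @return Numeric vector of length `k_max + 1`, `p[k+1] = P(K = k)`.
#' @examples
#' ld_pmf(1, 5)
#' @export
ld_pmf <- function(m, k_max) {
  .ld_pmf_cpp(m, as.integer(k_max))
}

#' Ma-Sandri-Sarkar maximum-likelihood estimate of m
#'
#' Maximizes the Luria-Delbruck log-likelihood of the per-culture mutant
#' counts over `log(m)` by bracketed 1-D optimization. Counts at or above
#' `k_cap` are pooled into a single tail class whose probability is
#' `1 - sum(p_0..p_{k_cap-1})`, which stabilizes jackpot cultures without
#' materially distorting the likelihood.
#'
#' @param selective_counts Non-negative integer mutant counts, one per culture.
#' @param k_cap Jackpot cap (default `1e4`).
#' @param lower,upper Bracket for `m` (defaults `1e-6`, `1e3`).
#' @param tol Relative tolerance on `log(m)` (default `1e-6`).
#' @return The MLE `m_hat` (numeric). If every count is zero the estimate is
#'   driven to the lower bracket and carries `attr(, "flag") = "zero-count"`.
#' @examples
#' mss_mle(c(0, 1, 0, 3, 25, 2, 0, 1, 4, 0, 2, 1))
#' @export
mss_mle <- function(selective_counts, k_cap = 1e4, lower = 1e-6, upper = 1e3,
                    tol = 1e-6) {
  counts <- as.integer(selective_counts)
  if (length(counts) < 1L || any(counts < 0L)) {
    stop("`selective_counts` must be non-negative integers", call. = FALSE)
  }
  if (all(counts == 0L)) {
    out <- lower
    attr(out, "flag") <- "zero-count"
    return(out)
  }
  k_cap <- as.integer(k_cap)
  capped <- pmin(counts, k_cap)
  kmax_needed <- max(capped[capped < k_cap], 0L)
  any_tail <- any(capped >= k_cap)
  kmax <- if (any_tail) k_cap else kmax_needed

  nll <- function(logm) {
    m <- exp(logm)
    p <- ld_pmf(m, kmax)
    ll <- 0
    body_counts <- capped[capped < k_cap]
    ll <- sum(log(pmax(p[body_counts + 1L], 1e-300)))
    if (any_tail) {
      tail_p <- max(1 - sum(p[seq_len(k_cap)]), 1e-300)
      ll <- ll + sum(capped >= k_cap) * log(tail_p)
    }
    -ll
  }
  opt <- stats::optimize(nll, interval = log(c(lower, upper)), tol = tol)
  exp(opt$minimum)
}

#' Stewart 95% confidence interval for m
#'
#' FALCOR-compatible closed form: the standard deviation of `log(m_hat)` is
#' `1.225 * m_hat^-0.315 / sqrt(C)` and the bounds are
#' `exp(log(m_hat) +/- 1.96 * sigma)`.
#'
#' @param m_hat MSS-MLE estimate of m (> 0).
#' @param C Number of parallel cultures (>= 2).
#' @return Named numeric vector `c(m_low, m_high)`.
#' @export
confidence_interval <- function(m_hat, C) {
  if (m_hat <= 0 || C < 2) {
    stop("parameter error: need m_hat > 0 and C >= 2", call. = FALSE)
  }
  sigma <- 1.225 * m_hat^(-0.315) / sqrt(C)
  c(m_low = exp(log(m_hat) - 1.96 * sigma),
    m_high = exp(log(m_hat) + 1.96 * sigma))
}

#' Final population size from diluted control plates
#'
#' @param control_counts Colony counts from control plates after dilution.
#' @param dilution_factor Fold dilution of the control aliquot (default `1e4`).
#' @param plated_fraction Fraction of the diluted suspension plated (default 1).
#' @return Estimated cells per culture `Nt = mean(counts) * dilution / fraction`.
#'   Zero carries `attr(, "flag") = "invalid"`.
#' @export
estimate_Nt <- function(control_counts, dilution_factor = 1e4,
                        plated_fraction = 1) {
  if (length(control_counts) < 1L) {
    stop("`control_counts` must contain at least one count", call. = FALSE)
  }
  Nt <- mean(control_counts) * dilution_factor / plated_fraction
  if (Nt <= 0) attr(Nt, "flag") <- "invalid"
  Nt
}

#' Construct a fluctuation experiment
#'
#' @param selective_counts Per-culture mutant colony counts on selective plates.
#' @param control_counts Colony counts on diluted non-selective control plates.
#' @param dilution_factor Fold dilution of the control aliquot (default `1e4`).
#' @param plated_fraction_selective Fraction of each culture plated selectively
#'   (default 1: the whole suspension).
#' @param label Experiment label.
#' @return A `fluctuation_experiment` object.
#' @export
fluctuation_experiment <- function(selective_counts, control_counts,
                                   dilution_factor = 1e4,
                                   plated_fraction_selective = 1,
                                   label = "experiment") {
  if (length(selective_counts) < 2L) {
    stop("need at least 2 cultures", call. = FALSE)
  }
  if (dilution_factor < 1) {
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  }
  if (any(selective_counts < 0) || any(control_counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(
    list(selective_counts = as.integer(selective_counts),
         control_counts = as.integer(control_counts),
         dilution_factor = dilution_factor,
         plated_fraction_selective = plated_fraction_selective,
         label = label),
    class = "fluctuation_experiment"
  )
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat("<fluctuation_experiment>", x$label, "- C =",
      length(x$selective_counts), "cultures, dilution",
      format(x$dilution_factor, scientific = TRUE), "\n")
  invisible(x)
}

#' Estimate a mutation rate from a fluctuation experiment
#'
#' Composes the MSS maximum-likelihood estimate of m (with plating
#' correction), the control-plate estimate of the final population size Nt,
#' and the Stewart confidence interval. The rate is `m_hat / Nt` per cell per
#' generation.
#'
#' @param experiment A [fluctuation_experiment()].
#' @param k_cap Jackpot cap passed to [mss_mle()].
#' @return A `ld_rate_estimate`: list with `label`, `m_hat`, `Nt`, `rate`,
#'   `ci_low`, `ci_high` (rate scale), `C` and `flags` (character vector,
#'   possibly empty; `"zero-count"` marks an upper-bound-only estimate).
#' @examples
#' expt <- fluctuation_experiment(c(0, 2, 1, 0, 14, 3, 1, 0, 2, 5, 1, 0),
#'                                control_counts = c(100, 96))
#' tidy(estimate_rate(expt))
#' @export
estimate_rate <- function(experiment, k_cap = 1e4) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  flags <- character(0)

  m_hat <- mss_mle(experiment$selective_counts, k_cap = k_cap)
  if (!is.null(attr(m_hat, "flag"))) flags <- c(flags, attr(m_hat, "flag"))
  m_hat <- as.numeric(m_hat)
  # plating correction: counts reflect the plated fraction of each culture
  pf <- experiment$plated_fraction_selective
  if (pf < 1) m_hat <- m_hat / pf

  Nt <- estimate_Nt(experiment$control_counts, experiment$dilution_factor)
  if (!is.null(attr(Nt, "flag"))) flags <- c(flags, "invalid-Nt")
  Nt <- as.numeric(Nt)

  C <- length(experiment$selective_counts)
  rate <- if (Nt > 0) m_hat / Nt else NA_real_
  ci <- if (m_hat > 0 && Nt > 0) {
    confidence_interval(m_hat, C) / Nt
  } else c(m_low = NA_real_, m_high = NA_real_)

  structure(
    list(label = experiment$label, m_hat = m_hat, Nt = Nt, rate = rate,
         ci_low = unname(ci[1]), ci_high = unname(ci[2]), C = C,
         flags = flags),
    class = "ld_rate_estimate"
  )
}

#' @export
print.ld_rate_estimate <- function(x, ...) {
  cat("<ld_rate_estimate>", x$label, "\n")
  cat(sprintf("  m_hat = %.3g, Nt = %.3g, C = %d\n", x$m_hat, x$Nt, x$C))
  cat(sprintf("  rate = %.3g (95%% CI %.3g - %.3g) per cell per generation\n",
              x$rate, x$ci_low, x$ci_high))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ld_rate_estimate <- function(x, ...) {
  tibble::tibble(label = x$label, m_hat = x$m_hat, Nt = x$Nt, rate = x$rate,
                 ci_low = x$ci_low, ci_high = x$ci_high, C = x$C,
                 flags = paste(x$flags, collapse = ";"))
}

#' @export
glance.ld_rate_estimate <- function(x, ...) {
  tibble::tibble(rate = x$rate, ci_low = x$ci_low, ci_high = x$ci_high,
                 C = x$C)
}
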