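#' Filter genetic instruments by pairwise linkage disequilibrium
#'
#' For every pair of instruments with LD `r2` strictly greater than
#' `r2_cutoff`, the SNP with the larger exposure standard error is dropped
#' (the more precisely instrumented SNP of the pair is kept). Exclusions are
#' reported in the `"exclusions"` attribute.
#'
#' @param stats Tibble `(snp, beta_exp, se_exp, beta_out, se_out)`.
#' @param ld Tibble `(snp_a, snp_b, r2)`; defaults to the `"ld"` attribute of
#'   `stats` if present.
#' @param r2_cutoff LD threshold; a pair exactly at the cutoff is retained.
#' @return Filtered stats tibble with attribute `"exclusions"`.
#' @export
filter_instruments <- function(stats, ld = NULL, r2_cutoff = 0.8) {
  stats <- as_tibble(stats)
  ld <- ld %||% attr(stats, "ld")
  if (is.null(ld) || nrow(ld) == 0) {
    attr(stats, "exclusions") <- tibble(snp = character(), reason = character())
    return(stats)
  }
  ld <- as_tibble(ld)
  if (!all(c(ld$snp_a, ld$snp_b) %in% stats$snp)) {
    abort("LD entries reference unknown SNPs")
  }
  dropped <- character(); reasons <- character()
  for (i in seq_len(nrow(ld))) {
    if (ld$r2[i] <= r2_cutoff) next
    a <- ld$snp_a[i]; b <- ld$snp_b[i]
    if (a %in% dropped || b %in% dropped) next
    se_a <- stats$se_exp[stats$snp == a]
    se_b <- stats$se_exp[stats$snp == b]
    drop <- if (se_a > se_b) a else b
    keep <- setdiff(c(a, b), drop)
    dropped <- c(dropped, drop)
    reasons <- c(reasons, sprintf("r2 = %.3g with %s > cutoff %.3g", ld$r2[i],
                                  keep, r2_cutoff))
  }
  out <- stats[!stats$snp %in% dropped, ]
  attr(out, "exclusions") <- tibble(snp = dropped, reason = reasons)
  attr(out, "ld") <- ld
  out
}

#' Per-SNP Wald ratio estimates
#'
#' The causal effect attributed to one instrument is the ratio of its outcome
#' and exposure effects, `beta = beta_out / beta_exp`, with a first-order
#' delta-method standard error
#' \eqn{\sqrt{se_\Gamma^2/\gamma^2 + \Gamma^2 se_\gamma^2/\gamma^4}}.
#'
#' @param beta_exp,se_exp Exposure effects and SEs (vectorised).
#' @param beta_out,se_out Outcome effects and SEs.
#' @return Tibble `(beta, se)` with one row per SNP.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) abort("undefined instrument: exposure beta is zero")
  tibble(
    beta = beta_out / beta_exp,
    se = sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  )
}

#' Inverse-variance-weighted pooling of per-SNP estimates
#'
#' Fixed-effect IVW: weights are inverse squared standard errors,
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, with a normal 95% CI
#' and two-sided p-value.
#'
#' @param estimates Tibble `(beta, se)` from [wald_ratio()].
#' @return An `mr_estimate` with `beta`, `se`, `ci` (length 2), `p`,
#'   `n_snps`.
#' @export
ivw <- function(estimates) {
  estimates <- as_tibble(estimates)
  if (nrow(estimates) == 0) abort("no estimates to pool")
  w <- 1 / estimates$se^2
  beta <- sum(w * estimates$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(list(
    beta = beta, se = se,
    ci = beta + c(-1, 1) * stats::qnorm(0.975) * se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    n_snps = nrow(estimates)
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("IVW MR estimate (%d instruments): beta = %.4f (SE %.4f), 95%% CI %.4f to %.4f, p = %.3g\n",
              x$n_snps, x$beta, x$se, x$ci[1], x$ci[2], x$p))
  if (!is.null(x$or_scaled)) {
    cat(sprintf("  OR per %s: %.3f (95%% CI %.3f-%.3f)\n", x$or_label,
                x$or_scaled, x$or_ci[1], x$or_ci[2]))
  }
  invisible(x)
}

#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(term = "exposure", estimate = x$beta, std.error = x$se,
         conf.low = x$ci[1], conf.high = x$ci[2], p.value = x$p)
}

#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(beta = x$beta, se = x$se, p = x$p, n_snps = x$n_snps,
         or_scaled = x$or_scaled %||% NA_real_)
}

#' Rescale an MR estimate to an odds ratio per relative exposure change
#'
#' Assumes `beta` is expressed per unit of log-exposure (a convention this
#' package requires and states explicitly: summary statistics must be on, or
#' converted to, the natural-log exposure scale before pooling). A relative
#' change of `change` (e.g. `-0.10` for a 10% decrease) then corresponds to
#' a log-odds shift of `beta * log(1 + change)`, so
#' `OR = exp(beta * log(1 + change))`, with the CI endpoints transformed by
#' the same monotone map (order preserved).
#'
#' @param estimate An [ivw()] result (or any list with `beta`, `ci`).
#' @param change Relative exposure change in (-1, Inf); default `-0.10`.
#' @return The estimate with `or_scaled`, `or_ci`, `or_label` added.
#' @export
scale_to_or <- function(estimate, change = -0.10) {
  if (!is.numeric(change) || change <= -1) abort("`change` must be > -1")
  mult <- log(1 + change)
  or <- exp(estimate$beta * mult)
  ci <- sort(exp(estimate$ci * mult))
  estimate$or_scaled <- or
  estimate$or_ci <- ci
  estimate$or_label <- sprintf("%g%% %s in exposure", abs(change) * 100,
                               if (change < 0) "decrease" else "increase")
  estimate
}

#' Run the full two-sample MR analysis on summary statistics
#'
#' LD-filters instruments, forms per-SNP Wald ratios, pools them by IVW and
#' rescales to an odds ratio for the requested exposure change.
#'
#' @param stats Summary statistics tibble (see [generate_mr_summary()] for
#'   the dialect).
#' @param ld Optional LD pair tibble.
#' @param r2_cutoff LD exclusion threshold.
#' @param change Relative exposure change for the odds ratio.
#' @return An `mr_estimate` with the per-SNP ratios in `$wald` and the LD
#'   exclusion report in `$exclusions`.
#' @export
mr_run <- function(stats, ld = NULL, r2_cutoff = 0.8, change = -0.10) {
  kept <- filter_instruments(stats, ld = ld, r2_cutoff = r2_cutoff)
  ratios <- wald_ratio(kept$beta_exp, kept$se_exp, kept$beta_out, kept$se_out)
  ratios$snp <- kept$snp
  est <- scale_to_or(ivw(ratios), change = change)
  est$wald <- ratios
  est$exclusions <- attr(kept, "exclusions")
  est
}
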