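# Nonparametric bootstrap inference for requirements and bootstrap-based
# post-hoc comparison across production phases.

#' Bootstrap distribution of a nutrient requirement
#'
#' Case-resampling bootstrap: each replicate draws `n` records with
#' replacement, refits the tanh neuron (warm-started at the full-data
#' fit plus one random restart), and computes `Req_p`. Replicates whose
#' refit diverges or whose requirement is invalid (non-saturating curve)
#' are dropped and counted, with their sub-seeds recorded for
#' reproduction. The confidence interval is the percentile interval of
#' the valid replicates (type-7 quantiles), computed only when at least
#' 20 replicates survive. Deterministic given `seed`.
#'
#' @param data,nutrient,response as in [fit_tanh_neuron()].
#' @param n_boot replicates requested (default 100).
#' @param p response fraction (default 0.95).
#' @param ci_level confidence level (default 0.95).
#' @param seed master integer seed; replicate r uses a derived sub-seed.
#' @param control a [tanh_control()] for the full-data fit.
#' @param label statistic label carried through reporting, e.g.
#'   `"req95:dlys:mid"`.
#' @return An object of class `boot_req`: `label`, `replicates` (valid
#'   Req_p values), `param_replicates` (tibble of A, b, c, B, req per
#'   valid replicate), `n_requested`, `n_failed`, `failed_seeds`,
#'   `point_estimate`, `fit`, `ci_level`, `ci` (named lower/upper, or
#'   `NULL`), `p`, `seed`.
#' @export
bootstrap_requirement <- function(data, nutrient,
                                  response = "chicks_per_hen_week",
                                  n_boot = 100, p = 0.95, ci_level = 0.95,
                                  seed = 1L,
                                  control = tanh_control(seed = seed),
                                  label = paste0("req", round(p * 100), ":",
                                                 nutrient)) {
  fit <- fit_tanh_neuron(data, nutrient, response, control)
  point <- requirement_at_fraction(fit$params, p)
  boot <- bootstrap_tanh(data, nutrient, response, fit, n_boot, seed, p)
  reqs <- purrr::map(boot$fits, function(f) requirement_at_fraction(f$params, p))
  valid <- vapply(reqs, function(r) r$valid, logical(1))
  n_invalid <- sum(!valid)
  replicates <- vapply(reqs[valid], function(r) r$req, numeric(1))
  param_replicates <- dplyr::bind_rows(purrr::map2(
    boot$fits[valid], reqs[valid],
    function(f, r) tibble::tibble(A = f$params$A, b = f$params$b,
                                  c = f$params$c, B = f$params$B,
                                  req = r$req)
  ))
  n_failed <- boot$n_failed + n_invalid
  if (n_failed > n_boot / 2) {
    abort(sprintf("Bootstrap failed: %d of %d replicates unusable.",
                  n_failed, n_boot),
          class = "phasereq_inference_error")
  }
  ci <- NULL
  if (length(replicates) >= 20) {
    # canonical percentile-bootstrap endpoints: the (R+1)p order-statistic
    # rule (quantile type 6), as in boot::boot.ci
    ci <- c(
      lower = unname(quantile(replicates, (1 - ci_level) / 2, type = 6)),
      upper = unname(quantile(replicates, (1 + ci_level) / 2, type = 6))
    )
  }
  structure(
    list(label = label, replicates = replicates,
         param_replicates = param_replicates,
         n_requested = as.integer(n_boot), n_failed = as.integer(n_failed),
         failed_seeds = boot$failed_seeds,
         point_estimate = point$req, point = point, fit = fit,
         ci_level = ci_level, ci = ci, p = p, seed = as.integer(seed)),
    class = "boot_req"
  )
}

#' @export
print.boot_req <- function(x, ...) {
  cat(sprintf("Bootstrap requirement [%s]: point %.4g", x$label,
              x$point_estimate))
  if (!is.null(x$ci)) {
    cat(sprintf(", %g%% CI [%.4g, %.4g]", 100 * x$ci_level,
                x$ci["lower"], x$ci["upper"]))
  }
  cat(sprintf("\n  %d/%d replicates valid (%d failed)\n",
              length(x$replicates), x$n_requested, x$n_failed))
  invisible(x)
}

#' @export
tidy.boot_req <- function(x, ...) {
  tibble::tibble(
    label = x$label, p = x$p, req = x$point_estimate,
    ci_lo = if (is.null(x$ci)) NA_real_ else x$ci[["lower"]],
    ci_hi = if (is.null(x$ci)) NA_real_ else x$ci[["upper"]],
    n_replicates = length(x$replicates), n_failed = x$n_failed
  )
}

#' Bootstrap post-hoc comparison of two phases' requirements
#'
#' Pairs replicate i of `dist_a` with replicate i of `dist_b`
#' (truncating to the shorter vector; the phases use disjoint data, so
#' index pairing is one valid pairing that keeps the test
#' deterministic) and forms the difference distribution. The two-sided
#' resampling p-value is `2 * min(P(diff <= 0), P(diff >= 0))` with the
#' `(count + 1)/(R + 1)` correction, floored at `2/(R + 1)` and capped
#' at 1.
#'
#' @param dist_a,dist_b [bootstrap_requirement()] results with at least
#'   20 valid replicates each.
#' @param threshold significance threshold, default 0.05.
#' @return A one-row tibble: `a`, `b`, `diff` (point estimates),
#'   `mean_diff` (replicate mean), `n_diff`, `p_value`, `significant`;
#'   the replicate differences are attached as attribute
#'   `diff_replicates`.
#' @export
compare_phases <- function(dist_a, dist_b, threshold = 0.05) {
  stopifnot(inherits(dist_a, "boot_req"), inherits(dist_b, "boot_req"))
  R <- min(length(dist_a$replicates), length(dist_b$replicates))
  if (R < 20) {
    abort("Need at least 20 valid replicates in each distribution.",
          class = "phasereq_inference_error")
  }
  d <- dist_a$replicates[seq_len(R)] - dist_b$replicates[seq_len(R)]
  p_lo <- (sum(d <= 0) + 1) / (R + 1)
  p_hi <- (sum(d >= 0) + 1) / (R + 1)
  p_value <- min(2 * min(p_lo, p_hi), 1)
  out <- tibble::tibble(
    a = dist_a$label, b = dist_b$label,
    diff = dist_a$point_estimate - dist_b$point_estimate,
    mean_diff = mean(d), n_diff = R,
    p_value = p_value, significant = p_value < threshold
  )
  attr(out, "diff_replicates") <- d
  out
}

#' Compact letter display for phase comparisons
#'
#' Standard insert-and-absorb construction: groups not significantly
#' different share a letter; letters are assigned in descending order
#' of point estimate.
#'
#' @param comparisons data frame with columns `a`, `b`, `significant`
#'   (rows of [compare_phases()] bound together), covering every pair.
#' @param estimates named numeric vector of point estimates, one per
#'   group label appearing in `comparisons`.
#' @return A tibble with columns `group`, `estimate`, `letters`.
#' @export
#' @examples
#' cmp <- tibble::tibble(a = c("early", "early", "mid"),
#'                       b = c("mid", "late", "late"),
#'                       significant = c(TRUE, TRUE, FALSE))
#' letter_display(cmp, c(early = 453.4, mid = 448.9, late = 448.3))
letter_display <- function(comparisons, estimates) {
  groups <- names(sort(estimates, decreasing = TRUE))
  sets <- list(groups)
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    pair <- c(sig$a[i], sig$b[i])
    for (k in rev(seq_along(sets))) {
      if (all(pair %in% sets[[k]])) {
        s <- sets[[k]]
        sets[[k]] <- NULL
        sets <- c(sets, list(setdiff(s, pair[1])), list(setdiff(s, pair[2])))
      }
    }
    sets <- Filter(length, sets)
    # absorb sets contained in another
    keep <- vapply(seq_along(sets), function(k) {
      !any(vapply(seq_along(sets), function(j) {
        j != k && all(sets[[k]] %in% sets[[j]]) &&
          (length(sets[[j]]) > length(sets[[k]]) || j < k)
      }, logical(1)))
    }, logical(1))
    sets <- sets[keep]
  }
  # order letters by the highest-estimate member of each set
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  letters_of <- vapply(groups, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = groups,
                 estimate = unname(estimates[groups]),
                 letters = unname(letters_of))
}
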