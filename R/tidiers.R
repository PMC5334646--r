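#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the volume-cell-number fit
#'
#' @param x a `spheroid_volume_fit`.
#' @param ... unused.
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy spheroid_volume_fit
#' @export
tidy.spheroid_volume_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "cell_number"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.spheroid_volume_fit
#' @return `glance()`: a one-row tibble with `slope`, `intercept`,
#'   `pearson_r`, `r.squared`, `sigma` and `nobs`.
#' @method glance spheroid_volume_fit
#' @export
glance.spheroid_volume_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r, r.squared = s$r.squared,
                 sigma = s$sigma, nobs = length(s$residuals))
}

#' Tidy a centroid match result
#'
#' @param x a `match_result`.
#' @param ... unused.
#' @return A one-row tibble with counts and the derived detection metrics.
#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) {
  cbind(tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, n_gt = x$n_gt,
                       n_sc = x$n_sc, match_radius = x$match_radius),
        compute_metrics(x))
}
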