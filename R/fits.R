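# regression-result container shared by the fitting helpers

new_ejection_fit <- function(tag, estimate, se, window, n, resid_norm,
                             r_squared) {
  if (!all(is.finite(se))) abort("non-finite standard errors in fit.")
  structure(list(tag = tag, estimate = estimate, se = se, window = window,
                 n = n, resid_norm = resid_norm, r_squared = r_squared),
            class = "ejection_fit")
}

#' @export
print.ejection_fit <- function(x, ...) {
  cat("<ejection_fit:", x$tag, "> n =", x$n, "\n")
  for (nm in names(x$estimate))
    cat(sprintf("  %-14s %10.5g  (se %.3g)\n", nm, x$estimate[[nm]],
                x$se[[nm]]))
  if (!is.null(x$window))
    cat("  window:", paste(signif(x$window, 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Tidy and summarise fit results
#'
#' `tidy()` returns one row per fitted parameter with its 1-sigma standard
#' error from the regression covariance; `glance()` returns one-row model
#' summaries.
#'
#' @param x an `ejection_fit`.
#' @param ... unused.
#' @return a tibble.
#' @importFrom generics tidy glance
#' @method tidy ejection_fit
#' @export
tidy.ejection_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(x$se))
}

#' @rdname tidy.ejection_fit
#' @method glance ejection_fit
#' @export
glance.ejection_fit <- function(x, ...) {
  tibble::tibble(model = x$tag, nobs = x$n, r.squared = x$r_squared,
                 deviance = x$resid_norm^2)
}

#' @rdname tidy.ejection_fit
#' @method glance stage_times
#' @export
glance.stage_times <- function(x, ...) {
  dplyr::summarise(x, dplyr::across(dplyr::starts_with("tau"),
                                    ~ mean(.x, na.rm = TRUE)),
                   n_runs = dplyr::n())
}

#' @export
generics::tidy

#' @export
generics::glance
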