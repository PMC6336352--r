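#' Hill-type dose-response curve
#'
#' Sigmoid curve in log dose used for the proliferation (MTT absorbance)
#' readouts:
#' \deqn{y = y_0 + a\,\frac{(\ln x - c)^n}{(\ln x - c)^n + b^n},}
#' evaluable for `ln(x) > c`. The saturating fraction is computed as
#' `1 / (1 + exp(n (ln b - ln(ln x - c))))`, which stays finite for the very
#' large Hill exponents this assay produces.
#'
#' @param y0 Baseline absorbance.
#' @param a Amplitude.
#' @param b Half-saturation constant on the shifted log-dose axis.
#' @param c Log-dose offset.
#' @param n Hill exponent (> 0).
#' @return An object of class `hill_curve`.
#' @examples
#' hc <- hill_curve(0.349, 0.449, 20.802, -23.309, 11.149)
#' predict(hc, dose = c(0.01, 0.1, 1, 10))
#' @export
hill_curve <- function(y0, a, b, c, n) {
  check_number(y0, "y0"); check_number(a, "a")
  check_number(b, "b", lower = 1e-12)
  check_number(c, "c"); check_number(n, "n", lower = 1e-12)
  structure(list(y0 = y0, a = a, b = b, c = c, n = n),
            class = "hill_curve")
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("<hill_curve> y0 = %.4g, a = %.4g, b = %.4g, c = %.4g, n = %.4g\n",
              x$y0, x$a, x$b, x$c, x$n))
  invisible(x)
}

hill_eval <- function(dose, y0, a, b, c, n) {
  u <- log(dose) - c
  out <- rep(y0, length(dose))
  ok <- u > 0
  out[ok] <- y0 + a / (1 + exp(n * (log(b) - log(u[ok]))))
  out
}

#' @param object A `hill_curve`.
#' @param dose Doses (ng/ml) at which to evaluate.
#' @param ... Unused.
#' @rdname hill_curve
#' @export
predict.hill_curve <- function(object, dose, ...) {
  hill_eval(dose, object$y0, object$a, object$b, object$c, object$n)
}

#' Joint Hill fit to two dose-response groups with a shared baseline
#'
#' Least-squares fit of [hill_curve()] models to a reference and a mutant
#' dose-response data set, with the baseline `y0` shared across groups and
#' `(a, b, c, n)` fitted per group — one joint optimisation, not two
#' independent fits. Multi-start `nlminb` minimisation over a documented grid
#' of starting values ((`n` in {2, 10, 30}) x (offset `c` at 1, 5 and 20 log
#' units below the smallest log dose)), with `n` bounded in (0, 50].
#'
#' @param data A data frame with columns `dose` (positive, ng/ml),
#'   `absorbance` and `group` (exactly two levels).
#' @param ref,mut Group labels of the reference and mutant arms; default to
#'   the first and second level encountered.
#' @param n_max Upper bound on the Hill exponent (default 50).
#' @return An object of class `hill_fit`: list with `curves` (named list of
#'   two `hill_curve`s), `coef` tibble, `rss`, `n_obs`, `convergence` and the
#'   data.
#' @examples
#' dat <- generate_dose_response(noise_sd = 0, seed = 1)
#' fit <- fit_hill(dat)
#' tidy(fit)
#' @export
fit_hill <- function(data, ref = NULL, mut = NULL, n_max = 50) {
  stopifnot(all(c("dose", "absorbance", "group") %in% names(data)))
  if (any(data$dose <= 0)) abort("doses must be positive (log transform)")
  groups <- unique(as.character(data$group))
  if (length(groups) != 2) abort("`data$group` must have exactly two levels")
  if (is.null(ref)) ref <- groups[1]
  if (is.null(mut)) mut <- setdiff(groups, ref)[1]
  d_ref <- data[data$group == ref, ]
  d_mut <- data[data$group == mut, ]
  if (length(unique(d_ref$dose)) < 5 || length(unique(d_mut$dose)) < 5) {
    abort("need >= 5 distinct doses per group")
  }
  lx_min <- min(log(data$dose))
  rng <- range(data$absorbance)
  # theta = (y0, then per group: a, log b, c, log n)
  unpack <- function(th) {
    list(y0 = th[1],
         ref = list(a = th[2], b = exp(th[3]), c = th[4], n = exp(th[5])),
         mut = list(a = th[6], b = exp(th[7]), c = th[8], n = exp(th[9])))
  }
  rss_fn <- function(th) {
    p <- unpack(th)
    if (p$ref$c >= lx_min || p$mut$c >= lx_min) return(1e10)
    r1 <- d_ref$absorbance -
      hill_eval(d_ref$dose, p$y0, p$ref$a, p$ref$b, p$ref$c, p$ref$n)
    r2 <- d_mut$absorbance -
      hill_eval(d_mut$dose, p$y0, p$mut$a, p$mut$b, p$mut$c, p$mut$n)
    sum(r1^2) + sum(r2^2)
  }
  amp <- max(rng[2] - rng[1], 1e-3)
  starts <- list()
  for (n0 in c(2, 10, 30)) {
    for (off in c(1, 5, 20)) {
      c0 <- lx_min - off
      b0 <- stats::median(log(data$dose)) - c0
      starts[[length(starts) + 1]] <-
        c(rng[1], amp, log(max(b0, 0.5)), c0, log(n0),
          amp, log(max(b0, 0.5)), c0, log(n0))
    }
  }
  lower <- c(-Inf, 0, log(1e-3), -1e3, log(1e-2),
             0, log(1e-3), -1e3, log(1e-2))
  upper <- c(Inf, Inf, log(1e3), lx_min - 1e-6, log(n_max),
             Inf, log(1e3), lx_min - 1e-6, log(n_max))
  fits <- lapply(starts, function(st) {
    tryCatch(
      nlminb(st, rss_fn, lower = lower, upper = upper,
             control = list(iter.max = 2000, eval.max = 4000)),
      error = function(e) NULL
    )
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$objective), fits)
  if (length(fits) == 0) abort("Hill fit failed to converge from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  p <- unpack(best$par)
  curves <- list(
    hill_curve(p$y0, p$ref$a, p$ref$b, p$ref$c, p$ref$n),
    hill_curve(p$y0, p$mut$a, p$mut$b, p$mut$c, p$mut$n)
  )
  names(curves) <- c(ref, mut)
  coef_tbl <- dplyr::bind_rows(lapply(names(curves), function(g) {
    cv <- curves[[g]]
    tibble(group = g, y0 = cv$y0, a = cv$a, b = cv$b, c = cv$c, n = cv$n)
  }))
  structure(
    list(curves = curves, coef = coef_tbl, rss = best$objective,
         n_obs = nrow(d_ref) + nrow(d_mut),
         convergence = best$convergence, data = as_tibble(data),
         ref = ref, mut = mut),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> shared-baseline joint fit\n")
  print(x$coef)
  cat(sprintf("RSS = %.5g on %d observations\n", x$rss, x$n_obs))
  invisible(x)
}

#' Tidy and summarise Hill fits
#'
#' `tidy()` returns one row per group/parameter; `glance()` a one-row model
#' summary.
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tidyr::pivot_longer(x$coef, c("y0", "a", "b", "c", "n"),
                      names_to = "term", values_to = "estimate")
}

#' @rdname tidy.hill_fit
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$rss, n_obs = x$n_obs,
         sigma = sqrt(x$rss / max(x$n_obs - 9, 1)),
         convergence = x$convergence)
}

#' Plot a Hill fit
#'
#' Raw absorbances and fitted curves on a log dose axis.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  doses <- exp(seq(log(min(object$data$dose)), log(max(object$data$dose)),
                   length.out = 200))
  fit_df <- dplyr::bind_rows(lapply(names(object$curves), function(g) {
    tibble(group = g, dose = doses,
           absorbance = predict(object$curves[[g]], doses))
  }))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$dose, .data$absorbance,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fit_df) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "G-CSF dose (ng/ml)", y = "absorbance (600 nm)",
                  colour = NULL)
}

#' Dose at which two Hill curves cross
#'
#' Root of `curve1 - curve2` inside `bracket`, found with [stats::uniroot()].
#'
#' @param curve1,curve2 `hill_curve` objects.
#' @param bracket Dose interval to search (ng/ml).
#' @return Crossing dose in ng/ml.
#' @examples
#' c1 <- hill_curve(0.349, 0.449, 20.802, -23.309, 11.149)
#' c2 <- hill_curve(0.349, 0.479, 21.075, -23.278, 28.255)
#' crossing_concentration(c1, c2) # ~0.1 ng/ml
#' @export
crossing_concentration <- function(curve1, curve2, bracket = c(0.01, 10)) {
  stopifnot(inherits(curve1, "hill_curve"), inherits(curve2, "hill_curve"))
  f <- function(x) predict(curve1, x) - predict(curve2, x)
  v <- c(f(bracket[1]), f(bracket[2]))
  if (any(!is.finite(v)) || prod(sign(v)) >= 0) {
    abort("curves do not cross (no sign change) inside the bracket")
  }
  uniroot(f, interval = bracket, tol = 1e-8)$root
}

#' One-sided rank tests on dose-split strata
#'
#' Wilcoxon two-sample rank tests of mutant vs reference absorbances,
#' performed separately above and at-or-below a dose threshold: above the
#' threshold the alternative is mutant > reference; at or below it,
#' reference > mutant. Exact p-values are used when there are no ties;
#' with ties, midranks with the normal approximation and no continuity
#' correction (so two identical samples give p = 0.5 by convention).
#'
#' @param data Data frame with columns `dose`, `absorbance`, `group`.
#' @param threshold Dose split point in ng/ml (default 0.1).
#' @param ref,mut Group labels (defaults as in [fit_hill()]).
#' @return A tibble with one row per stratum: `stratum`, `n_ref`, `n_mut`,
#'   `statistic`, `p_value`, `alternative`.
#' @examples
#' dat <- generate_dose_response(seed = 1)
#' split_rank_test(dat)
#' @export
split_rank_test <- function(data, threshold = 0.1, ref = NULL, mut = NULL) {
  stopifnot(all(c("dose", "absorbance", "group") %in% names(data)))
  groups <- unique(as.character(data$group))
  if (is.null(ref)) ref <- groups[1]
  if (is.null(mut)) mut <- setdiff(groups, ref)[1]
  one_stratum <- function(keep, x_group, y_group, label, alt_label) {
    x <- data$absorbance[keep & data$group == x_group]
    y <- data$absorbance[keep & data$group == y_group]
    if (length(x) < 3 || length(y) < 3) {
      abort(sprintf("stratum '%s' has fewer than 3 points per group", label))
    }
    ties <- anyDuplicated(c(x, y)) > 0
    if (ties && length(unique(c(x, y))) == 1L) {
      # all observations identical: define p = 0.5 (documented convention)
      return(tibble(stratum = label, n_ref = length(y), n_mut = length(x),
                    statistic = length(x) * length(y) / 2, p_value = 0.5,
                    alternative = alt_label))
    }
    wt <- if (ties) {
      suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                   exact = FALSE, correct = FALSE))
    } else {
      wilcox.test(x, y, alternative = "greater")
    }
    tibble(stratum = label, n_ref = length(y), n_mut = length(x),
           statistic = unname(wt$statistic), p_value = wt$p.value,
           alternative = alt_label)
  }
  bind_rows(
    one_stratum(data$dose > threshold, mut, ref,
                sprintf("dose > %g", threshold), "mutant > reference"),
    one_stratum(data$dose <= threshold, ref, mut,
                sprintf("dose <= %g", threshold), "reference > mutant")
  )
}
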