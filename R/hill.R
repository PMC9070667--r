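#' Hill binding isotherm
#'
#' Fraction bound at protein concentration `conc` under the Hill model
#' `f = f_low + (f_high - f_low) * conc^n / (Kd^n + conc^n)`, monotone
#' non-decreasing in `conc` for `f_high > f_low`.
#'
#' @param conc concentration vector (same units as `Kd`), >= 0.
#' @param Kd dissociation constant, > 0.
#' @param hill_n Hill coefficient, > 0.
#' @param f_low,f_high baseline and plateau fraction bound.
#' @return fraction bound at each concentration.
#' @examples
#' hill_model(1.8, Kd = 1.8)  # half-maximal at conc = Kd
#' @export
hill_model <- function(conc, Kd, hill_n = 1, f_low = 0, f_high = 1) {
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (Kd <= 0) stop("Kd must be positive", call. = FALSE)
  if (hill_n <= 0) stop("hill_n must be positive", call. = FALSE)
  r <- (conc / Kd)^hill_n
  f_low + (f_high - f_low) * r / (1 + r)
}

#' Serial-dilution concentration design
#'
#' `c_i = top / ratio^(i-1)` for `i = 1..n_points`; the defaults give the
#' standard 16-point 3:1 dilution from 5 uM used in thermophoresis
#' titrations.
#'
#' @param top highest concentration (uM), > 0.
#' @param ratio dilution ratio, > 1.
#' @param n_points number of points, >= 2.
#' @return numeric vector of concentrations, descending.
#' @export
dilution_series <- function(top = 5, ratio = 3, n_points = 16) {
  if (top <= 0) stop("top must be positive", call. = FALSE)
  if (ratio <= 1) stop("ratio must be greater than 1", call. = FALSE)
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  top / ratio^(seq_len(n_points) - 1)
}

#' Fit a Hill model to a titration series
#'
#' Bounded Levenberg-Marquardt least squares ([minpack.lm::nls.lm()]) from a
#' deterministic initializer: `Kd0` is the concentration whose response is
#' nearest half-maximal, the Hill coefficient starts at 1, and the
#' baseline/plateau start at the observed extremes. A small deterministic
#' multi-start over Hill-coefficient starting values guards against
#' boundary-pinned local minima; the lowest residual sum of squares wins.
#' By default the baseline and plateau are fitted rather than pinned at 0/1
#' because fraction-bound normalisation of real titrations is imperfect;
#' any of the non-`Kd` parameters can be held fixed (e.g. `fix_f_low = 0`,
#' `fix_f_high = 1` for perfectly normalised synthetic data). `hill_n` is
#' bounded to `[0.3, 4]` and boundary-pinned parameters are flagged. With a
#' `replicate_id` column containing several replicates, each replicate is
#' fitted separately and `Kd` is aggregated as mean +/- SD across replicates
#' (see [fit_hill_replicates()]).
#'
#' @param series data frame with columns `concentration` (uM, > 0) and
#'   `fraction_bound`, optionally `replicate_id`; at least 5 points per fit.
#' @param fix_n fix the Hill coefficient at this value instead of fitting it
#'   (`NULL`, the default, fits it).
#' @param fix_f_low,fix_f_high fix the baseline / plateau instead of fitting
#'   them (`NULL` fits them).
#' @param bounds named list overriding the default box constraints
#'   (`Kd`, `hill_n`, `f_low`, `f_high`, each `c(lower, upper)`).
#' @return an object of class `hill_fit` (or `hill_fit_set` when several
#'   replicates are supplied): coefficients `Kd`, `hill_n`, `f_low`,
#'   `f_high`, their standard errors, a `converged` flag, and quality flags
#'   (`unidentifiable`, `boundary_pinned`, `kd_outside_range`).
#' @export
fit_hill <- function(series, fix_n = NULL, fix_f_low = NULL,
                     fix_f_high = NULL, bounds = NULL) {
  stopifnot(is.data.frame(series),
            all(c("concentration", "fraction_bound") %in% names(series)))
  if ("replicate_id" %in% names(series) &&
      length(unique(series$replicate_id)) > 1L) {
    return(fit_hill_replicates(series, fix_n = fix_n, fix_f_low = fix_f_low,
                               fix_f_high = fix_f_high, bounds = bounds))
  }
  conc <- series$concentration
  fb <- series$fraction_bound
  if (length(conc) < 5L) {
    stop("at least 5 concentration points are required", call. = FALSE)
  }
  if (any(conc <= 0)) stop("concentrations must be positive for fitting",
                           call. = FALSE)
  b <- list(Kd = c(min(conc) / 100, max(conc) * 1000),
            hill_n = c(0.3, 4),
            f_low = c(-0.2, 1.2),
            f_high = c(-0.2, 1.2))
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  fixed <- c(Kd = NA_real_, hill_n = if (is.null(fix_n)) NA_real_ else fix_n,
             f_low = if (is.null(fix_f_low)) NA_real_ else fix_f_low,
             f_high = if (is.null(fix_f_high)) NA_real_ else fix_f_high)
  free <- names(fixed)[is.na(fixed)]
  flags <- character(0)

  # deterministic initializer
  f_low0 <- if (is.na(fixed["f_low"])) min(fb) else fixed[["f_low"]]
  f_high0 <- if (is.na(fixed["f_high"])) max(fb) else fixed[["f_high"]]
  half <- (f_low0 + f_high0) / 2
  Kd0 <- conc[which.min(abs(fb - half))]
  Kd0 <- min(max(Kd0, b$Kd[1]), b$Kd[2])
  n0 <- if (is.na(fixed["hill_n"])) 1 else fixed[["hill_n"]]
  init <- c(Kd = Kd0, hill_n = n0, f_low = f_low0, f_high = f_high0)

  if (stats::sd(fb) < 1e-8 || (max(fb) - min(fb)) < 0.05) {
    flags <- c(flags, "unidentifiable")
    return(new_hill_fit(c(Kd = NA_real_, init[-1]),
                        se = rep(NA_real_, 4), converged = FALSE,
                        flags = flags, series = series, fix_n = fix_n))
  }

  start_rss <- sum((fb - hill_model(conc, init["Kd"], init["hill_n"],
                                    init["f_low"], init["f_high"]))^2)
  resid_fn <- function(par) {
    full <- fixed
    full[free] <- par
    fb - hill_model(conc, full[["Kd"]], full[["hill_n"]],
                    full[["f_low"]], full[["f_high"]])
  }
  lower <- vapply(free, function(p) b[[p]][1], numeric(1))
  upper <- vapply(free, function(p) b[[p]][2], numeric(1))
  one_fit <- function(start_free) {
    tryCatch(minpack.lm::nls.lm(
      par = pmin(pmax(start_free, lower), upper),
      lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  # deterministic multi-start over Hill-coefficient starting values (when
  # free): the box-constrained objective has boundary-pinned local minima
  n_starts <- if (is.na(fixed["hill_n"])) c(n0, 0.5, 2) else n0
  fits <- list()
  for (ns in n_starts) {
    st <- init
    st["hill_n"] <- ns
    cand <- one_fit(st[free])
    if (!inherits(cand, "error") && cand$info %in% 1:4) {
      fits[[length(fits) + 1L]] <- cand
    }
  }
  if (length(fits) == 0L) {
    flags <- c(flags, "non_convergence")
    return(new_hill_fit(c(Kd = NA_real_, init[-1]),
                        se = rep(NA_real_, 4), converged = FALSE,
                        flags = flags, series = series, fix_n = fix_n))
  }
  fit <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  coefs <- fixed
  coefs[free] <- fit$par
  ses <- c(Kd = NA_real_, hill_n = NA_real_, f_low = NA_real_,
           f_high = NA_real_)
  ses[free] <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                        error = function(e) rep(NA_real_, length(free)))
  tol <- 1e-6
  pinned <- vapply(free, function(p) {
    coefs[[p]] <= b[[p]][1] + abs(b[[p]][1]) * tol + tol ||
      coefs[[p]] >= b[[p]][2] - abs(b[[p]][2]) * tol - tol
  }, logical(1))
  if (any(pinned)) flags <- c(flags, "boundary_pinned")
  if (coefs[["Kd"]] < min(conc) * 0.999 || coefs[["Kd"]] > max(conc) * 1.001) {
    flags <- c(flags, "kd_outside_range")
  }
  new_hill_fit(coefs, ses, converged = TRUE, flags = flags,
               series = series, fix_n = fix_n,
               rss = stats::deviance(fit), start_rss = start_rss,
               start = init)
}

new_hill_fit <- function(coefs, se, converged, flags, series, fix_n,
                         rss = NA_real_, start_rss = NA_real_, start = NULL) {
  names(coefs) <- c("Kd", "hill_n", "f_low", "f_high")
  names(se) <- names(coefs)
  fitted <- if (!is.na(coefs["Kd"])) {
    hill_model(series$concentration, coefs["Kd"], coefs["hill_n"],
               coefs["f_low"], coefs["f_high"])
  } else rep(NA_real_, nrow(series))
  structure(list(coefficients = coefs, se = se, converged = converged,
                 flags = flags, series = series, fix_n = fix_n,
                 fitted = fitted,
                 residuals = series$fraction_bound - fitted,
                 rss = rss, start_rss = start_rss, start = start,
                 call = sys.call(-1)),
            class = "hill_fit")
}

#' Fit Hill models per replicate and aggregate
#'
#' Fits each replicate separately and aggregates the dissociation constant
#' as mean +/- SD across converged replicate fits, the convention for
#' titrations repeated in at least three independent experiments.
#'
#' @inheritParams fit_hill
#' @return an object of class `hill_fit_set`: list with `fits` (per
#'   replicate), `Kd_mean`, `Kd_sd`, `n_replicates`.
#' @export
fit_hill_replicates <- function(series, fix_n = NULL, fix_f_low = NULL,
                                fix_f_high = NULL, bounds = NULL) {
  stopifnot("replicate_id" %in% names(series))
  reps <- split(series, series$replicate_id)
  fits <- lapply(reps, function(s) {
    s$replicate_id <- NULL
    fit_hill(s, fix_n = fix_n, fix_f_low = fix_f_low,
             fix_f_high = fix_f_high, bounds = bounds)
  })
  kds <- vapply(fits, function(f) {
    if (f$converged) unname(f$coefficients["Kd"]) else NA_real_
  }, numeric(1))
  ok <- !is.na(kds)
  structure(list(fits = fits,
                 Kd_mean = if (any(ok)) mean(kds[ok]) else NA_real_,
                 Kd_sd = if (sum(ok) > 1) stats::sd(kds[ok]) else NA_real_,
                 n_replicates = length(fits),
                 n_converged = sum(ok)),
            class = "hill_fit_set")
}

#' @export
print.hill_fit <- function(x, digits = 3, ...) {
  cat("Hill binding fit\n")
  if (x$converged) {
    cat(sprintf("  Kd = %.*g +/- %.*g, hill_n = %.*g, f_low = %.*g, f_high = %.*g\n",
                digits, x$coefficients["Kd"], digits, x$se["Kd"],
                digits, x$coefficients["hill_n"],
                digits, x$coefficients["f_low"],
                digits, x$coefficients["f_high"]))
  } else {
    cat("  did not converge\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, std_error = object$se)
  out <- list(coefficients = tab, converged = object$converged,
              flags = object$flags, rss = object$rss,
              n_points = nrow(object$series))
  class(out) <- "summary.hill_fit"
  out
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat("Hill fit on", x$n_points, "points; converged:", x$converged, "\n")
  print(x$coefficients)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  cat("residual sum of squares:", format(x$rss), "\n")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
fitted.hill_fit <- function(object, ...) object$fitted

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$series$concentration else newdata$concentration
  cf <- object$coefficients
  hill_model(conc, cf["Kd"], cf["hill_n"], cf["f_low"], cf["f_high"])
}

#' @export
plot.hill_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$concentration, s$fraction_bound, log = "x",
                 xlab = "concentration (uM)", ylab = "fraction bound", ...)
  if (x$converged) {
    cg <- exp(seq(log(min(s$concentration)), log(max(s$concentration)),
                  length.out = 200))
    graphics::lines(cg, predict(x, data.frame(concentration = cg)))
  }
  invisible(x)
}

#' @export
print.hill_fit_set <- function(x, digits = 3, ...) {
  cat(sprintf("Hill fits over %d replicate(s) (%d converged): Kd = %.*g +/- %.*g\n",
              x$n_replicates, x$n_converged, digits, x$Kd_mean, digits, x$Kd_sd))
  invisible(x)
}

#' @export
coef.hill_fit_set <- function(object, ...) {
  c(Kd_mean = object$Kd_mean, Kd_sd = object$Kd_sd)
}

#' Read / write titration series
#'
#' TSV with columns `replicate_id`, `concentration` (uM) and
#' `fraction_bound`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_titration <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("concentration", "fraction_bound")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("titration table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tab
}

#' @rdname read_titration
#' @param series titration data frame.
#' @export
write_titration <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
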