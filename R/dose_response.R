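#' @importFrom stats coef aggregate
#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

#' Four-parameter logistic response
#'
#' \eqn{y = bottom + (top - bottom) / (1 + (x / ic50)^{hill})}. With a
#' positive hill slope the response decreases with concentration (a
#' viability curve); at \code{x = ic50} the response is the midpoint
#' \code{(top + bottom) / 2}.
#'
#' @param x concentration(s), > 0.
#' @param bottom,top asymptotes.
#' @param hill slope.
#' @param ic50 midpoint concentration.
#' @return response value(s).
#' @export
fourPL <- function(x, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Validate a dose-response table
#'
#' Long-format viability data: one row per measured well with columns
#' \code{cell_line}, \code{concentration} (molar, > 0) and \code{response}
#' (luminescence, arbitrary units). At least 4 distinct concentrations with
#' at least one replicate each are required per cell line.
#'
#' @param table a data.frame.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
validateDoseResponseTable <- function(table) {
  need <- c("cell_line", "concentration", "response")
  miss <- setdiff(need, colnames(table))
  if (length(miss))
    stop("dose-response table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(table$concentration)) || any(table$concentration <= 0))
    stop("concentrations must be finite and positive")
  if (any(!is.finite(table$response)))
    stop("responses must be finite")
  for (cl in unique(table$cell_line)) {
    nconc <- length(unique(table$concentration[table$cell_line == cl]))
    if (nconc < 4L)
      stop("cell line '", cl, "' has only ", nconc,
           " distinct concentrations (>= 4 required)")
  }
  table
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on the log-concentration scale
#' (\code{minpack.lm::nlsLM}), initialized from the data: bottom and top
#' from the extreme per-concentration mean responses, IC50 from the
#' concentration whose mean response is nearest the half-maximum, hill
#' slope 1. On failure the optimizer is restarted from 3 perturbed
#' initializations before the fit is declared non-converged. The result is
#' canonicalized to \code{top >= bottom} (flipping the hill sign, which
#' leaves the curve unchanged); IC50 is the midpoint parameter (relative
#' EC50 convention).
#'
#' @param table long-format data.frame for ONE cell line (see
#'   \code{\link{validateDoseResponseTable}}).
#' @param normalizeToMax divide responses by the largest per-concentration
#'   mean before fitting (default FALSE: raw responses are fitted).
#' @return a \linkS4class{DoseResponseFit}.
#' @export
fit4PL <- function(table, normalizeToMax = FALSE) {
  table <- validateDoseResponseTable(table)
  cl <- unique(as.character(table$cell_line))
  if (length(cl) > 1L)
    stop("fit4PL expects a single cell line; got: ", paste(cl, collapse = ", "))
  x <- table$concentration
  y <- table$response
  if (var(y) == 0) stop("responses are constant; no curve can be fitted")
  means <- aggregate(y, list(conc = x), mean)
  if (normalizeToMax) {
    sc <- max(means$x)
    y <- y / sc
    means$x <- means$x / sc
  }
  b0 <- min(means$x); t0 <- max(means$x)
  half <- (b0 + t0) / 2
  ic0 <- means$conc[which.min(abs(means$x - half))]
  df <- data.frame(lx = log(x), y = y)
  tryFit <- function(start) {
    tryCatch(
      nlsLM(y ~ bottom + (top - bottom) / (1 + exp(hill * (lx - lic50))),
            data = df, start = start,
            control = nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  starts <- list(list(bottom = b0, top = t0, hill = 1, lic50 = log(ic0)))
  pert <- c(0.5, 2, 4)
  for (f in pert)
    starts <- c(starts, list(list(bottom = b0, top = t0, hill = 1,
                                  lic50 = log(ic0 * f))))
  fit <- NULL
  for (s in starts) {
    fit <- tryFit(s)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(new("DoseResponseFit", bottom = NA_real_, top = NA_real_,
               hill = NA_real_, ic50 = NA_real_, sse = NA_real_,
               converged = FALSE, se = setNames(numeric(), character()),
               cellLine = cl))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  bottom <- cf[["bottom"]]; top <- cf[["top"]]
  hill <- cf[["hill"]]; icv <- exp(cf[["lic50"]])
  if (top < bottom) {          # equivalent curve with swapped asymptotes
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  new("DoseResponseFit", bottom = bottom, top = top, hill = hill,
      ic50 = icv, sse = sum(residuals(fit)^2), converged = TRUE,
      se = c(bottom = unname(se[["bottom"]]), top = unname(se[["top"]]),
             hill = unname(se[["hill"]]), lic50 = unname(se[["lic50"]])),
      cellLine = cl)
}

#' Compare IC50 estimates across cell lines
#'
#' Orders converged fits by ascending IC50 (ties broken by cell line id)
#' and reports fold differences against the most sensitive line.
#' Non-converged fits are excluded with a warning; at least 2 converged
#' fits are required.
#'
#' @param fits list of \linkS4class{DoseResponseFit} objects.
#' @return data.frame with columns \code{cell_line}, \code{ic50},
#'   \code{fold_vs_min}.
#' @export
ic50Compare <- function(fits) {
  ok <- vapply(fits, function(f) f@converged, TRUE)
  if (any(!ok))
    warning(sum(!ok), " non-converged fit(s) excluded: ",
            paste(vapply(fits[!ok], function(f) f@cellLine, ""), collapse = ", "))
  fits <- fits[ok]
  if (length(fits) < 2L)
    stop("at least 2 converged fits are required (got ", length(fits), ")")
  df <- data.frame(
    cell_line = vapply(fits, function(f) f@cellLine, ""),
    ic50 = vapply(fits, function(f) f@ic50, 1))
  df <- df[order(df$ic50, df$cell_line), , drop = FALSE]
  df$fold_vs_min <- df$ic50 / df$ic50[[1L]]
  rownames(df) <- NULL
  df
}
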