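#' Normalise reaction rates to assay controls
#'
#' `(raw - min_control) / (max_control - min_control)`: 1 at the
#' no-competitor maximum, 0 at the no-kinase minimum.
#'
#' @param raw numeric vector of raw rates.
#' @param max_control rate with no competitor peptide.
#' @param min_control rate with no kinase.
#' @return normalised rates.
#' @export
normalize_rates <- function(raw, max_control, min_control) {
  if (max_control <= min_control)
    stop("max_control must exceed min_control")
  (raw - min_control) / (max_control - min_control)
}

## four-parameter logistic on concentration c (h > 0 means inhibition)
fpl <- function(c, top, bottom, ic50, h) {
  bottom + (top - bottom) / (1 + (c / ic50)^h)
}

fit_4pl_once <- function(conc, rate, bottom_fixed = NULL) {
  pos <- conc > 0   # zero-concentration points anchor only the controls
  cc <- conc[pos]
  rr <- rate[pos]
  if (length(unique(cc)) < 4)
    stop("need >= 4 distinct non-zero concentrations")
  o <- order(cc)
  cc <- cc[o]; rr <- rr[o]
  top0 <- mean(rr[cc <= quantile(cc, 0.25)])
  bot0 <- mean(rr[cc >= quantile(cc, 0.75)])
  half <- (top0 + bot0) / 2
  cross <- which(diff(sign(rr - half)) != 0)
  ic0 <- if (length(cross) > 0) sqrt(cc[cross[1]] * cc[cross[1] + 1])
         else exp(mean(log(cc)))
  lc <- log10(cc)
  fit <- tryCatch({
    if (is.null(bottom_fixed)) {
      minpack.lm::nlsLM(
        rr ~ bottom + (top - bottom) / (1 + 10^(h * (lc - lic))),
        start = list(top = top0, bottom = bot0, lic = log10(ic0), h = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        rr ~ bottom_fixed + (top - bottom_fixed) / (1 + 10^(h * (lc - lic))),
        start = list(top = top0, lic = log10(ic0), h = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit))
    return(list(ok = FALSE, flag = "no_convergence", ic50 = NA_real_,
                hill = NA_real_, top = NA_real_, bottom = NA_real_))
  p <- coef(fit)
  ic50 <- 10^p[["lic"]]
  bottom <- if (is.null(bottom_fixed)) p[["bottom"]] else bottom_fixed
  flag <- "ok"
  if (ic50 < min(cc) || ic50 > max(cc)) flag <- "ic50_outside_range"
  # a negative Hill slope or inverted asymptotes both mean the signal rises
  # with dose: not a competitive-inhibition curve
  if (p[["h"]] <= 0 || p[["top"]] < bottom) flag <- "no_inhibition"
  list(ok = flag == "ok", flag = flag, ic50 = ic50, hill = p[["h"]],
       top = p[["top"]], bottom = bottom)
}

#' Fit a competitive-inhibition dose-response curve
#'
#' Fits the four-parameter logistic
#' `y = bottom + (top - bottom) / (1 + (c / IC50)^h)` to each replicate by
#' nonlinear least squares on a log10 concentration grid (all four parameters
#' free by default; `bottom_fixed = 0` gives the 3PL variant).
#' Zero-concentration points enter only the normalisation, never the logistic
#' fit. The reported IC50 is the mean of the replicate IC50s with a
#' t-distribution 95% confidence interval across replicates. Fits whose IC50
#' falls outside the tested range, or that do not converge, or whose Hill
#' slope indicates no inhibition, are flagged (reported, not dropped).
#'
#' @param data data.frame with columns `concentration` (uM) and `rate`
#'   (normalised), and optionally `replicate`.
#' @param bottom_fixed fix the lower asymptote (e.g. 0), or `NULL` to fit it.
#' @param conf confidence level for the across-replicate interval.
#' @return a `fit_result`: `ic50`, `ci` (length 2), `hill`, `top`, `bottom`
#'   (replicate means), `n_replicates`, `converged`, `flags`, `replicates`
#'   (per-replicate data.frame).
#' @export
fit_ic50 <- function(data, bottom_fixed = NULL, conf = 0.95) {
  if (!all(c("concentration", "rate") %in% names(data)))
    stop("data needs 'concentration' and 'rate' columns")
  if (any(data$concentration < 0)) stop("concentrations must be >= 0")
  if (all(data$concentration == data$concentration[1]))
    stop("concentrations must not all be equal")
  if (is.null(data$replicate)) data$replicate <- 1L
  reps <- lapply(split(data, data$replicate), function(d)
    fit_4pl_once(d$concentration, d$rate, bottom_fixed))
  rdf <- data.frame(replicate = names(reps),
                    ic50 = vapply(reps, `[[`, numeric(1), "ic50"),
                    hill = vapply(reps, `[[`, numeric(1), "hill"),
                    top = vapply(reps, `[[`, numeric(1), "top"),
                    bottom = vapply(reps, `[[`, numeric(1), "bottom"),
                    flag = vapply(reps, `[[`, character(1), "flag"),
                    row.names = NULL)
  flags <- unique(rdf$flag[rdf$flag != "ok"])
  if (length(flags) > 0)
    warning("flagged replicate fit(s): ", paste(flags, collapse = ", "),
            call. = FALSE)
  ok <- !is.na(rdf$ic50)
  ic <- rdf$ic50[ok]
  nrep <- sum(ok)
  mean_ic <- if (nrep > 0) mean(ic) else NA_real_
  ci <- if (nrep >= 2) {
    half <- qt(1 - (1 - conf) / 2, nrep - 1) * sd(ic) / sqrt(nrep)
    c(mean_ic - half, mean_ic + half)
  } else c(NA_real_, NA_real_)
  fit_result(ic50 = mean_ic, ci = ci,
             hill = mean(rdf$hill[ok]), top = mean(rdf$top[ok]),
             bottom = mean(rdf$bottom[ok]), n_replicates = nrep,
             converged = nrep > 0 && all(rdf$flag == "ok"),
             flags = flags, replicates = rdf)
}

#' Construct a dose-response fit result
#'
#' Also usable directly for published IC50 summaries (mean and 95% CI) when
#' the raw points are unavailable, so that [fold_change()] can operate on
#' printed tables.
#'
#' @param ic50 IC50 (uM).
#' @param ci length-2 confidence interval on the IC50 (uM).
#' @param hill,top,bottom curve parameters (optional).
#' @param n_replicates number of replicate fits behind the summary.
#' @param converged logical.
#' @param flags character vector of quality flags.
#' @param replicates optional per-replicate data.frame.
#' @return a `fit_result` object.
#' @export
fit_result <- function(ic50, ci = c(NA_real_, NA_real_), hill = NA_real_,
                       top = NA_real_, bottom = NA_real_, n_replicates = 3L,
                       converged = TRUE, flags = character(0),
                       replicates = NULL) {
  if (!is.na(ic50) && ic50 <= 0) stop("IC50 must be > 0")
  if (!anyNA(ci) && !is.na(ic50) && (ci[1] > ic50 || ci[2] < ic50))
    stop("CI must bracket the IC50")
  if (converged && !is.na(bottom) && !is.na(top) && bottom > top)
    stop("bottom must not exceed top")
  structure(list(ic50 = ic50, ci = ci, hill = hill, top = top,
                 bottom = bottom, n_replicates = n_replicates,
                 converged = converged, flags = flags,
                 replicates = replicates),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("IC50 = %.3g uM (95%% CI %.3g-%.3g, n = %d)%s\n", x$ic50,
              x$ci[1], x$ci[2], x$n_replicates,
              if (!x$converged) paste0("  [flagged: ",
                                       paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

## standard error of log(ic50) recovered from a t-based CI across replicates
log_se_from_fit <- function(fit) {
  if (anyNA(fit$ci) || fit$n_replicates < 2) return(NA_real_)
  tq <- qt(0.975, fit$n_replicates - 1)
  (log(fit$ci[2]) - log(fit$ci[1])) / (2 * tq)
}

#' IC50 fold change between two fits
#'
#' Ratio `IC50_B / IC50_A` (conventionally mutant over wild type, so a value
#' above 1 means the mutant binds more weakly) with a delta-method confidence
#' interval on the log scale. Flagged input fits propagate their flags.
#'
#' @param fit_a,fit_b `fit_result` objects (A is the reference).
#' @return list with `ratio`, `ci`, `flagged`.
#' @export
#' @examples
#' fold_change(fit_result(5.4, c(4.8, 6.2)), fit_result(220, c(198, 253)))
fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "fit_result"), inherits(fit_b, "fit_result"))
  ratio <- fit_b$ic50 / fit_a$ic50
  se <- sqrt(log_se_from_fit(fit_a)^2 + log_se_from_fit(fit_b)^2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_)
        else ratio * exp(c(-1, 1) * 1.96 * se)
  list(ratio = ratio, ci = ci,
       flagged = !fit_a$converged || !fit_b$converged)
}
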