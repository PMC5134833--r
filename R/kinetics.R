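# Inhibition rate laws and global nonlinear fitting.
#
# Three models, as used for product-tripeptide inhibition of the protease:
#   fractional dose response  vi/v0 = 1 / (1 + [I]/IC50)
#   global noncompetitive     v = Vmax[S] / ([S](1+[I]/Kii) + Km(1+[I]/Ki))
#   Yonetani-Theorell         1/vij = (1/v0)(1 + [I]/Ki + [J]/Kj
#                                            + [I][J] beta/(Ki Kj))
# with beta = 1/alpha; beta = 0 is exact mutual exclusivity (alpha = Inf),
# never a large finite sentinel.

#' Fractional velocity under simple dose-response inhibition
#'
#' @param I inhibitor concentration(s), >= 0.
#' @param ic50 half-inhibitory concentration, > 0.
#' @return vi/v0 in (0, 1].
#' @examples
#' ic50Fraction(c(0, 150, 450), ic50 = 150)  # 1, 0.5, 0.25
#' @export
ic50Fraction <- function(I, ic50) {
    if (any(ic50 <= 0)) stop("ic50 must be positive")
    if (any(I < 0)) stop("inhibitor concentrations must be nonnegative")
    1 / (1 + I / ic50)
}

#' Noncompetitive-inhibition rate law
#'
#' The inhibitor binds free enzyme (dissociation constant \code{ki}) and
#' the enzyme-substrate complex (\code{kii}); at I = 0 the law reduces to
#' the Michaelis-Menten form.
#'
#' @param S,I substrate and inhibitor concentrations, >= 0 (vectorized).
#' @param vmax,km,ki,kii rate-law parameters, > 0.
#' @return initial velocity.
#' @export
noncompetitiveRate <- function(S, I, vmax, km, ki, kii) {
    if (any(c(vmax, km, ki, kii) <= 0))
        stop("all rate-law parameters must be positive")
    if (any(S < 0) || any(I < 0))
        stop("concentrations must be nonnegative")
    vmax * S / (S * (1 + I / kii) + km * (1 + I / ki))
}

#' Yonetani-Theorell double-inhibition rate law
#'
#' Reciprocal form with interaction parameter beta = 1/alpha: the cross
#' term vanishes at beta = 0 (mutually exclusive binding, parallel lines
#' of 1/v against I) and equals the independent-sites case at beta = 1.
#'
#' @param I,J concentrations of the two inhibitors, >= 0 (vectorized).
#' @param v0 uninhibited velocity, > 0.
#' @param ki,kj dissociation constants, > 0.
#' @param beta interaction parameter, >= 0.
#' @return initial velocity.
#' @export
yonetaniTheorellRate <- function(I, J, v0, ki, kj, beta = 0) {
    if (any(c(v0, ki, kj) <= 0)) stop("v0, ki, kj must be positive")
    if (beta < 0) stop("beta must be nonnegative")
    if (any(I < 0) || any(J < 0))
        stop("concentrations must be nonnegative")
    v0 / (1 + I / ki + J / kj + beta * I * J / (ki * kj))
}

check_cols <- function(data, cols) {
    miss <- setdiff(cols, names(data))
    if (length(miss))
        stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
    if (any(vapply(cols, function(cc) any(data[[cc]] < 0), TRUE)))
        stop("concentrations and velocities must be nonnegative")
}

r_squared <- function(obs, fitted) {
    1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2)
}

aicc <- function(rss, n, k) {
    # gaussian log-likelihood criterion with small-sample correction;
    # k counts the variance as one estimated parameter
    k <- k + 1
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the fractional dose-response model
#'
#' Least-squares fit of \code{v = v0 / (1 + I/ic50)} with both parameters
#' free and positivity enforced through log parameterization.
#'
#' @param data data.frame with columns \code{I} and \code{v}.
#' @return an [Ic50Fit-class].
#' @export
fitIC50 <- function(data) {
    check_cols(data, c("I", "v"))
    if (length(unique(data$I)) < 4L)
        stop("need at least 4 distinct inhibitor concentrations")
    if (stats::sd(data$v) == 0)
        stop("degenerate dataset: all velocities identical")
    v00 <- max(data$v)
    half <- data$I[which.min(abs(data$v - v00 / 2))]
    ic0 <- if (half > 0) half else stats::median(data$I[data$I > 0])
    fit <- minpack.lm::nlsLM(
        v ~ exp(lv0) / (1 + I / exp(lic)), data = data,
        start = list(lv0 = log(v00), lic = log(ic0)),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12, ptol = 1e-12))
    cf <- stats::coef(fit)
    pred <- stats::fitted(fit)
    new("Ic50Fit", ic50 = unname(exp(cf["lic"])),
        v0 = unname(exp(cf["lv0"])),
        r2 = r_squared(data$v, pred), rss = sum((data$v - pred)^2))
}

#' Globally fit the noncompetitive-inhibition model
#'
#' One simultaneous least-squares fit across the whole [S] x [I] grid,
#' log-parameterized, with a small multi-start schedule on Km and the
#' inhibition constants.
#'
#' @param data data.frame with columns \code{S}, \code{I}, \code{v}.
#' @return a [NoncompetitiveFit-class].
#' @export
fitNoncompetitive <- function(data) {
    check_cols(data, c("S", "I", "v"))
    if (length(unique(data$S)) < 3L)
        stop("non-identifiable design: need >= 3 distinct substrate ",
             "concentrations")
    if (length(unique(data$I)) < 3L)
        stop("non-identifiable design: need >= 3 distinct inhibitor ",
             "concentrations")
    vmax0 <- max(data$v) * 1.2
    km0 <- stats::median(data$S)
    ki0 <- stats::median(data$I[data$I > 0])
    predict_nc <- function(par)
        exp(par[1]) * data$S /
            (data$S * (1 + data$I / exp(par[4])) +
             exp(par[2]) * (1 + data$I / exp(par[3])))
    best <- NULL
    # the kii >> ki corner (near-competitive data) needs a start with a
    # weak ES-complex interaction, hence the large factors
    for (fk in c(1, 0.2, 5)) for (fi in c(1, 0.2, 5, 100)) {
        fit <- tryCatch(minpack.lm::nls.lm(
            par = c(log(vmax0), log(km0 * fk), log(ki0 * fi),
                    log(ki0 * fi)),
            fn = function(par) data$v - predict_nc(par),
            control = minpack.lm::nls.lm.control(maxiter = 500,
                                                 ftol = 1e-13,
                                                 ptol = 1e-13)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(fit$fvec^2)
        if (is.null(best) || rss < best$rss)
            best <- list(fit = fit, rss = rss)
    }
    if (is.null(best)) stop("noncompetitive fit failed to converge")
    cf <- exp(best$fit$par)
    pred <- predict_nc(best$fit$par)
    new("NoncompetitiveFit",
        vmax = cf[1], km = cf[2], ki = cf[3], kii = cf[4],
        r2 = r_squared(data$v, pred), rss = best$rss)
}

yt_predict <- function(par, data) {
    beta <- if (length(par) == 4L) par[4] else 0
    exp(par[1]) / (1 + data$I / exp(par[2]) + data$J / exp(par[3]) +
                   beta * data$I * data$J / (exp(par[2]) * exp(par[3])))
}

fit_yt <- function(data, freeBeta) {
    v00 <- max(data$v) * 1.05
    ki0 <- stats::median(data$I[data$I > 0])
    kj0 <- stats::median(data$J[data$J > 0])
    par0 <- c(log(v00), log(ki0), log(kj0))
    if (freeBeta) par0 <- c(par0, 0.5)
    lower <- if (freeBeta) c(-Inf, -Inf, -Inf, 0) else rep(-Inf, 3L)
    minpack.lm::nls.lm(
        par = par0,
        fn = function(par) data$v - yt_predict(par, data),
        lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-13, ptol = 1e-13))
}

#' Fit the Yonetani-Theorell cross-competition model
#'
#' Globally fits the reciprocal double-inhibition law with beta = 1/alpha
#' bounded below by zero, refits with beta fixed at exactly zero
#' (mutual exclusivity), and selects between the two by small-sample
#' corrected information criterion.  The exclusivity call is
#' \code{"mutually exclusive"} when the beta = 0 model is preferred.
#'
#' @param data data.frame with columns \code{I}, \code{J}, \code{v},
#'   covering a grid over both inhibitors including their zeros.
#' @return a [CrossCompetitionFit-class].
#' @export
fitCrossCompetition <- function(data) {
    check_cols(data, c("I", "J", "v"))
    if (length(unique(data$J)) < 2L || all(data$J == 0))
        stop("cross term unidentifiable: no variation in the second ",
             "inhibitor")
    if (length(unique(data$I)) < 2L || all(data$I == 0))
        stop("cross term unidentifiable: no variation in the first ",
             "inhibitor")
    n <- nrow(data)
    fitF <- fit_yt(data, freeBeta = TRUE)
    fit0 <- fit_yt(data, freeBeta = FALSE)
    aF <- aicc(sum(fitF$fvec^2), n, 4L)
    a0 <- aicc(sum(fit0$fvec^2), n, 3L)
    exclusive <- a0 <= aF
    sel <- if (exclusive) fit0 else fitF
    pred <- yt_predict(sel$par, data)
    new("CrossCompetitionFit",
        v0 = exp(sel$par[1]), ki = exp(sel$par[2]), kj = exp(sel$par[3]),
        beta = if (exclusive) 0 else sel$par[4],
        exclusivity = if (exclusive) "mutually exclusive"
                      else "distinct sites",
        r2 = r_squared(data$v, pred),
        aiccFree = aF, aiccExclusive = a0)
}

#' Yonetani-Theorell plot series
#'
#' For each level of the second inhibitor J, the reciprocal velocity is
#' linear in I: intercept (1/v0)(1 + J/Kj) and slope
#' (1/v0)(1/Ki)(1 + J beta / Kj).  At beta = 0 all slopes coincide
#' (parallel lines); at alpha = 1 the lines intersect at I = -Ki.
#'
#' @param fit a [CrossCompetitionFit-class].
#' @param J levels of the second inhibitor to tabulate.
#' @param data optional dataset; per-point residuals of 1/v are attached.
#' @return data.frame with columns \code{J}, \code{intercept},
#'   \code{slope}; attribute \code{residuals} when \code{data} given.
#' @export
yonetaniPlotData <- function(fit, J, data = NULL) {
    stopifnot(is(fit, "CrossCompetitionFit"))
    if (missing(J)) {
        if (is.null(data)) return(data.frame(J = numeric(),
                                             intercept = numeric(),
                                             slope = numeric()))
        J <- sort(unique(data$J))
    }
    out <- data.frame(
        J = J,
        intercept = (1 / fit@v0) * (1 + J / fit@kj),
        slope = (1 / fit@v0) * (1 / fit@ki) * (1 + J * fit@beta / fit@kj))
    if (!is.null(data)) {
        pred <- yonetaniTheorellRate(data$I, data$J, fit@v0, fit@ki,
                                     fit@kj, fit@beta)
        attr(out, "residuals") <- 1 / data$v - 1 / pred
    }
    out
}

setMethod("show", "Ic50Fit", function(object) {
    cat(sprintf("Ic50Fit: IC50 = %.4g, v0 = %.4g, R^2 = %.4f\n",
                object@ic50, object@v0, object@r2))
})

setMethod("show", "NoncompetitiveFit", function(object) {
    cat(sprintf(paste0("NoncompetitiveFit: Vmax = %.4g, Km = %.4g, ",
                       "Ki = %.4g, Kii = %.4g, R^2 = %.4f\n"),
                object@vmax, object@km, object@ki, object@kii, object@r2))
})

setMethod("show", "CrossCompetitionFit", function(object) {
    cat(sprintf(paste0("CrossCompetitionFit: v0 = %.4g, Ki = %.4g, ",
                       "Kj = %.4g, beta = %.4g (%s), R^2 = %.4f\n"),
                object@v0, object@ki, object@kj, object@beta,
                object@exclusivity, object@r2))
})
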