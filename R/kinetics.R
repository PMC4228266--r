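# Michaelis-Menten fitting and the ratiometric specificity statistics used
# for +1 (Arg vs Pro) and phosphoacceptor (Ser vs Thr) preferences.

#' Fit the Michaelis-Menten model to initial velocities
#'
#' Unweighted nonlinear least squares of
#' \eqn{V_0 = V_{max} [S] / (K_M + [S])} (Levenberg-Marquardt, starting at
#' \eqn{V_{max} = \max V_0}, \eqn{K_M = } median \eqn{[S]}). With the
#' enzyme concentration supplied, turnover is
#' \eqn{k_{cat} = V_{max}/[E]}: velocities are in concentration/min and
#' `enzyme_nM` is converted to the same concentration unit via
#' `v_unit_nM` (default 1000, i.e. velocities in uM/min), giving
#' \eqn{k_{cat}} in 1/min and efficiency \eqn{k_{cat}/K_M} in
#' 1/(min uM). Standard errors come from the local curvature of the fit
#' and first-order propagation.
#'
#' @param conc substrate concentrations, uM (>= 4 distinct values).
#' @param v0 initial velocities, concentration/min, same length as `conc`.
#' @param enzyme_nM enzyme concentration in nM (optional; required for
#'   `k_cat`).
#' @param v_unit_nM how many nM in one unit of the velocity's
#'   concentration scale (1000 when `v0` is in uM/min).
#' @param peptide,acceptor,plus1 optional labels carried into the result.
#' @return Object of class `mm_fit`: list with `K_M`, `V_max`, `k_cat`,
#'   `efficiency` (= k_cat/K_M), standard errors `se` (named), `n_obs`,
#'   the data, and the underlying `nls` object.
#' @export
fit_mm <- function(conc, v0, enzyme_nM = NULL, v_unit_nM = 1000,
                   peptide = NA_character_, acceptor = NA_character_,
                   plus1 = NA_character_) {
  conc <- as.numeric(conc); v0 <- as.numeric(v0)
  if (length(conc) != length(v0))
    stop("conc and v0 must have the same length", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("substrate concentrations must be positive", call. = FALSE)
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  if (!is.null(enzyme_nM) && enzyme_nM <= 0)
    stop("enzyme concentration must be positive", call. = FALSE)

  df <- data.frame(S = conc, v = v0)
  # double-reciprocal linearization seeds the nonlinear fit; fall back to
  # the crude max(V0)/median([S]) guess when it degenerates
  Vmax0 <- max(v0)
  Km0 <- stats::median(conc)
  if (all(v0 > 0)) {
    lb <- stats::coef(stats::lm(I(1 / v0) ~ I(1 / conc)))
    if (all(is.finite(lb)) && lb[1] > 0 && lb[2] > 0) {
      Vmax0 <- unname(1 / lb[1])
      Km0 <- unname(lb[2] * Vmax0)
    }
  }
  starts <- list(
    c(Vmax0, Km0),
    c(max(v0), stats::median(conc)),
    c(max(v0) * 2, unname(stats::quantile(conc, 0.25))),
    c(max(v0) * 1.2, unname(stats::quantile(conc, 0.75))))
  fit <- NULL
  last_err <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                        start = list(Vmax = s[1], Km = s[2]),
                        lower = c(Vmax = 0, Km = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Michaelis-Menten fit failed to converge: ", last_err,
         call. = FALSE)
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(cf)

  Km <- unname(cf["Km"]); Vmax <- unname(cf["Vmax"])
  if (Km <= 0 || Vmax <= 0)
    stop("fit returned non-positive K_M or V_max", call. = FALSE)
  kcat <- kcat_se <- NA_real_
  if (!is.null(enzyme_nM)) {
    E <- enzyme_nM / v_unit_nM      # enzyme in the velocity's unit
    kcat <- Vmax / E
    kcat_se <- se["Vmax"] / E
  }
  eff <- kcat / Km
  eff_se <- if (is.na(kcat)) NA_real_ else
    abs(eff) * sqrt((kcat_se / kcat)^2 + (se["Km"] / Km)^2)

  structure(list(K_M = Km, V_max = Vmax, k_cat = unname(kcat),
                 efficiency = unname(eff),
                 se = c(K_M = unname(se["Km"]), V_max = unname(se["Vmax"]),
                        k_cat = unname(kcat_se), efficiency = unname(eff_se)),
                 n_obs = length(conc), enzyme_nM = enzyme_nM,
                 peptide = peptide, acceptor = acceptor, plus1 = plus1,
                 data = df, nls = fit),
            class = "mm_fit")
}

#' Construct an `mm_fit` from reported parameters
#'
#' For working with published kinetic tables (no raw velocities): builds
#' the same object from \eqn{K_M}, \eqn{k_{cat}} and their standard
#' errors, so ratio statistics like [efficiency_fold()] apply unchanged.
#'
#' @param K_M,k_cat parameter values (uM, 1/min).
#' @param K_M_se,k_cat_se standard errors (optional).
#' @param ... labels passed through (`peptide`, `acceptor`, `plus1`).
#' @return an `mm_fit`.
#' @export
mm_fit_from_params <- function(K_M, k_cat, K_M_se = NA, k_cat_se = NA, ...) {
  stopifnot(K_M > 0, k_cat > 0)
  eff <- k_cat / K_M
  eff_se <- if (is.na(K_M_se) || is.na(k_cat_se)) NA_real_ else
    eff * sqrt((k_cat_se / k_cat)^2 + (K_M_se / K_M)^2)
  lbl <- list(...)
  structure(list(K_M = K_M, V_max = NA_real_, k_cat = k_cat,
                 efficiency = eff,
                 se = c(K_M = K_M_se, V_max = NA_real_, k_cat = k_cat_se,
                        efficiency = eff_se),
                 n_obs = NA_integer_, enzyme_nM = NA_real_,
                 peptide = if (is.null(lbl$peptide)) NA_character_ else lbl$peptide,
                 acceptor = if (is.null(lbl$acceptor)) NA_character_ else lbl$acceptor,
                 plus1 = if (is.null(lbl$plus1)) NA_character_ else lbl$plus1,
                 data = NULL, nls = NULL),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit")
  if (!is.na(x$peptide)) cat(" [", x$peptide, "]", sep = "")
  cat("\n")
  cat("  K_M  =", format(x$K_M, digits = 4), "uM  (se",
      format(x$se["K_M"], digits = 3), ")\n")
  if (!is.na(x$k_cat))
    cat("  k_cat =", format(x$k_cat, digits = 4), "/min  (se",
        format(x$se["k_cat"], digits = 3), ")\n")
  if (!is.na(x$efficiency))
    cat("  k_cat/K_M =", format(x$efficiency, digits = 4), "/(min uM)\n")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(K_M = object$K_M, V_max = object$V_max, k_cat = object$k_cat,
    efficiency = object$efficiency)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else
    if (is.data.frame(newdata)) newdata$S else as.numeric(newdata)
  object$V_max * S / (object$K_M + S)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  if (is.null(object$data)) stop("no data in this fit", call. = FALSE)
  object$data$v - predict(object)
}

#' @export
summary.mm_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$nls)) {
    cat("\n")
    print(summary(object$nls))
  }
  invisible(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  if (is.null(x$data)) stop("no data in this fit", call. = FALSE)
  graphics::plot(x$data$S, x$data$v, xlab = "[S] (uM)",
                 ylab = "V0", pch = 19, ...)
  Sg <- seq(min(x$data$S) / 2, max(x$data$S) * 1.05, length.out = 200)
  graphics::lines(Sg, predict(x, Sg))
  invisible(x)
}

#' Fold-ratio of catalytic efficiencies
#'
#' \eqn{(k_{cat,a}/K_{M,a}) / (k_{cat,b}/K_{M,b})}, with first-order
#' propagation of the component standard errors.
#'
#' @param fit_a,fit_b `mm_fit` objects.
#' @return the fold ratio, with attribute `se`.
#' @export
efficiency_fold <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "mm_fit"), inherits(fit_b, "mm_fit"))
  fold <- fit_a$efficiency / fit_b$efficiency
  sa <- fit_a$se["efficiency"] / fit_a$efficiency
  sb <- fit_b$se["efficiency"] / fit_b$efficiency
  se <- if (is.na(sa) || is.na(sb)) NA_real_ else abs(fold) * sqrt(sa^2 + sb^2)
  attr(fold, "se") <- unname(se)
  fold
}

#' Ratiometric specificity from parallel initial velocities
#'
#' \eqn{\log_2} of the ratio of mean initial velocities of two peptides
#' assayed in parallel (e.g. +1R vs +1P), with standard error by
#' first-order propagation of the replicate standard errors of the means.
#' Antisymmetric under operand swap.
#'
#' @param v0_a,v0_b positive replicate velocities (>= 1 each).
#' @param acceptor phosphoacceptor context label (`"S"`, `"T"`, or
#'   `"S/T"`).
#' @param ids optional operand labels.
#' @param parallel flag asserting the operands were assayed in parallel;
#'   a warning is issued when `FALSE`.
#' @return Object of class `specificity_ratio`: list with `log2_ratio`,
#'   `se`, `acceptor`, `ids`, `n` (replicate counts).
#' @export
ratiometric_specificity <- function(v0_a, v0_b, acceptor = "S",
                                    ids = c("a", "b"), parallel = TRUE) {
  v0_a <- as.numeric(v0_a); v0_b <- as.numeric(v0_b)
  if (!length(v0_a) || !length(v0_b))
    stop("need at least one replicate per operand", call. = FALSE)
  if (any(v0_a <= 0) || any(v0_b <= 0))
    stop("velocities must be positive", call. = FALSE)
  if (!parallel)
    warning("operands not flagged as assayed in parallel; ",
            "ratio may be confounded by batch effects")
  ma <- mean(v0_a); mb <- mean(v0_b)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  se <- sqrt((sem(v0_a) / ma)^2 + (sem(v0_b) / mb)^2) / log(2)
  structure(list(log2_ratio = log2(ma / mb), se = se,
                 acceptor = acceptor, ids = ids,
                 n = c(length(v0_a), length(v0_b))),
            class = "specificity_ratio")
}

#' @export
print.specificity_ratio <- function(x, ...) {
  cat("log2(", x$ids[1], "/", x$ids[2], ") = ",
      format(x$log2_ratio, digits = 4), " (se ",
      format(x$se, digits = 3), "), acceptor ", x$acceptor, "\n", sep = "")
  invisible(x)
}

#' Phosphoacceptor preference
#'
#' [ratiometric_specificity()] specialized to serine vs threonine
#' phosphoacceptor velocities: \eqn{\log_2(V_{0,S}/V_{0,T})}.
#'
#' @param v0_S,v0_T positive replicate velocities.
#' @param ... passed to [ratiometric_specificity()].
#' @return a `specificity_ratio` with ids `S`, `T`.
#' @export
acceptor_preference <- function(v0_S, v0_T, ...) {
  ratiometric_specificity(v0_S, v0_T, acceptor = "S/T", ids = c("S", "T"),
                          ...)
}
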