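#' 1:1 Langmuir binding parameters
#'
#' Single-site reversible binding with association rate `ka` (M^-1 s^-1),
#' dissociation rate `kd` (s^-1), equilibrium dissociation constant
#' `KD = kd/ka` (M, enforced identity) and maximal response `Rmax` (RU).
#'
#' @param ka association rate constant (> 0), M^-1 s^-1.
#' @param kd dissociation rate constant (>= 0), s^-1.
#' @param Rmax maximal response, RU.
#' @return an object of class `kinetic_params`.
#' @export
#' @examples
#' kinetic_params(5809, 2.136e-3, Rmax = 100)$KD
kinetic_params <- function(ka, kd, Rmax = 100) {
  check_scalar_num(ka, "ka")
  if (ka <= 0) stop_param("ka", "must be > 0")
  check_scalar_num(kd, "kd", lower = 0)
  check_scalar_num(Rmax, "Rmax", lower = 0)
  structure(list(ka = ka, kd = kd, KD = kd / ka, Rmax = Rmax),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> ka = %.4g M^-1 s^-1, kd = %.4g s^-1, KD = %.4g M, Rmax = %.4g RU\n",
              x$ka, x$kd, x$KD, x$Rmax))
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `KD = kd / ka`, in molar units.
#'
#' @param ka association rate constant, M^-1 s^-1 (> 0).
#' @param kd dissociation rate constant, s^-1.
#' @return KD in M.
#' @export
#' @examples
#' kd_from_rates(5809, 2.136e-3) # 3.677e-7 M
kd_from_rates <- function(ka, kd) {
  check_scalar_num(ka, "ka")
  if (ka <= 0) stop_param("ka", "must be > 0")
  check_scalar_num(kd, "kd", lower = 0)
  kd / ka
}

#' Noise-free 1:1 Langmuir response curve
#'
#' Association phase `R(t) = Req (1 - exp(-(ka C + kd) t))` with plateau
#' `Req = Rmax C / (C + KD)`; dissociation decays as `exp(-kd (t - t_assoc))`
#' from the association end point.
#'
#' @param t time points in seconds.
#' @param conc analyte concentration in M.
#' @param ka,kd,Rmax model parameters.
#' @param t_assoc end of the association phase in seconds.
#' @return response values in RU.
#' @export
langmuir_response <- function(t, conc, ka, kd, Rmax, t_assoc) {
  KD <- kd / ka
  req <- Rmax * conc / (conc + KD)
  kobs <- ka * conc + kd
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc,
         req * (1 - exp(-kobs * t)),
         r_end * exp(-kd * (t - t_assoc)))
}

#' Simulate an SPR sensorgram under the 1:1 Langmuir model
#'
#' @param kp a [kinetic_params()] object.
#' @param conc analyte concentration in M (> 0).
#' @param t_assoc,t_dissoc association and dissociation durations, s (> 0).
#' @param noise_sd Gaussian noise sd in RU.
#' @param seed RNG seed (NULL: use current stream).
#' @param dt sampling interval in seconds.
#' @return an object of class `sensorgram`: data.frame `t`, `response` with
#'   attributes `conc` and `t_assoc`.
#' @export
#' @examples
#' sg <- simulate_sensorgram(kinetic_params(5809, 2.136e-3, 100),
#'                           conc = 3.7e-7, t_assoc = 300, t_dissoc = 300)
#' tail(sg$response[sg$t <= 300], 1) # approaches Rmax*C/(C+KD)
simulate_sensorgram <- function(kp, conc, t_assoc, t_dissoc,
                                noise_sd = 0, seed = NULL, dt = 1) {
  stopifnot(inherits(kp, "kinetic_params"))
  check_scalar_num(conc, "conc")
  if (conc <= 0) stop_param("conc", "must be > 0")
  check_scalar_num(t_assoc, "t_assoc")
  if (t_assoc <= 0) stop_param("t_assoc", "must be > 0")
  check_scalar_num(t_dissoc, "t_dissoc")
  if (t_dissoc <= 0) stop_param("t_dissoc", "must be > 0")
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  t <- seq(0, t_assoc + t_dissoc, by = dt)
  r <- langmuir_response(t, conc, kp$ka, kp$kd, kp$Rmax, t_assoc)
  if (noise_sd > 0)
    r <- r + with_seed(seed, rnorm(length(r), 0, noise_sd))
  structure(data.frame(t = t, response = r),
            conc = conc, t_assoc = t_assoc,
            class = c("sensorgram", "data.frame"))
}

# starting values from linearized plateau/dissociation analysis
langmuir_start <- function(sensorgrams) {
  concs <- vapply(sensorgrams, attr, numeric(1), "conc")
  req <- vapply(sensorgrams, function(sg) {
    ta <- attr(sg, "t_assoc")
    assoc <- sg$response[sg$t <= ta]
    mean(tail(assoc, max(3, length(assoc) %/% 10)))
  }, numeric(1))
  # kd from the dissociation tail of the highest-concentration curve
  sg <- sensorgrams[[which.max(concs)]]
  ta <- attr(sg, "t_assoc")
  dis <- sg[sg$t > ta, , drop = FALSE]
  pos <- dis$response > max(dis$response) * 1e-3
  kd0 <- if (sum(pos) >= 3) {
    sl <- coef(lm(log(dis$response[pos]) ~ dis$t[pos]))[2]
    max(1e-6, -unname(sl))
  } else 1e-3
  # 1/Req = 1/Rmax + (KD/Rmax) (1/C)
  ok <- req > 0
  if (sum(ok) >= 2 && length(unique(concs[ok])) >= 2) {
    fit <- coef(lm(I(1 / req[ok]) ~ I(1 / concs[ok])))
    rmax0 <- 1 / max(fit[1], 1e-8)
    kD0 <- max(fit[2] * rmax0, 1e-12)
  } else {
    rmax0 <- max(req) * 1.5
    kD0 <- stats::median(concs)
  }
  c(ka = max(kd0 / kD0, 1e-3), kd = kd0, Rmax = max(rmax0, max(req), 1))
}

#' Fit the 1:1 Langmuir model jointly to sensorgrams
#'
#' Nonlinear least squares over all supplied sensorgrams for the shared
#' parameters `(ka, kd, Rmax)` (optimized on the log scale for positivity),
#' with starting values from linearized plateau and dissociation analysis.
#' `KD = kd/ka` is derived. The fit is deterministic given the data.
#'
#' @param sensorgrams a [simulate_sensorgram()] result or a list of them;
#'   at least two concentrations are recommended for identifiability.
#' @param start optional named vector `c(ka =, kd =, Rmax =)`.
#' @return an object of class `langmuir_fit` with components `params`
#'   ([kinetic_params()]), `rms` residual, `fitted`, `residuals`,
#'   `convergence`, `ill_conditioned` (TRUE when the parameter Jacobian is
#'   numerically rank-deficient, e.g. a single concentration far below KD
#'   with no dissociation decay), and the input data. Methods: `print`,
#'   `coef`, `summary`, `predict`, `residuals`, `plot`, `simulate`.
#' @export
#' @examples
#' kp <- kinetic_params(5809, 2.136e-3, 120)
#' sgs <- lapply(c(1e-7, 4e-7, 1.6e-6), function(C)
#'   simulate_sensorgram(kp, C, 300, 300))
#' fit <- fit_1to1(sgs)
#' coef(fit)
fit_1to1 <- function(sensorgrams, start = NULL) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  if (!is.list(sensorgrams) || length(sensorgrams) == 0 ||
      !all(vapply(sensorgrams, inherits, logical(1), "sensorgram")))
    stop_param("sensorgrams", "must be a sensorgram or list of sensorgrams")
  if (is.null(start)) start <- langmuir_start(sensorgrams)
  concs <- vapply(sensorgrams, attr, numeric(1), "conc")
  tas <- vapply(sensorgrams, attr, numeric(1), "t_assoc")
  obs <- unlist(lapply(sensorgrams, `[[`, "response"))

  resid_fn <- function(logp) {
    ka <- exp(logp[1]); kd <- exp(logp[2]); rmax <- exp(logp[3])
    pred <- unlist(lapply(seq_along(sensorgrams), function(i)
      langmuir_response(sensorgrams[[i]]$t, concs[i], ka, kd, rmax, tas[i])))
    obs - pred
  }
  p0 <- log(pmax(c(start[["ka"]], start[["kd"]], start[["Rmax"]]), 1e-10))
  res <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  if (res$info %in% c(0, 5, 9))
    stop(sprintf("1:1 fit did not converge (%s); last iterate ka = %.4g, kd = %.4g, Rmax = %.4g",
                 res$message, exp(res$par[1]), exp(res$par[2]), exp(res$par[3])))
  ka <- exp(res$par[1]); kd <- exp(res$par[2]); rmax <- exp(res$par[3])
  params <- kinetic_params(ka, kd, rmax)

  # conditioning of the parameter Jacobian at the solution
  jac <- vapply(1:3, function(j) {
    dp <- res$par; step <- 1e-5
    dp[j] <- dp[j] + step
    (resid_fn(dp) - resid_fn(res$par)) / step
  }, numeric(length(obs)))
  sv <- svd(jac)$d
  cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  ill <- !is.finite(cond) || cond > 1e8
  if (ill)
    warning("1:1 Langmuir fit is ill-conditioned: parameters are not jointly identifiable from these sensorgrams")

  resi <- resid_fn(res$par)
  out <- structure(list(
    params = params,
    rms = sqrt(mean(resi^2)),
    fitted = obs - resi,
    residuals = resi,
    convergence = list(info = res$info, message = res$message,
                       iterations = res$niter),
    condition_number = cond,
    ill_conditioned = ill,
    sensorgrams = sensorgrams,
    start = start
  ), class = "langmuir_fit")
  out
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("1:1 Langmuir binding fit\n")
  print(x$params)
  cat(sprintf("  residual RMS = %.4g RU over %d points (%d curves)%s\n",
              x$rms, length(x$fitted), length(x$sensorgrams),
              if (x$ill_conditioned) " [ill-conditioned]" else ""))
  invisible(x)
}

#' @export
coef.langmuir_fit <- function(object, ...) {
  with(object$params, c(ka = ka, kd = kd, KD = KD, Rmax = Rmax))
}

#' @export
summary.langmuir_fit <- function(object, ...) {
  cat("1:1 Langmuir binding fit\n")
  print(object$params)
  concs <- vapply(object$sensorgrams, attr, numeric(1), "conc")
  cat(sprintf("  concentrations (M): %s\n",
              paste(signif(sort(concs), 3), collapse = ", ")))
  cat(sprintf("  residual RMS: %.4g RU; Jacobian condition number: %.3g\n",
              object$rms, object$condition_number))
  plateaus <- object$params$Rmax * concs / (concs + object$params$KD)
  cat(sprintf("  fitted association plateaus (RU): %s\n",
              paste(signif(plateaus[order(concs)], 3), collapse = ", ")))
  invisible(object)
}

#' @export
predict.langmuir_fit <- function(object, t, conc, t_assoc, ...) {
  p <- object$params
  langmuir_response(t, conc, p$ka, p$kd, p$Rmax, t_assoc)
}

#' @export
residuals.langmuir_fit <- function(object, ...) object$residuals

#' @export
simulate.langmuir_fit <- function(object, nsim = 1, seed = NULL,
                                  conc, t_assoc = 300, t_dissoc = 300,
                                  noise_sd = 0, ...) {
  simulate_sensorgram(object$params, conc, t_assoc, t_dissoc,
                      noise_sd = noise_sd, seed = seed)
}

#' @export
plot.langmuir_fit <- function(x, ...) {
  concs <- vapply(x$sensorgrams, attr, numeric(1), "conc")
  ord <- order(concs)
  cols <- grDevices::hcl.colors(length(concs), "viridis")
  rng <- range(unlist(lapply(x$sensorgrams, `[[`, "response")))
  plot(NA, xlim = range(x$sensorgrams[[1]]$t), ylim = rng,
       xlab = "time (s)", ylab = "response (RU)",
       main = "1:1 Langmuir fit", ...)
  for (i in seq_along(ord)) {
    sg <- x$sensorgrams[[ord[i]]]
    points(sg$t, sg$response, pch = ".", col = cols[i])
    lines(sg$t, predict(x, sg$t, concs[ord[i]], attr(sg, "t_assoc")),
          col = cols[i], lwd = 2)
  }
  legend("topright", legend = signif(concs[ord], 2), col = cols, lwd = 2,
         title = "conc (M)", cex = 0.8)
  invisible(x)
}
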