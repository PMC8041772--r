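#' Fraction of product-free dimers with both substrate sites occupied
#'
#' Substrate binding to the two sites of the dimer is at rapid equilibrium and
#' independent (the second site is unaffected by occupancy of the first), so
#' the probability that a product-free dimer is in the doubly-loaded, competent
#' state is \eqn{f(S) = (S/(K_d+S))^2}.
#'
#' @param substrate free substrate concentration, uM (>= 0).
#' @param Kd substrate dissociation constant, uM (> 0).
#' @return the competent fraction, in [0, 1]; monotone increasing in S.
#' @examples
#' competentFraction(0, 5)        # 0
#' competentFraction(5, 5)        # 0.25
#' competentFraction(50, 5)       # (10/11)^2
#' @export
competentFraction <- function(substrate, Kd) {
  if (!is.numeric(substrate) || any(!is.finite(substrate)) || any(substrate < 0))
    stop("'substrate' must be finite and non-negative (uM)")
  .assertScalarPositive(Kd, "Kd")
  (substrate / (Kd + substrate))^2
}

#' Inhibitory constant Ki = koff/kon
#'
#' @param params a \linkS4class{KineticParameters}.
#' @return Ki in uM.
#' @export
inhibitionConstant <- function(params) {
  stopifnot(is(params, "KineticParameters"))
  if (params@kon <= 0)
    stop("Ki is undefined when kon = 0 (no product binding)")
  params@koff / params@kon
}

# Right-hand side of the reduced ODE system.
# State: y = (Psyn, I); algebraic: S = S0 - 2*Psyn, A = E0 - I, P = Psyn - I.
# Only the doubly-substrate-loaded, product-free dimer catalyses, so
#   dPsyn/dt = kcat * A * f(S)
#   dI/dt    = kon * P * A - koff * I
.cyclaseRHS <- function(t, y, parms) {
  S <- max(parms[["s0"]] - 2 * y[1], 0)
  A <- parms[["e0"]] - y[2]
  f <- (S / (parms[["Kd"]] + S))^2
  P <- max(y[1] - y[2], 0)
  list(c(parms[["kcat"]] * A * f,
         parms[["kon"]] * P * A - parms[["koff"]] * y[2]))
}

#' Simulate a progress curve of the product-inhibited cyclase
#'
#' Integrates the kinetic scheme: rapid-equilibrium substrate binding
#' (competent fraction \code{(S/(Kd+S))^2}), turnover \code{kcat} consuming two
#' substrates per product (S + S -> P), and kinetic non-competitive product
#' binding (\code{kon}, \code{koff}) that converts active dimers A into an
#' inhibited pool I. Substrate and active enzyme are eliminated algebraically
#' (\code{S = S0 - 2*Psyn}, \code{A = E0 - I}) so both conservation laws hold
#' exactly; enzyme-bound product is subtracted from the free product that
#' drives further binding.
#'
#' @param params a \linkS4class{KineticParameters}.
#' @param cond a \linkS4class{ReactionConditions}.
#' @param label label carried on the returned curve.
#' @param rtol,atol relative / absolute integrator tolerances (lsoda; the
#'   burst-to-plateau transition is stiff when \code{kon*P*E0 >> koff}).
#' @return a \linkS4class{ProgressCurve} with product (P_syn), substrate and
#'   bound-product series.
#' @examples
#' p <- KineticParameters(kcat = 0.33, Kd = 10, kon = 6.667e-3, koff = 1e-3)
#' cc <- ReactionConditions(e0 = 5, s0 = 500, times = seq(0, 600, 5))
#' simulateProgress(p, cc)
#' @export
simulateProgress <- function(params, cond, label = "",
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(params, "KineticParameters"), is(cond, "ReactionConditions"))
  validObject(params); validObject(cond)
  parms <- c(kcat = params@kcat, Kd = params@Kd, kon = params@kon,
             koff = params@koff, e0 = cond@e0, s0 = cond@s0)
  out <- deSolve::lsoda(y = c(Psyn = 0, I = 0), times = cond@times,
                        func = .cyclaseRHS, parms = parms,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0 || anyNA(out[, "Psyn"])) {
    last_ok <- suppressWarnings(max(out[stats::complete.cases(out), "time"]))
    stop(sprintf("integration failed (istate %s); last valid time %.6g s",
                 istate, last_ok))
  }
  psyn <- pmin(pmax(out[, "Psyn"], 0), cond@s0 / 2)
  inh <- pmax(out[, "I"], 0)
  ProgressCurve(cond, product = psyn, substrate = pmax(cond@s0 - 2 * psyn, 0),
                bound = inh, label = label)
}

#' Initial reaction velocity
#'
#' Closed form of the t -> 0 slope of the progress curve, before any product
#' has accumulated: \code{v0 = kcat * E0 * competentFraction(S0, Kd)}.
#'
#' @param params a \linkS4class{KineticParameters}.
#' @param cond a \linkS4class{ReactionConditions}.
#' @return initial product synthesis rate, uM/s.
#' @export
initialRate <- function(params, cond) {
  stopifnot(is(params, "KineticParameters"), is(cond, "ReactionConditions"))
  params@kcat * cond@e0 * competentFraction(cond@s0, params@Kd)
}

# ---- global fitting --------------------------------------------------------

.kinParNames <- c("kcat", "Kd", "kon", "koff")

.paramsToVector <- function(p) c(kcat = p@kcat, Kd = p@Kd,
                                 kon = p@kon, koff = p@koff)

# Build the free-parameter bookkeeping for a global fit: parameters named in
# 'shared' get one log-space entry for all curves, the rest one per curve;
# parameters with collapsed bounds (lower == upper) are held fixed and never
# enter the optimiser (this is also the only way to pin a rate to zero, which
# log-space cannot represent).
.fitLayout <- function(n_curves, guess, shared, bounds) {
  g <- .paramsToVector(guess)
  layout <- list(); theta <- numeric(0); lower <- numeric(0); upper <- numeric(0)
  for (nm in .kinParNames) {
    b <- bounds[[nm]]
    if (!is.null(b) && length(b) == 2 && b[1] == b[2]) {
      layout[[nm]] <- list(kind = "fixed", value = b[1])
      next
    }
    lo <- if (is.null(b)) g[nm] / 1e4 else max(b[1], 1e-12)
    hi <- if (is.null(b)) g[nm] * 1e4 else b[2]
    if (g[nm] < lo || g[nm] > hi)
      stop(sprintf("initial guess for '%s' outside its bounds", nm))
    k <- if (nm %in% shared) 1L else n_curves
    layout[[nm]] <- list(kind = if (nm %in% shared) "shared" else "free",
                         index = length(theta) + seq_len(k))
    theta <- c(theta, rep(log(g[nm]), k))
    lower <- c(lower, rep(log(lo), k)); upper <- c(upper, rep(log(hi), k))
  }
  list(layout = layout, theta = theta, lower = lower, upper = upper)
}

.assembleParams <- function(theta, layout, curve_i) {
  v <- vapply(.kinParNames, function(nm) {
    l <- layout[[nm]]
    switch(l$kind,
           fixed = l$value,
           shared = exp(theta[l$index]),
           free = exp(theta[l$index[curve_i]]))
  }, numeric(1))
  KineticParameters(v["kcat"], v["Kd"], v["kon"], v["koff"])
}

#' Globally fit the kinetic model to one or more progress curves
#'
#' Damped least-squares (Levenberg-Marquardt) minimisation of the joint
#' residuals of all curves, over the product series and, when present, the
#' substrate series. Parameters are fitted in log space to enforce positivity;
#' residuals are unweighted. Parameters listed in \code{shared} are tied to a
#' single value across curves; a parameter whose bounds collapse to a point
#' (e.g. \code{kon = c(0, 0)}) is held fixed at that value.
#'
#' @param curves a \linkS4class{ProgressCurve} or list of them.
#' @param guess a \linkS4class{KineticParameters} starting point (within
#'   bounds).
#' @param shared character vector of parameter names
#'   (\code{"kcat","Kd","kon","koff"}) shared across curves.
#' @param bounds named list of length-2 numeric ranges per parameter.
#' @param control overrides for \code{\link[minpack.lm]{nls.lm.control}}.
#'   Defaults are tight (\code{maxiter 1000}, \code{ftol/ptol 1e-13},
#'   \code{gtol 0}, \code{epsfcn 1e-10}): the kcat-Kd direction is a narrow
#'   curved valley and loose tolerances stall on its floor.
#' @details The optimiser runs twice: once directly from the guess, and once
#' in two stages (Kd held at its guess, then released from the stage-one
#' optimum). The kcat-Kd correlation creates a secondary local minimum at
#' large Kd that the direct run can fall into; the staged run approaches the
#' global valley from a well-conditioned subproblem. The better deviance
#' wins, followed by iterated restarts from the winner (each restart resets
#' the trust region, which keeps the descent moving along the flat valley)
#' until the deviance stops improving.
#' @return a \linkS4class{KineticFit}.
#' @examples
#' p <- KineticParameters(0.33, 10, 6.667e-3, 1e-3)
#' cc <- ReactionConditions(5, 500, seq(0, 300, 5))
#' crv <- simulateProgress(p, cc)
#' fitProgress(crv, KineticParameters(0.66, 20, 1.33e-2, 2e-3))
#' @export
fitProgress <- function(curves, guess, shared = character(0),
                        bounds = list(), control = list()) {
  if (is(curves, "ProgressCurve")) curves <- list(curves)
  stopifnot(length(curves) >= 1,
            all(vapply(curves, is, TRUE, "ProgressCurve")),
            is(guess, "KineticParameters"))
  bad <- setdiff(shared, .kinParNames)
  if (length(bad)) stop("unknown shared parameter(s): ",
                        paste(bad, collapse = ", "))
  lay <- .fitLayout(length(curves), guess, shared, bounds)

  resid_fn <- function(theta) {
    r <- lapply(seq_along(curves), function(i) {
      cv <- curves[[i]]
      sim <- tryCatch(.assembleParams(theta, lay$layout, i), error = identity)
      if (inherits(sim, "error")) return(rep(1e6, length(timeGrid(cv))))
      sim <- tryCatch(simulateProgress(sim, cv@conditions), error = identity)
      if (inherits(sim, "error")) return(rep(1e6, length(timeGrid(cv))))
      out <- sim@product - cv@product
      if (length(cv@substrate)) out <- c(out, sim@substrate - cv@substrate)
      out
    })
    unlist(r)
  }

  control <- utils::modifyList(list(maxiter = 1000, ftol = 1e-13,
                                    ptol = 1e-13, gtol = 0, epsfcn = 1e-10),
                               control)
  ctrl <- do.call(minpack.lm::nls.lm.control, control)
  total_iter <- 0
  run_lm <- function(theta0, lower = lay$lower, upper = lay$upper) {
    f <- minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                            fn = resid_fn, control = ctrl)
    total_iter <<- total_iter + f$niter
    f
  }

  fit <- run_lm(lay$theta)
  kd_lay <- lay$layout$Kd
  if (kd_lay$kind != "fixed") {
    # staged route: hold Kd at its guess, then release from that optimum
    lo2 <- lay$lower; up2 <- lay$upper
    lo2[kd_lay$index] <- up2[kd_lay$index] <- lay$theta[kd_lay$index]
    staged <- run_lm(run_lm(lay$theta, lo2, up2)$par)
    if (is.finite(staged$deviance) && staged$deviance < fit$deviance)
      fit <- staged
  }
  # iterated restarts reset the trust region and keep descending along the
  # flat kcat-Kd valley; stop when the deviance no longer improves materially
  for (k in seq_len(15)) {
    restarted <- run_lm(fit$par)
    if (!is.finite(restarted$deviance)) break
    improved <- restarted$deviance < fit$deviance * (1 - 1e-3)
    if (restarted$deviance <= fit$deviance) fit <- restarted
    if (!improved) break
  }
  final_res <- resid_fn(fit$par)
  if (any(!is.finite(final_res)))
    stop("non-finite residuals at the optimum; parameter vector: ",
         paste(signif(exp(fit$par), 6), collapse = ", "))

  # standard errors: log-space covariance from the LM Hessian approximation,
  # mapped to the linear scale by value * sd(log value)
  n_obs <- length(final_res); n_par <- length(fit$par)
  se_log <- rep(NA_real_, n_par)
  if (n_obs > n_par && length(fit$par)) {
    sigma2 <- fit$deviance / (n_obs - n_par)
    covl <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
    if (!is.null(covl)) se_log <- sqrt(pmax(diag(covl), 0))
  }

  pars <- lapply(seq_along(curves), function(i)
    .assembleParams(fit$par, lay$layout, i))
  errs <- lapply(seq_along(curves), function(i) {
    vapply(.kinParNames, function(nm) {
      l <- lay$layout[[nm]]
      if (l$kind == "fixed") return(NA_real_)
      j <- if (l$kind == "shared") l$index else l$index[i]
      exp(fit$par[j]) * se_log[j]
    }, numeric(1))
  })

  new("KineticFit", parameters = pars, stderr = errs, shared = shared,
      rss = fit$deviance, converged = fit$info %in% 1:3,
      neval = as.numeric(total_iter))
}

# ---- delimited-text IO -----------------------------------------------------

#' Read / write progress curves as delimited text
#'
#' The on-disk convention is a header with columns \code{time_s},
#' \code{product_uM} and optionally \code{substrate_uM}; comma or tab
#' separated (autodetected on read).
#'
#' @param path file path.
#' @param e0 enzyme dimer concentration, uM (not stored in the table).
#' @param s0 initial substrate, uM; defaults to \code{substrate_uM[1]} when
#'   that column is present.
#' @param label curve label.
#' @return \code{readProgressCurve}: a \linkS4class{ProgressCurve}.
#' @export
readProgressCurve <- function(path, e0, s0 = NULL, label = basename(path)) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_s", "product_uM") %in% names(d)))
    stop(sprintf("'%s': need columns time_s and product_uM", path))
  if (is.null(s0)) {
    if ("substrate_uM" %in% names(d)) s0 <- d$substrate_uM[1]
    else stop("s0 must be given when the file has no substrate_uM column")
  }
  ProgressCurve(ReactionConditions(e0, s0, d$time_s),
                product = d$product_uM,
                substrate = if ("substrate_uM" %in% names(d))
                  d$substrate_uM else numeric(0),
                label = label)
}

#' @rdname readProgressCurve
#' @param curve a \linkS4class{ProgressCurve} to write.
#' @return \code{writeProgressCurve}: the path, invisibly.
#' @export
writeProgressCurve <- function(curve, path) {
  d <- as.data.frame(curve)
  d <- d[, intersect(c("time_s", "substrate_uM", "product_uM"), names(d))]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
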