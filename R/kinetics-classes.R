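#' @import methods
NULL

#' Rate constants of the product-inhibited dimeric cyclase model
#'
#' Container for the four constants of the kinetic scheme: a dimeric enzyme
#' binds two substrate molecules independently (rapid equilibrium, dissociation
#' constant \code{Kd}); only the doubly-loaded, product-free dimer turns over
#' (\code{kcat}); product binding to the allosteric site is kinetic, with an
#' effective second-order on-rate \code{kon} and first-order off-rate
#' \code{koff}. The inhibitory constant is the derived quantity
#' \code{Ki = koff/kon}.
#'
#' Units are fixed package-wide: concentrations in uM, time in seconds.
#' \code{kcat} [1/s], \code{Kd} [uM], \code{kon} [1/(uM s)], \code{koff} [1/s].
#'
#' @slot kcat turnover number of the competent dimer, per second.
#' @slot Kd substrate equilibrium dissociation constant, uM.
#' @slot kon effective product-binding rate constant, per uM per second.
#' @slot koff product-release rate constant, per second.
#' @export
setClass("KineticParameters",
  representation(kcat = "numeric", Kd = "numeric",
                 kon = "numeric", koff = "numeric"))

setValidity("KineticParameters", function(object) {
  v <- c(kcat = object@kcat, Kd = object@Kd,
         kon = object@kon, koff = object@koff)
  if (length(v) != 4L || any(!is.finite(v)))
    return("all four rate constants must be single finite numbers")
  if (any(v < 0)) return("rate constants must be non-negative")
  if (object@Kd <= 0) return("Kd must be strictly positive")
  TRUE
})

#' Construct kinetic parameters
#'
#' @param kcat turnover number, 1/s.
#' @param Kd substrate dissociation constant, uM (strictly positive).
#' @param kon product on-rate, 1/(uM s). Zero switches product inhibition off.
#' @param koff product off-rate, 1/s.
#' @return a \linkS4class{KineticParameters} object.
#' @examples
#' p <- KineticParameters(kcat = 0.33, Kd = 10, kon = 6.667e-3, koff = 1e-3)
#' inhibitionConstant(p)  # ~0.15 uM
#' @export
KineticParameters <- function(kcat, Kd, kon, koff) {
  new("KineticParameters", kcat = as.numeric(kcat), Kd = as.numeric(Kd),
      kon = as.numeric(kon), koff = as.numeric(koff))
}

#' Reaction conditions for a progress-curve experiment
#'
#' @slot e0 total enzyme dimer concentration, uM.
#' @slot s0 initial substrate (GTP) concentration, uM.
#' @slot times output time grid in seconds, strictly increasing, starting at 0.
#' @export
setClass("ReactionConditions",
  representation(e0 = "numeric", s0 = "numeric", times = "numeric"))

setValidity("ReactionConditions", function(object) {
  if (length(object@e0) != 1L || !is.finite(object@e0) || object@e0 <= 0)
    return("e0 must be a single positive number (uM)")
  if (length(object@s0) != 1L || !is.finite(object@s0) || object@s0 < 0)
    return("s0 must be a single non-negative number (uM)")
  t <- object@times
  if (length(t) < 2L || any(!is.finite(t)))
    return("time grid needs at least two finite points")
  if (t[1] != 0) return("time grid must start at 0")
  if (any(diff(t) <= 0)) return("time grid must be strictly increasing")
  TRUE
})

#' Construct reaction conditions
#'
#' @param e0 enzyme dimer concentration, uM.
#' @param s0 initial substrate concentration, uM.
#' @param times time grid in seconds (strictly increasing, starting at 0).
#' @return a \linkS4class{ReactionConditions} object.
#' @export
ReactionConditions <- function(e0, s0, times) {
  new("ReactionConditions", e0 = as.numeric(e0), s0 = as.numeric(s0),
      times = as.numeric(times))
}

#' A progress curve of the cyclase reaction
#'
#' Time series of synthesised product (and optionally substrate) under stated
#' enzyme/substrate conditions. Simulated curves additionally carry the free
#' product and the inhibited-enzyme pool; measured curves leave those empty.
#' \code{product} is total synthesised product P_syn; the free product is
#' \code{P_syn - bound} (enzyme-sequestered product subtracted).
#'
#' @slot conditions a \linkS4class{ReactionConditions}.
#' @slot substrate substrate series, uM (may be length 0 when unobserved).
#' @slot product total synthesised product series P_syn, uM.
#' @slot bound enzyme-bound product (inhibited pool I), uM; length 0 for data.
#' @slot label free-text label (variant / activation state).
#' @export
setClass("ProgressCurve",
  representation(conditions = "ReactionConditions", substrate = "numeric",
                 product = "numeric", bound = "numeric", label = "character"))

setValidity("ProgressCurve", function(object) {
  n <- length(object@conditions@times)
  if (length(object@product) != n)
    return("product series length must match the time grid")
  if (length(object@substrate) && length(object@substrate) != n)
    return("substrate series length must match the time grid")
  if (length(object@bound) && length(object@bound) != n)
    return("bound-product series length must match the time grid")
  if (any(object@product < -1e-9, na.rm = TRUE) ||
      any(object@substrate < -1e-9, na.rm = TRUE))
    return("concentrations must be non-negative")
  TRUE
})

#' Construct a progress curve
#'
#' @param conditions a \linkS4class{ReactionConditions}.
#' @param product product series (total synthesised, uM).
#' @param substrate optional substrate series (uM).
#' @param bound optional enzyme-bound product series (uM).
#' @param label curve label.
#' @return a \linkS4class{ProgressCurve}.
#' @export
ProgressCurve <- function(conditions, product, substrate = numeric(0),
                          bound = numeric(0), label = "") {
  new("ProgressCurve", conditions = conditions,
      substrate = as.numeric(substrate), product = as.numeric(product),
      bound = as.numeric(bound), label = as.character(label)[1])
}

#' Result of a (global) progress-curve fit
#'
#' @slot parameters list of \linkS4class{KineticParameters}, one per curve.
#' @slot stderr list of named numeric vectors of parameter standard errors
#'   (linear scale), one per curve; \code{NA} for parameters held fixed.
#' @slot shared character vector of parameter names tied across curves.
#' @slot rss residual sum of squares, uM^2.
#' @slot converged logical convergence flag.
#' @slot neval number of residual-function evaluations.
#' @export
setClass("KineticFit",
  representation(parameters = "list", stderr = "list", shared = "character",
                 rss = "numeric", converged = "logical", neval = "numeric"))

setValidity("KineticFit", function(object) {
  if (!all(vapply(object@parameters, is, TRUE, "KineticParameters")))
    return("parameters must be a list of KineticParameters")
  if (length(object@rss) != 1L || object@rss < 0)
    return("rss must be a single non-negative number")
  bad <- unlist(object@stderr)
  if (length(bad) && any(!is.na(bad) & bad < 0))
    return("standard errors must be non-negative")
  TRUE
})

# ---- accessors -------------------------------------------------------------

#' @rdname KineticParameters-class
#' @param object a KineticParameters object.
#' @export
setGeneric("kcat", function(object) standardGeneric("kcat"))
#' @rdname KineticParameters-class
#' @export
setMethod("kcat", "KineticParameters", function(object) object@kcat)

#' @rdname KineticParameters-class
#' @export
setGeneric("Kd", function(object) standardGeneric("Kd"))
#' @rdname KineticParameters-class
#' @export
setMethod("Kd", "KineticParameters", function(object) object@Kd)

#' @rdname KineticParameters-class
#' @export
setGeneric("kon", function(object) standardGeneric("kon"))
#' @rdname KineticParameters-class
#' @export
setMethod("kon", "KineticParameters", function(object) object@kon)

#' @rdname KineticParameters-class
#' @export
setGeneric("koff", function(object) standardGeneric("koff"))
#' @rdname KineticParameters-class
#' @export
setMethod("koff", "KineticParameters", function(object) object@koff)

#' Time grid of a curve or conditions object
#' @param object a ReactionConditions or ProgressCurve.
#' @return numeric vector of times in seconds.
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))
#' @rdname timeGrid
#' @export
setMethod("timeGrid", "ReactionConditions", function(object) object@times)
#' @rdname timeGrid
#' @export
setMethod("timeGrid", "ProgressCurve", function(object) object@conditions@times)

#' Series accessors for progress curves
#' @param object a ProgressCurve.
#' @return numeric vector (uM), possibly length 0 for unobserved series.
#' @export
setGeneric("productSeries", function(object) standardGeneric("productSeries"))
#' @rdname productSeries
#' @export
setMethod("productSeries", "ProgressCurve", function(object) object@product)

#' @rdname productSeries
#' @export
setGeneric("substrateSeries",
           function(object) standardGeneric("substrateSeries"))
#' @rdname productSeries
#' @export
setMethod("substrateSeries", "ProgressCurve", function(object) object@substrate)

#' @rdname productSeries
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))
#' @rdname productSeries
#' @export
setMethod("conditions", "ProgressCurve", function(object) object@conditions)

#' Fitted per-curve parameters
#' @param object a KineticFit.
#' @return list of KineticParameters.
#' @export
setGeneric("fittedParameters",
           function(object) standardGeneric("fittedParameters"))
#' @rdname fittedParameters
#' @export
setMethod("fittedParameters", "KineticFit", function(object) object@parameters)

# ---- show ------------------------------------------------------------------

setMethod("show", "KineticParameters", function(object) {
  ki <- if (object@kon > 0) sprintf("%.4g uM", object@koff / object@kon)
        else "undefined (kon = 0)"
  cat("KineticParameters\n",
      sprintf("  kcat = %.4g /s, Kd = %.4g uM, kon = %.4g /(uM s), koff = %.4g /s\n",
              object@kcat, object@Kd, object@kon, object@koff),
      sprintf("  Ki (koff/kon) = %s\n", ki), sep = "")
})

setMethod("show", "ProgressCurve", function(object) {
  t <- timeGrid(object)
  cat(sprintf("ProgressCurve '%s': %d time points over %.4g s, E0 = %.4g uM, S0 = %.4g uM\n",
              object@label, length(t), max(t),
              object@conditions@e0, object@conditions@s0))
  cat(sprintf("  final product %.4g uM%s\n",
              object@product[length(t)],
              if (length(object@substrate))
                sprintf(", final substrate %.4g uM",
                        object@substrate[length(t)]) else ""))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit: %d curve(s), rss = %.6g uM^2, converged = %s, %d evaluations\n",
              length(object@parameters), object@rss, object@converged,
              as.integer(object@neval)))
  if (length(object@shared))
    cat("  shared:", paste(object@shared, collapse = ", "), "\n")
  for (i in seq_along(object@parameters)) {
    p <- object@parameters[[i]]
    cat(sprintf("  [%d] kcat=%.4g Kd=%.4g kon=%.4g koff=%.4g\n",
                i, p@kcat, p@Kd, p@kon, p@koff))
  }
})

#' Coerce a progress curve to a data.frame
#'
#' Columns follow the package's delimited-text convention: \code{time_s},
#' \code{product_uM} (total synthesised) and, when present,
#' \code{substrate_uM} and \code{bound_uM}.
#'
#' @param x a ProgressCurve.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a data.frame.
#' @export
as.data.frame.ProgressCurve <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  d <- data.frame(time_s = timeGrid(x), product_uM = x@product)
  if (length(x@substrate)) d$substrate_uM <- x@substrate
  if (length(x@bound)) d$bound_uM <- x@bound
  d
}
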