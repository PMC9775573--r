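# Item-to-ensemble insulation summation, clothing-area-factor estimation,
# and the regression machinery to refit these models from wardrobe data.
# All published coefficients live in inst/extdata/summation_models.json
# (data, not code), so users can refit and swap models.

#' Construct a linear prediction model
#'
#' A plain slope/intercept model with provenance, used both for the shipped
#' item-summation and clothing-area-factor equations and for user refits.
#'
#' @param slope,intercept coefficients.
#' @param r_squared coefficient of determination on the fitting data
#'   (1 - SS_res/SS_tot), or `NA` for conventions not fitted here.
#' @param n_points number of fitting points (`NA` for shipped conventions).
#' @param input_unit `"clo"` or `"si"`: the unit the predictor must be in.
#' @param fitted_on free-text provenance.
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(slope, intercept, r_squared = NA_real_,
                         n_points = NA_integer_,
                         input_unit = c("clo", "si"), fitted_on = "") {
  input_unit <- match.arg(input_unit)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n_points = n_points, input_unit = input_unit, fitted_on = fitted_on),
    class = "linear_model"
  )
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear_model> y = %.4f + %.4f x  [x in %s]%s\n",
              x$intercept, x$slope, x$input_unit,
              if (!is.na(x$r_squared)) sprintf("  R2=%.3f", x$r_squared) else ""))
  if (nzchar(x$fitted_on)) cat("  fitted on: ", x$fitted_on, "\n", sep = "")
  invisible(x)
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' Load the packaged model coefficients
#'
#' Reads the versioned coefficient file shipped with the package (or a user
#' file of the same layout) into named [linear_model()] objects.
#'
#' @param path path to a JSON coefficient file; default is the packaged one.
#' @return List with elements `icl_summation` (models `standard`,
#'   `incident`, `ou`) and `fcl_estimation` (models `modern_western`,
#'   `firefighter`), plus `version`.
#' @export
load_model_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "summation_models.json", package = "maniclo")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_lm <- function(m) linear_model(
    slope = m$slope, intercept = m$intercept,
    r_squared = if (!is.null(m$r_squared)) m$r_squared else NA_real_,
    input_unit = m$input_unit, fitted_on = m$fitted_on %||% "")
  list(
    version = raw$version,
    icl_summation = lapply(raw$icl_summation, as_lm),
    fcl_estimation = lapply(raw$fcl_estimation, as_lm)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum the basic insulation of an ensemble's items
#'
#' The starting point of every summation model: the plain sum of the member
#' items' basic (intrinsic) insulation values.
#'
#' @param composition character vector of item ids.
#' @param items the wardrobe item table (from [load_wardrobe()]`$items`, or
#'   any data frame with columns `item_id`, `iclu`).
#' @return List with `iclu_si` (m2K/W) and `iclu_clo`.
#' @examples
#' wdb <- load_wardrobe()
#' sum_item_insulation(c("1", "2", "8", "9", "10", "11", "15"), wdb$items)
#' @export
sum_item_insulation <- function(composition, items) {
  composition <- as.character(composition)
  unknown <- setdiff(composition, items$item_id)
  if (length(unknown) > 0L) {
    stop("unknown item id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  s <- sum(items$iclu[match(composition, items$item_id)])
  list(iclu_si = s, iclu_clo = to_clo(s))
}

#' Predict ensemble basic insulation from summed item insulation
#'
#' Applies a linear summation model I_cl = intercept + slope * sum(I_clu),
#' all in clo. The shipped models are `"standard"` (the conventional
#' summation), `"incident"` (intercept-adjusted for turnout/incident gear)
#' and `"ou"` (refit for operational-uniform station wear); a custom
#' [linear_model()] may be passed instead.
#'
#' @param sum_iclu_clo summed item basic insulation (clo), >= 0.
#' @param model model name or a [linear_model()] with `input_unit` `"clo"`.
#' @param config model coefficients, see [load_model_config()].
#' @return Predicted ensemble basic insulation (clo).
#' @examples
#' predict_icl(2.0, "incident")
#' @export
predict_icl <- function(sum_iclu_clo, model = c("standard", "incident", "ou"),
                        config = load_model_config()) {
  stopifnot(all(sum_iclu_clo >= 0))
  m <- resolve_model(model, config$icl_summation, c("standard", "incident", "ou"))
  if (m$input_unit != "clo") {
    stop("summation models take the item sum in clo", call. = FALSE)
  }
  predict(m, sum_iclu_clo)
}

#' Estimate the clothing area factor from basic insulation
#'
#' Applies a linear model f_cl = intercept + slope * I_cl. The shipped
#' models are `"firefighter"` (I_cl in clo) and `"modern_western"` (I_cl in
#' m2K/W); the predictor unit must match the model's `input_unit`.
#'
#' @param icl basic insulation, >= 0, in the unit named by `unit`.
#' @param model model name or a [linear_model()].
#' @param unit `"clo"` or `"si"`: the unit `icl` is expressed in.
#' @param config model coefficients, see [load_model_config()].
#' @return Estimated clothing area factor (dimensionless, >= 1).
#' @examples
#' estimate_fcl(0.67, "firefighter", unit = "clo")
#' @export
estimate_fcl <- function(icl, model = c("firefighter", "modern_western"),
                         unit = c("clo", "si"), config = load_model_config()) {
  stopifnot(all(icl >= 0))
  unit <- match.arg(unit)
  m <- resolve_model(model, config$fcl_estimation,
                     c("firefighter", "modern_western"))
  if (m$input_unit != unit) {
    stop(sprintf("model expects icl in %s but got %s", m$input_unit, unit),
         call. = FALSE)
  }
  out <- predict(m, icl)
  if (any(out < 1)) stop("estimated fcl below 1", call. = FALSE)
  out
}

resolve_model <- function(model, shipped, choices) {
  if (inherits(model, "linear_model")) return(model)
  shipped[[match.arg(model, choices)]]
}

#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, `x` not constant.
#' @param input_unit recorded on the result for unit-safe prediction.
#' @param fitted_on provenance text.
#' @return A [linear_model()] with `r_squared` = 1 - SS_res/SS_tot.
#' @export
fit_linear <- function(x, y, input_unit = "clo", fitted_on = "user fit") {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 paired points", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("x is constant: degenerate design", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  linear_model(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = 1 - ss_res / ss_tot,
    n_points = length(x), input_unit = input_unit, fitted_on = fitted_on
  )
}

#' Intercept-only refit at a fixed slope
#'
#' Keeps the slope of an existing summation convention and adjusts only the
#' intercept: intercept = mean(y) - slope * mean(x) (the least-squares
#' solution under the slope constraint). The reported R squared is computed
#' against the constrained fit and is never above the unconstrained one.
#'
#' @param x,y numeric vectors of equal length, `n >= 2`.
#' @param slope the fixed slope.
#' @inheritParams fit_linear
#' @return A [linear_model()].
#' @export
fit_intercept_fixed_slope <- function(x, y, slope, input_unit = "clo",
                                      fitted_on = "fixed-slope refit") {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need at least 2 paired points", call. = FALSE)
  }
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  linear_model(
    slope = slope, intercept = intercept,
    r_squared = max(0, 1 - ss_res / ss_tot),
    n_points = length(x), input_unit = input_unit, fitted_on = fitted_on
  )
}

#' Refit the summation or area-factor models from a wardrobe
#'
#' Rebuilds the regression inputs from the packaged (or user) wardrobe
#' tables and refits:
#' \describe{
#'   \item{`icl_ou` / `icl_incident`}{measured ensemble I_cl (clo) against
#'     the summed item I_clu (clo) of the ensemble's composition, restricted
#'     to the named group; `fixed_slope` switches to the intercept-only
#'     refit of the standard slope.}
#'   \item{`fcl`}{measured f_cl against measured I_cl (clo) over all
#'     ensembles.}
#' }
#'
#' @param wardrobe a wardrobe, see [load_wardrobe()].
#' @param target `"fcl"`, `"icl_ou"` or `"icl_incident"`.
#' @param fixed_slope optional slope to hold fixed (summation targets only).
#' @return A [linear_model()] with provenance.
#' @examples
#' refit_model(load_wardrobe(), "fcl")
#' @export
refit_model <- function(wardrobe, target = c("fcl", "icl_ou", "icl_incident"),
                        fixed_slope = NULL) {
  target <- match.arg(target)
  ens <- wardrobe$ensembles
  if (target == "fcl") {
    if (!is.null(fixed_slope)) {
      stop("fixed_slope applies to the summation targets only", call. = FALSE)
    }
    return(fit_linear(ens$icl_clo, ens$fcl, input_unit = "clo",
                      fitted_on = sprintf("fcl ~ icl_clo, %d ensembles",
                                          nrow(ens))))
  }
  grp <- if (target == "icl_ou") "operational_uniform" else "incident"
  sub <- ens[ens$group == grp, ]
  x <- vapply(sub$composition,
              function(cc) sum_item_insulation(cc, wardrobe$items)$iclu_clo,
              numeric(1))
  y <- sub$icl_clo
  prov <- sprintf("icl_clo ~ sum(iclu_clo), %d %s ensembles", nrow(sub), grp)
  if (is.null(fixed_slope)) {
    fit_linear(x, y, input_unit = "clo", fitted_on = prov)
  } else {
    fit_intercept_fixed_slope(x, y, fixed_slope, input_unit = "clo",
                              fitted_on = paste(prov, "(fixed slope)"))
  }
}
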