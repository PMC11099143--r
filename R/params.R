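#' Decision-value parameter sets
#'
#' A `pat_params` object is a named coefficient vector for one decision-value
#' model. The base model carries an intercept, main effects of standardized
#' money, shocks, action context and bradycardia, and the money:shocks,
#' money:ac, shocks:ac interactions. Each "freezing" variant adds exactly one
#' bradycardia interaction: with shocks (`av`, aversive value), with the
#' standardized money-shock difference (`vc`, value comparison), or with the
#' action context (`ai`, action invigoration). `full` allows every
#' bradycardia interaction simultaneously (the single-model analogue of the
#' task-effect regression with all dhr terms).
#'
#' @param values named numeric vector; names must equal
#'   `model_terms(kind)`.
#' @param kind one of `"base"`, `"av"`, `"vc"`, `"ai"`, `"full"`.
#' @return a `pat_params` object.
#' @export
param_set <- function(values, kind = c("base", "av", "vc", "ai", "full")) {
  kind <- match.arg(kind)
  terms <- model_terms(kind)
  if (is.null(names(values)) || !identical(names(values), terms))
    stop("values must be named exactly: ", paste(terms, collapse = ", "),
         call. = FALSE)
  structure(as.numeric(stats::setNames(values, terms)),
            names = terms, kind = kind, class = "pat_params")
}

#' @rdname param_set
#' @export
model_terms <- function(kind = c("base", "av", "vc", "ai", "full")) {
  kind <- match.arg(kind)
  base <- c("(Intercept)", "z_money", "z_shocks", "z_money:z_shocks",
            "ac", "z_dhr", "z_money:ac", "z_shocks:ac")
  extra <- switch(kind,
    base = character(0),
    av   = "z_shocks:z_dhr",
    vc   = "z_dms:z_dhr",
    ai   = "ac:z_dhr",
    full = c("z_money:z_dhr", "z_shocks:z_dhr", "ac:z_dhr",
             "z_money:z_shocks:z_dhr", "z_money:ac:z_dhr",
             "z_shocks:ac:z_dhr"))
  c(base, extra)
}

#' @rdname param_set
#' @export
param_kind <- function(params) {
  stopifnot(inherits(params, "pat_params"))
  attr(params, "kind")
}

#' Group-level parameter estimates of the four decision-value models
#'
#' Returns the group-level coefficient row for the requested model, on the
#' standardized-predictor scale, as used to generate trial-wise decision
#' values for the model-based analysis and to parameterize the simulator's
#' choice agents.
#'
#' @param kind one of `"base"`, `"av"`, `"vc"`, `"ai"`.
#' @return a `pat_params` object.
#' @export
#' @examples
#' pat_group_params("base")
pat_group_params <- function(kind = c("base", "av", "vc", "ai")) {
  kind <- match.arg(kind)
  rows <- list(
    base = c(0.73, 1.54, -1.10, 0.41, 0.07, 0.05, -0.28, 0.09),
    av   = c(0.73, 1.54, -1.11, 0.40, 0.07, 0.04, -0.28, 0.09, 0.07),
    vc   = c(0.73, 1.55, -1.11, 0.40, 0.07, 0.03, -0.28, 0.09, -0.09),
    ai   = c(0.73, 1.54, -1.10, 0.40, 0.07, 0.05, -0.28, 0.09, 0.05))
  param_set(stats::setNames(rows[[kind]], model_terms(kind)), kind)
}

# Design matrix for the decision-value family. `data` must carry the pooled
# standardized columns z_money, z_shocks, z_dms, z_dhr and the sum-coded
# action context ac_code (-1 active / +1 passive). One code path serves the
# base, freezing and full models.
choice_design <- function(data, kind = c("base", "av", "vc", "ai", "full")) {
  kind <- match.arg(kind)
  need <- c("z_money", "z_shocks", "z_dms", "z_dhr", "ac_code")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks standardized columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(data$ac_code %in% c(-1, 1)))
    stop("ac_code must be -1 (active) or +1 (passive)", call. = FALSE)
  m <- data$z_money; s <- data$z_shocks
  ms <- data$z_dms; hr <- data$z_dhr; ac <- data$ac_code
  cols <- list(`(Intercept)` = rep(1, nrow(data)),
               z_money = m, z_shocks = s,
               `z_money:z_shocks` = m * s,
               ac = ac, z_dhr = hr,
               `z_money:ac` = m * ac, `z_shocks:ac` = s * ac,
               `z_shocks:z_dhr` = s * hr,
               `z_dms:z_dhr` = ms * hr,
               `ac:z_dhr` = ac * hr,
               `z_money:z_dhr` = m * hr,
               `z_money:z_shocks:z_dhr` = m * s * hr,
               `z_money:ac:z_dhr` = m * ac * hr,
               `z_shocks:ac:z_dhr` = s * ac * hr)
  terms <- model_terms(kind)
  do.call(cbind, stats::setNames(cols[terms], terms))
}
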