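#' z-standardize a neuropsychological battery
#'
#' Standardizes every variable with mean and SD taken from a reference sample
#' (the baseline cohort), storing the parameters so that follow-up batteries
#' can be standardized on the baseline scale. Variables on a "higher = worse"
#' scale (Trail-Making times, ADAS free-recall errors) are negated first so
#' that every standardized column reads "higher = better".
#'
#' @param battery Data frame or matrix of raw test scores (subjects x
#'   variables).
#' @param params Optional parameters from a previous call (`variable`,
#'   `mean`, `sd`, `negated`); if supplied, those are applied instead of
#'   being estimated.
#' @param negate Variables to sign-flip before standardization.
#' @return List with `z` (standardized matrix) and `params` (data frame of
#'   per-variable mean, SD and negation flag, computed after negation).
#' @export
zstandardize <- function(battery, params = NULL,
                         negate = negated_battery_variables()) {
  x <- as.matrix(battery)
  if (nrow(x) < 2 && is.null(params))
    stop("zstandardize: at least 2 subjects are needed to estimate parameters")
  if (is.null(params)) {
    neg <- colnames(x) %in% negate
    x[, neg] <- -x[, neg]
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    if (any(sdv == 0))
      stop("zstandardize: zero variance in variable(s): ",
           paste(colnames(x)[sdv == 0], collapse = ", "))
    params <- data.frame(variable = colnames(x), mean = mu, sd = sdv,
                         negated = neg, row.names = NULL,
                         stringsAsFactors = FALSE)
  } else {
    m <- match(colnames(x), params$variable)
    if (anyNA(m))
      stop("zstandardize: no stored parameters for: ",
           paste(colnames(x)[is.na(m)], collapse = ", "))
    params <- params[m, ]
    x[, params$negated] <- -x[, params$negated]
    mu <- params$mean; sdv <- params$sd
  }
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  list(z = z, params = params)
}

#' Extract rotated components and composite weights from a battery
#'
#' Principal component analysis on the correlation matrix of the standardized
#' battery; components with eigenvalue >= 1.0 (Kaiser criterion) are
#' retained and, when more than one is kept, obliquely rotated (promax,
#' kappa = 4, on the pattern matrix). Components are reflected so that the
#' majority of their salient variables load positively, and a variable enters
#' a component's composite only if its absolute pattern loading reaches the
#' threshold (0.50).
#'
#' @param z Standardized battery matrix from [zstandardize()].
#' @param threshold Absolute loading needed for inclusion (0.50).
#' @param rotation `"promax"` (default) or `"none"`.
#' @param kappa Promax power.
#' @return Object of class `composite_weights`: `loadings` (variable x
#'   component pattern matrix), `eigenvalues`, `included` (named list of
#'   variable sets per component), `threshold`, `rotation`, and `z_params`
#'   (filled by [derive_composite_weights()] wrappers when available).
#' @export
extract_components <- function(z, threshold = 0.50,
                               rotation = c("promax", "none"), kappa = 4) {
  rotation <- match.arg(rotation)
  z <- as.matrix(z)
  cm <- stats::cor(z)
  if (any(!is.finite(cm))) stop("extract_components: degenerate correlation matrix")
  eg <- eigen(cm, symmetric = TRUE)
  if (eg$values[1] < 1) stop("extract_components: no component reaches eigenvalue 1")
  k <- sum(eg$values >= 1.0)
  L <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(k)]), k)
  rownames(L) <- colnames(z)
  if (k > 1 && rotation == "promax") {
    rot <- stats::promax(L, m = kappa)
    L <- unclass(rot$loadings)
  }
  # reflect each component so its salient variables load positively
  for (j in seq_len(ncol(L)))
    if (sum(L[abs(L[, j]) >= threshold / 2, j]) < 0) L[, j] <- -L[, j]
  colnames(L) <- paste0("C", seq_len(ncol(L)))
  included <- lapply(seq_len(ncol(L)), function(j)
    rownames(L)[abs(L[, j]) >= threshold])
  names(included) <- colnames(L)
  structure(list(loadings = L, eigenvalues = eg$values, included = included,
                 threshold = threshold, rotation = rotation, z_params = NULL),
            class = "composite_weights")
}

#' @export
print.composite_weights <- function(x, ...) {
  cat(sprintf("<composite_weights> %d component(s) (Kaiser), rotation: %s\n",
              ncol(x$loadings), x$rotation))
  print(round(x$loadings, 3))
  for (j in names(x$included))
    cat(sprintf("%s includes (|loading| >= %.2f): %s\n", j, x$threshold,
                paste(x$included[[j]], collapse = ", ")))
  invisible(x)
}

#' Build composite scores from standardized variables and weights
#'
#' A component's composite is the weighted average of its included
#' standardized variables, with the pattern loadings as weights:
#' `sum(loading * z) / sum(|loading|)` over the included set.
#'
#' @param z Standardized battery matrix.
#' @param weights A `composite_weights` object.
#' @param components Which components to build (default: all).
#' @return Matrix subjects x components of composite scores.
#' @export
build_composites <- function(z, weights, components = colnames(weights$loadings)) {
  z <- as.matrix(z)
  out <- sapply(components, function(j) {
    vars <- weights$included[[j]]
    if (length(vars) == 0) stop("build_composites: component ", j,
                                " has no included variables")
    missing_v <- setdiff(vars, colnames(z))
    if (length(missing_v))
      stop("build_composites: missing included variable(s): ",
           paste(missing_v, collapse = ", "))
    w <- weights$loadings[vars, j]
    as.numeric(z[, vars, drop = FALSE] %*% w / sum(abs(w)))
  })
  rownames(out) <- rownames(z)
  out
}

#' Composite scores for a reduced follow-up battery
#'
#' Re-applies the baseline weights to the variables available at follow-up:
#' follow-up raw scores are standardized with the stored baseline parameters,
#' each component's included set is restricted to the available variables,
#' and the weights are renormalized over that restricted set.
#'
#' @param followup_battery Data frame/matrix of follow-up raw scores; its
#'   variables must be a subset of the baseline battery.
#' @param weights Baseline `composite_weights`.
#' @param z_params Baseline standardization parameters from [zstandardize()].
#' @return Matrix subjects x components (components with no available
#'   variable are dropped).
#' @export
followup_composites <- function(followup_battery, weights, z_params) {
  zs <- zstandardize(followup_battery, params = z_params)
  avail <- colnames(zs$z)
  restricted <- weights
  restricted$included <- lapply(weights$included, intersect, avail)
  keep <- vapply(restricted$included, length, 1L) > 0
  if (!any(keep))
    stop("followup_composites: no baseline variable available at follow-up")
  build_composites(zs$z, restricted,
                   components = names(restricted$included)[keep])
}

#' Identify the memory and executive components by their loadings
#'
#' Labels each retained component by the battery block (episodic memory vs
#' attention/executive) whose variables dominate its included set.
#'
#' @param weights A `composite_weights` built from the standard battery.
#' @return Named character vector mapping component name to `"memory"` or
#'   `"ef"`.
#' @export
label_components <- function(weights) {
  lay <- battery_layout()
  vapply(names(weights$included), function(j) {
    vars <- weights$included[[j]]
    blocks <- lay$block[match(vars, lay$variable)]
    if (length(blocks) == 0) return(NA_character_)
    names(sort(table(blocks), decreasing = TRUE))[1]
  }, character(1))
}
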