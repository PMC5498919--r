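#' Assemble a preprocessed feature matrix
#'
#' Optional natural-log transform of marker concentrations followed by
#' per-marker centering and scaling to unit (sample) variance. Penalized
#' coefficients are scale-sensitive, so the preprocessing parameters are
#' retained and travel with every fitted model, allowing new subjects to be
#' scored on the training scale.
#'
#' @param levels Matrix or data.frame of marker concentrations, one row per
#'   subject, named columns.
#' @param labels Case indicator (logical, 0/1, or `"case"`/`"control"`);
#'   1/`TRUE`/`"case"` = lung cancer.
#' @param log_transform Apply `log()` first (requires strictly positive
#'   levels). Default `TRUE`.
#' @param standardize Center and scale each marker. Default `TRUE`.
#' @return Object of class `feature_matrix`: `x` (preprocessed matrix), `y`
#'   (0/1 outcome), `marker_names`, `preprocessing` (`log_transform`,
#'   `center`, `scale`).
#' @export
feature_matrix <- function(levels, labels, log_transform = TRUE,
                           standardize = TRUE) {
  x <- as.matrix(levels)
  if (is.null(colnames(x))) stop("marker columns must be named")
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("marker levels contain missing values")
  y <- as.numeric(as_case_indicator(labels))
  if (length(y) != nrow(x)) stop("labels length must match rows of levels")
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (log_transform) {
    if (any(x <= 0)) stop("log transform requires strictly positive levels")
    x <- log(x)
  }
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    if (any(scl == 0))
      stop("zero-variance marker: ",
           paste(colnames(x)[scl == 0], collapse = ", "))
    x <- scale(x, center = ctr, scale = scl)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
    names(ctr) <- names(scl) <- colnames(x)
  }
  structure(
    list(x = x, y = y, marker_names = colnames(x),
         preprocessing = list(log_transform = log_transform,
                              center = ctr, scale = scl)),
    class = "feature_matrix")
}

#' Penalty grid for an elasticnet path
#'
#' Log-spaced decreasing grid from `lambda_max` (the smallest penalty at
#' which every coefficient is zero, `max_j |<x_j, y - mean(y)>| / (n *
#' alpha)`) down to `lambda_max * lambda_min_ratio`.
#'
#' @param fm A [feature_matrix()].
#' @param alpha Lasso share of the penalty, in (0, 1].
#' @param n_lambda Number of grid points (default 100).
#' @param lambda_min_ratio Ratio of the smallest to largest penalty
#'   (default 1e-3).
#' @return Strictly decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(fm, alpha = 0.95, n_lambda = 100,
                        lambda_min_ratio = 1e-3) {
  stopifnot(inherits(fm, "feature_matrix"), alpha > 0, alpha <= 1,
            n_lambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1)
  n <- nrow(fm$x)
  lmax <- max(abs(crossprod(fm$x, fm$y - mean(fm$y)))) / (n * alpha)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit the elasticnet-logistic penalty path
#'
#' Minimizes the mean negative Bernoulli log-likelihood plus
#' `lambda * (alpha * sum|beta_j| + (1 - alpha)/2 * sum beta_j^2)` (intercept
#' unpenalized) at every penalty of a decreasing grid, warm-starting each
#' solution from the previous one. Solutions are iterated until the
#' subgradient (KKT) conditions of the exact logistic objective hold within
#' `kkt_tol`; cyclic coordinate updates make fits deterministic for a given
#' row order.
#'
#' @inheritParams lambda_grid
#' @param lambda Optional explicit decreasing penalty grid; overrides
#'   `n_lambda` / `lambda_min_ratio`.
#' @param kkt_tol Convergence tolerance on the exact-objective KKT residual
#'   (default 1e-8).
#' @param max_outer Maximum proximal-Newton iterations per grid point.
#' @return Object of class `enet_path`: `lambdas`, `beta` (markers x
#'   penalties), `intercepts`, `kkt`, `alpha`, `marker_names`,
#'   `preprocessing`.
#' @export
fit_path <- function(fm, alpha = 0.95, n_lambda = 100,
                     lambda_min_ratio = 1e-3, lambda = NULL,
                     kkt_tol = 1e-8, max_outer = 200) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(lambda))
    lambda <- lambda_grid(fm, alpha, n_lambda, lambda_min_ratio)
  if (is.unsorted(rev(lambda), strictly = TRUE) && length(lambda) > 1L)
    stop("lambda grid must be strictly decreasing")
  fit <- enet_path_cpp(fm$x, fm$y, lambda, alpha, kkt_tol = kkt_tol,
                       max_outer = max_outer)
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)[1]
    stop(sprintf(
      "elasticnet fit did not converge at lambda = %.6g (%d outer iterations, KKT residual %.3g)",
      lambda[bad], fit$iterations[bad], fit$kkt[bad]))
  }
  beta <- fit$beta
  dimnames(beta) <- list(fm$marker_names, NULL)
  structure(
    list(lambdas = lambda, beta = beta, intercepts = fit$intercept,
         kkt = fit$kkt, alpha = alpha, marker_names = fm$marker_names,
         preprocessing = fm$preprocessing),
    class = "enet_path")
}

#' Extract one model from a fitted path
#'
#' @param path An [fit_path()] result.
#' @param lambda Penalty of the wanted model; must match a grid point (within
#'   floating-point tolerance).
#' @return Object of class `enet_model`: `intercept`, `beta` (named, on the
#'   preprocessed scale), `lambda`, `alpha`, `preprocessing`.
#' @export
path_model <- function(path, lambda) {
  stopifnot(inherits(path, "enet_path"))
  i <- which(abs(path$lambdas - lambda) <=
               1e-12 * pmax(1, abs(path$lambdas)))
  if (length(i) != 1L) stop("lambda does not match a unique grid point")
  new_enet_model(path$intercepts[i], path$beta[, i], path$lambdas[i],
                 path$alpha, path$preprocessing)
}

new_enet_model <- function(intercept, beta, lambda, alpha, preprocessing) {
  structure(
    list(intercept = unname(intercept), beta = beta, lambda = lambda,
         alpha = alpha, preprocessing = preprocessing,
         marker_names = names(beta)),
    class = "enet_model")
}

#' Panel membership of a fitted model
#'
#' Markers whose coefficient is exactly zero at the fitted penalty are
#' excluded from the panel by the lasso component.
#'
#' @param model An `enet_model`.
#' @return Character vector of markers with non-zero coefficients.
#' @export
panel_markers <- function(model) {
  stopifnot(inherits(model, "enet_model"))
  names(model$beta)[model$beta != 0]
}

#' Score subjects with a fitted model
#'
#' Applies the model's stored preprocessing (log transform, centering,
#' scaling) to raw marker concentrations, then returns the linear predictor
#' `intercept + beta . x`. Higher scores mean higher cancer risk; since the
#' AUC is rank-based, the linear predictor and the logistic probability give
#' identical ROC results, so the linear predictor is the canonical score.
#'
#' @param model An `enet_model`.
#' @param levels Matrix or data.frame of raw marker concentrations containing
#'   every model marker (extra columns are ignored).
#' @return Numeric score per subject.
#' @export
enet_score <- function(model, levels) {
  stopifnot(inherits(model, "enet_model"))
  x <- as.matrix(as.data.frame(levels)[,
         intersect(colnames(as.data.frame(levels)), model$marker_names),
         drop = FALSE])
  miss <- setdiff(model$marker_names, colnames(x))
  if (length(miss))
    stop("missing marker column(s): ", paste(miss, collapse = ", "))
  x <- x[, model$marker_names, drop = FALSE]
  storage.mode(x) <- "double"
  pp <- model$preprocessing
  if (pp$log_transform) {
    if (any(x <= 0)) stop("log transform requires strictly positive levels")
    x <- log(x)
  }
  x <- sweep(sweep(x, 2L, pp$center[model$marker_names], `-`),
             2L, pp$scale[model$marker_names], `/`)
  drop(model$intercept + x %*% model$beta)
}

#' @param object An `enet_model`.
#' @param newdata Raw marker concentrations to score.
#' @param type `"link"` for the linear predictor (default) or `"response"`
#'   for the logistic probability.
#' @param ... Unused.
#' @rdname enet_score
#' @export
predict.enet_model <- function(object, newdata, type = c("link", "response"),
                               ...) {
  type <- match.arg(type)
  eta <- enet_score(object, newdata)
  if (type == "response") 1 / (1 + exp(-eta)) else eta
}

#' Freeze a model to a human-readable text file
#'
#' Serializes an `enet_model` (penalty, mixing, preprocessing, coefficients)
#' at full double precision so a trained classifier can be shipped and later
#' applied unchanged to a blinded validation cohort. [read_model()] restores
#' it exactly.
#'
#' @param model An `enet_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "enet_model"))
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  lines <- c(
    "# lungpanel elasticnet model",
    paste0("alpha: ", num(model$alpha)),
    paste0("lambda: ", num(model$lambda)),
    paste0("log_transform: ", tolower(model$preprocessing$log_transform)),
    paste0("intercept: ", num(model$intercept)),
    "marker,center,scale,beta",
    vapply(model$marker_names, function(mk)
      paste(mk, num(model$preprocessing$center[[mk]]),
            num(model$preprocessing$scale[[mk]]),
            num(model$beta[[mk]]), sep = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Restore a frozen model
#'
#' @param path File written by [write_model()].
#' @return The `enet_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(ln) != 1L) stop("model file lacks field '", key, "'")
    trimws(sub("^[^:]+:", "", ln))
  }
  tab_start <- which(lines == "marker,center,scale,beta")
  if (length(tab_start) != 1L) stop("model file lacks coefficient table")
  tab <- read.csv(text = lines[tab_start:length(lines)],
                  stringsAsFactors = FALSE)
  beta <- stats::setNames(tab$beta, tab$marker)
  new_enet_model(
    intercept = as.numeric(kv("intercept")),
    beta = beta,
    lambda = as.numeric(kv("lambda")),
    alpha = as.numeric(kv("alpha")),
    preprocessing = list(
      log_transform = identical(kv("log_transform"), "true"),
      center = stats::setNames(tab$center, tab$marker),
      scale = stats::setNames(tab$scale, tab$marker)))
}

#' Checksum of a frozen model file
#'
#' @param path Model file path.
#' @return MD5 digest string.
#' @export
model_checksum <- function(path) {
  unname(tools::md5sum(path))
}

#' @export
print.enet_model <- function(x, ...) {
  nz <- panel_markers(x)
  cat(sprintf(
    "<enet_model> lambda = %.4g, alpha = %.2f, panel of %d marker(s): %s\n",
    x$lambda, x$alpha, length(nz),
    if (length(nz)) paste(nz, collapse = ", ") else "(intercept only)"))
  invisible(x)
}

#' @export
print.enet_path <- function(x, ...) {
  cat(sprintf(
    "<enet_path> %d penalties from %.4g down to %.4g (alpha = %.2f), %d markers\n",
    length(x$lambdas), max(x$lambdas), min(x$lambdas), x$alpha,
    length(x$marker_names)))
  invisible(x)
}
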