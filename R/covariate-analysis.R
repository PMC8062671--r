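#' Covariate stack: co-registered raster layers
#'
#' A named collection of `raster_grid` layers sharing origin, cell size and
#' shape — the terrain, vegetation, climate and human variables of the
#' ignition-risk analysis (distance to roads, distance to powerline,
#' housing density, population density, elevation, slope, aspect, tree %,
#' shrub %, grass %, Tmax, VPDmax).
#'
#' @param layers named list of `raster_grid`s.
#' @return object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    abort("Layers must have unique non-empty names",
          class = "firescape_argument_error")
  }
  ref <- layers[[1]]
  for (l in layers) {
    stopifnot(inherits(l, "raster_grid"))
    if (!isTRUE(all.equal(l$origin, ref$origin)) ||
        l$cell_size != ref$cell_size ||
        l$n_rows != ref$n_rows || l$n_cols != ref$n_cols) {
      abort("All layers must share origin, cell size and shape",
            class = "firescape_argument_error")
    }
  }
  structure(list(layers = layers), class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  ref <- x$layers[[1]]
  cat(sprintf("<covariate_stack> %d layers on %d x %d cells of %g m\n",
              length(x$layers), ref$n_rows, ref$n_cols, ref$cell_size))
  cat("  ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

stack_matrix <- function(stack) {
  vapply(stack$layers, function(l) as.vector(l$values),
         numeric(stack$layers[[1]]$n_rows * stack$layers[[1]]$n_cols))
}

#' Pairwise Pearson correlation between raster layers
#'
#' Computes `Corr_ij = Cov_ij / (sd_i sd_j)` with the `N - 1` sample
#' covariance `Cov_ij = sum_k (Z_ik - mu_i)(Z_jk - mu_j) / (N - 1)` over
#' the unmasked cells of every layer pair — the raster correlation screen
#' applied before multivariate modelling.
#'
#' @param stack a `covariate_stack` (>= 2 layers).
#' @param mask optional logical vector/matrix over cells (`TRUE` = keep).
#' @return symmetric correlation matrix of class `correlation_matrix` with
#'   unit diagonal, dimnames from the layer names.
#' @export
raster_correlation <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "covariate_stack"))
  Z <- stack_matrix(stack)
  if (ncol(Z) < 2) {
    abort("Need at least 2 layers", class = "firescape_argument_error")
  }
  keep <- stats::complete.cases(Z)
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  if (sum(keep) < 3) {
    abort("Need at least 3 unmasked cells", class = "firescape_argument_error")
  }
  Z <- Z[keep, , drop = FALSE]
  sds <- apply(Z, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance layer(s): ",
                 paste(colnames(Z)[sds == 0], collapse = ", ")),
          class = "firescape_degenerate_error")
  }
  m <- cor(Z)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  class(m) <- c("correlation_matrix", class(m))
  m
}

#' Drop collinear variables by greedy correlation screening
#'
#' Removes variables until no off-diagonal `|r|` exceeds the threshold: at
#' each step the variable with the largest mean `|r|` to the remaining
#' variables is dropped from the offending pairs, unless it appears in
#' `keep_rules` and some unprotected variable is also involved in a
#' violation — mirroring the common manual practice of preferring one
#' variable of each correlated pair on subject-matter grounds.
#'
#' @param matrix a `correlation_matrix`.
#' @param threshold correlation magnitude above which a pair violates
#'   (default 0.5).
#' @param keep_rules optional character vector of variables to keep in
#'   preference when choosing which of a correlated pair to drop.
#' @return list with `retained` (character), `removed` (character, in
#'   removal order) and `log` (tibble of step, removed, mean_abs_r).
#' @export
filter_correlated <- function(matrix, threshold = 0.5, keep_rules = NULL) {
  stopifnot(inherits(matrix, "correlation_matrix") || (is.matrix(matrix) &&
            isSymmetric(unclass(matrix))))
  m <- abs(unclass(matrix))
  vars <- colnames(m)
  removed <- character(0)
  log_rows <- list()
  step <- 0L
  repeat {
    sub <- m[setdiff(vars, removed), setdiff(vars, removed), drop = FALSE]
    off <- sub
    diag(off) <- 0
    if (all(off <= threshold)) break
    violating <- colnames(off)[apply(off > threshold, 2, any)]
    droppable <- setdiff(violating, keep_rules)
    if (length(droppable) == 0) droppable <- violating
    mean_r <- vapply(droppable, function(v) {
      mean(off[v, setdiff(colnames(off), v)])
    }, numeric(1))
    worst <- droppable[order(-mean_r, droppable)][1]
    step <- step + 1L
    log_rows[[step]] <- tibble(step = step, removed = worst,
                               mean_abs_r = mean_r[[worst]])
    removed <- c(removed, worst)
  }
  list(
    retained = setdiff(vars, removed),
    removed = removed,
    log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
      tibble(step = integer(0), removed = character(0),
             mean_abs_r = numeric(0))
  )
}

#' Principal component analysis of gridded covariates
#'
#' Eigendecomposition of the covariance matrix of the (optionally
#' standardized) variables. Standardization (the correlation matrix) is
#' the default because the variables span incommensurate units (km,
#' houses/km^2, degrees, %, degC, hPa). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param table a `grid_dataset` tibble, `covariate_stack`, or plain
#'   data frame of numeric variables.
#' @param standardize use the correlation rather than covariance matrix
#'   (default `TRUE`).
#' @param variables optional subset of variable names.
#' @return object of class `pca_result`: list with `eigenvalues`
#'   (descending), `loadings` (variables x components, orthonormal),
#'   `variance_fraction`, `cumulative_fraction`, `center`, `scale`,
#'   `scores`.
#' @export
pca_covariates <- function(table, standardize = TRUE, variables = NULL) {
  X <- if (inherits(table, "covariate_stack")) {
    stack_matrix(table)
  } else {
    df <- as.data.frame(table)
    num <- vapply(df, is.numeric, logical(1))
    drop_cols <- c("cell_id", "cx", "cy", "presence")
    as.matrix(df[, setdiff(names(df)[num], drop_cols), drop = FALSE])
  }
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (ncol(X) < 2) {
    abort("Need at least 2 variables", class = "firescape_argument_error")
  }
  if (nrow(X) <= ncol(X)) {
    abort("Need more observations than variables",
          class = "firescape_argument_error")
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = standardize)
  ev <- pr$sdev^2
  load <- pr$rotation
  scores <- pr$x
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rank_def <- sum(ev < max(ev) * 1e-12)
  if (rank_def > 0) {
    warn(paste0("Rank deficiency: ", rank_def,
                " near-zero eigenvalue(s)"))
  }
  structure(
    list(eigenvalues = ev, loadings = load,
         variance_fraction = ev / sum(ev),
         cumulative_fraction = cumsum(ev) / sum(ev),
         center = pr$center,
         scale = if (standardize) pr$scale else rep(1, ncol(X)),
         scores = scores),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", length(x$eigenvalues), "components\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", head(x$variance_fraction, 6)), collapse = " "),
      "\n")
  invisible(x)
}

#' Aggregate ignitions and covariates onto an analysis grid
#'
#' Divides the study window into square analysis cells (default 3 km) and
#' builds the design table of the ignition-presence model: per cell a
#' binary presence flag (1 iff at least one ignition point falls in the
#' cell; cells are the half-open rectangles `[x, x + s) x [y, y + s)`, so
#' assignment is a partition) and the mean of every covariate layer over
#' the stack cells whose centres fall in the analysis cell. Points outside
#' the window are excluded and counted in the `diagnostics` attribute.
#'
#' @param catalog a `fire_catalog` (may be `NULL` for covariates only).
#' @param stack a `covariate_stack`.
#' @param cell_size analysis cell edge in metres (default 3000).
#' @param study_window `c(xmin, ymin, xmax, ymax)`; defaults to the stack
#'   extent.
#' @return tibble of class `grid_dataset`: one row per cell with `cell_id`,
#'   `cx`, `cy` (cell centres), `presence`, and one column per layer.
#' @export
grid_aggregate <- function(catalog, stack, cell_size = 3000,
                           study_window = NULL) {
  stopifnot(inherits(stack, "covariate_stack"), cell_size > 0)
  ref <- stack$layers[[1]]
  if (is.null(study_window)) {
    study_window <- c(ref$origin[1],
                      ref$origin[2] - ref$n_rows * ref$cell_size,
                      ref$origin[1] + ref$n_cols * ref$cell_size,
                      ref$origin[2])[c(1, 2, 3, 4)]
    study_window <- c(xmin = study_window[1], ymin = study_window[2],
                      xmax = study_window[3], ymax = study_window[4])
  }
  xmin <- study_window[[1]]; ymin <- study_window[[2]]
  xmax <- study_window[[3]]; ymax <- study_window[[4]]
  ncx <- ceiling((xmax - xmin) / cell_size)
  ncy <- ceiling((ymax - ymin) / cell_size)
  cell_of <- function(x, y) {
    cxi <- floor((x - xmin) / cell_size)
    cyi <- floor((y - ymin) / cell_size)
    inside <- x >= xmin & x < xmin + ncx * cell_size &
      y >= ymin & y < ymin + ncy * cell_size
    idx <- cyi * ncx + cxi + 1
    idx[!inside] <- NA_integer_
    idx
  }
  n_cells <- ncx * ncy
  # covariate averages from stack cell centres
  cc <- cell_centers(ref)
  gx <- rep(cc$x, each = ref$n_rows)
  gy <- rep(cc$y, times = ref$n_cols)
  gidx <- cell_of(gx, gy)
  ok <- !is.na(gidx)
  covs <- lapply(stack$layers, function(l) {
    v <- as.vector(l$values)
    s <- rowsum(v[ok], gidx[ok])
    cnt <- rowsum(rep(1, sum(ok)), gidx[ok])
    out <- rep(NA_real_, n_cells)
    out[as.integer(rownames(s))] <- s / cnt
    out
  })
  presence <- rep(0L, n_cells)
  n_outside <- 0L
  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "fire_catalog"))
    pidx <- cell_of(catalog$records$x, catalog$records$y)
    n_outside <- sum(is.na(pidx))
    presence[unique(pidx[!is.na(pidx)])] <- 1L
  }
  ids <- seq_len(n_cells)
  cxi <- (ids - 1) %% ncx
  cyi <- (ids - 1) %/% ncx
  out <- tibble(
    cell_id = ids,
    cx = xmin + (cxi + 0.5) * cell_size,
    cy = ymin + (cyi + 0.5) * cell_size,
    presence = presence
  )
  for (nm in names(covs)) out[[nm]] <- covs[[nm]]
  attr(out, "diagnostics") <- list(n_outside = n_outside,
                                   n_cells = n_cells,
                                   cell_size = cell_size)
  class(out) <- c("grid_dataset", class(out))
  out
}

#' Logistic regression of ignition presence on gridded covariates
#'
#' Fits `ln(P / (1 - P)) = w0 + w1 x1 + ... + wn xn` by maximum likelihood
#' (iteratively reweighted least squares via [stats::glm()]), where `P` is
#' the probability that a cell saw at least one ignition. Wald standard
#' errors and two-sided p-values are reported per coefficient.
#' Non-convergence and (quasi-)complete separation (fitted probabilities
#' numerically at 0 or 1) are flagged, never silently ignored.
#'
#' @param grid a `grid_dataset`.
#' @param variables covariate names to include (default: all layer
#'   columns).
#' @return object of class `logistic_fit`: list with `coefficients`
#'   (tibble: term, estimate, std_error, p_value), `converged`,
#'   `separation`, `n`, `n_presence`, and the underlying `glm` object as
#'   `model`.
#' @export
logistic_fit <- function(grid, variables = NULL) {
  stopifnot(inherits(grid, "grid_dataset"))
  if (is.null(variables)) {
    variables <- setdiff(names(grid), c("cell_id", "cx", "cy", "presence"))
  }
  stopifnot(all(variables %in% names(grid)))
  df <- as.data.frame(grid)[, c("presence", variables), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$presence)) < 2) {
    abort("Response has a single class; cannot fit",
          class = "firescape_fit_error")
  }
  form <- if (length(variables) == 0) {
    presence ~ 1
  } else {
    stats::as.formula(paste("presence ~",
                            paste(sprintf("`%s`", variables),
                                  collapse = " + ")))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  eps <- .Machine$double.eps^0.5
  separation <- sep_warn || any(fit$fitted.values < eps |
                                  fit$fitted.values > 1 - eps)
  if (separation) {
    warn("Possible complete separation: fitted probabilities at 0/1")
  }
  if (!fit$converged) {
    warn("IRLS did not converge")
  }
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  terms <- gsub("`", "", terms)
  structure(
    list(
      coefficients = tibble(term = terms,
                            estimate = sm[, "Estimate"],
                            std_error = sm[, "Std. Error"],
                            p_value = sm[, "Pr(>|z|)"]),
      converged = fit$converged,
      separation = separation,
      n = nrow(df),
      n_presence = sum(df$presence),
      model = fit
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d cells, %d with ignitions%s\n",
              x$n, x$n_presence,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients)
  invisible(x)
}
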