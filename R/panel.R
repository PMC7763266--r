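#' Construct a multivariate time-series panel
#'
#' Bundles a panel of `p` time series of common length `n` with a per-series
#' exponential-family label. The panel is the basic input of every inference
#' function in the package: each series may follow a different distribution
#' (Gaussian, binomial, Poisson, gamma or inverse-Gaussian), and the
#' family label decides which GLM likelihood and weight matrix are used when
#' that series is the regression target.
#'
#' Family-specific domain checks are enforced at construction time:
#' binomial series must take values in \{0, 1\}, Poisson series must be
#' non-negative integers, and gamma / inverse-Gaussian series must be
#' strictly positive. Missing values are rejected.
#'
#' @param data A data frame or matrix with one column per series and one row
#'   per time point (time running down the rows).
#' @param families Character vector of family labels, one of `"gaussian"`,
#'   `"binomial"`, `"poisson"`, `"gamma"`, `"inverse_gaussian"`. Either
#'   unnamed and of length `ncol(data)` (matched by position), or named by
#'   series.
#' @return An object of class `ts_panel`: a list with elements `values`
#'   (an `n x p` numeric matrix), `families` and `names`.
#' @examples
#' df <- data.frame(a = rnorm(50), b = rpois(50, 1))
#' pan <- ts_panel(df, c(a = "gaussian", b = "poisson"))
#' pan
#' @export
ts_panel <- function(data, families) {
  values <- as.matrix(data)
  if (!is.numeric(values)) {
    stop("panel values must be numeric", call. = FALSE)
  }
  n <- nrow(values)
  p <- ncol(values)
  if (n < 1L) stop("panel must contain at least one time point", call. = FALSE)
  if (p < 1L) stop("panel must contain at least one series", call. = FALSE)
  nms <- colnames(values)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  colnames(values) <- nms

  families <- match_families(families, nms)
  for (j in seq_len(p)) {
    check_series_domain(values[, j], families[[j]], nms[[j]])
  }
  structure(
    list(values = values, families = families, names = nms),
    class = "ts_panel"
  )
}

hggm_family_names <- c(
  "gaussian", "binomial", "poisson", "gamma", "inverse_gaussian"
)

match_families <- function(families, nms) {
  p <- length(nms)
  families <- unlist(families, use.names = TRUE)
  if (!is.null(names(families)) && all(nzchar(names(families)))) {
    missing <- setdiff(nms, names(families))
    if (length(missing) > 0) {
      stop("no family label for series: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    families <- families[nms]
  } else if (length(families) == 1L) {
    families <- rep(families, p)
  } else if (length(families) != p) {
    stop("`families` must have one entry per series", call. = FALSE)
  }
  families <- as.character(families)
  bad <- !(families %in% hggm_family_names)
  if (any(bad)) {
    stop("unknown family label(s): ", paste(unique(families[bad]), collapse = ", "),
         "; expected one of ", paste(hggm_family_names, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(families, nms)
}

check_series_domain <- function(x, family, name) {
  if (anyNA(x)) {
    stop("series '", name, "' contains missing values", call. = FALSE)
  }
  ok <- switch(family,
    gaussian = TRUE,
    binomial = all(x %in% c(0, 1)),
    poisson = all(x >= 0 & x == round(x)),
    gamma = all(x > 0),
    inverse_gaussian = all(x > 0)
  )
  if (!ok) {
    stop("series '", name, "' violates the ", family, " domain (",
         switch(family,
           binomial = "values must be 0 or 1",
           poisson = "values must be non-negative integers",
           "values must be strictly positive"),
         ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("<ts_panel> ", ncol(x$values), " series x ", nrow(x$values),
      " time points\n", sep = "")
  fam <- paste0(x$names, " [", x$families, "]")
  cat("  ", paste(fam, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble ts_panel
#' @export
as_tibble.ts_panel <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$values))
}

#' Build the lagged fixed-design matrix for one target series
#'
#' Rewrites the lag-`d` vector-autoregressive problem for a target series as
#' a fixed-design GLM regression. The design has one row per response time
#' point `t = d+1, ..., n` and one block of `d` columns per candidate parent
#' series; column `l` of block `j` holds the value of series `j` at `d - l`
#' steps before ... more precisely, for response row `t` (predicting time
#' `t + d`) it holds `x_j[t + d - l]`, so each block reads from the most
#' recent lag (`l = 1`) to the most distant (`l = d`). Any consistent
#' within-block ordering yields identical model selection because the MML
#' criterion is invariant to column permutations under an identity prior
#' covariance.
#'
#' No intercept column is added: the regression is fit through the origin.
#'
#' @param panel A [ts_panel()].
#' @param lag Positive integer lag `d`. The identifiability condition
#'   `n - d > p * d` is enforced.
#' @param target Index or name of the target series.
#' @return An object of class `lag_design` with elements `X` (the
#'   `(n-d) x (d*p)` design matrix), `y` (the response vector, observations
#'   `d+1 ... n` of the target), `column_map` (a tibble mapping each column
#'   to its source series and lag offset), and bookkeeping fields.
#' @examples
#' pan <- ts_panel(data.frame(a = 1:11, b = rep(0, 11)),
#'                 c("gaussian", "gaussian"))
#' des <- build_lag_design(pan, lag = 2, target = "a")
#' dim(des$X)
#' @export
build_lag_design <- function(panel, lag, target) {
  stopifnot(inherits(panel, "ts_panel"))
  d <- as.integer(lag)
  if (length(d) != 1L || is.na(d) || d < 1L) {
    stop("`lag` must be a positive integer", call. = FALSE)
  }
  n <- nrow(panel$values)
  p <- ncol(panel$values)
  if (n - d <= p * d) {
    stop("need n - d > p * d (here n - d = ", n - d, ", p * d = ", p * d,
         "); the lagged design would be rank-deficient by construction",
         call. = FALSE)
  }
  target <- resolve_series(panel, target)

  nr <- n - d
  X <- matrix(0, nrow = nr, ncol = d * p)
  map <- vector("list", d * p)
  for (j in seq_len(p)) {
    for (l in seq_len(d)) {
      col <- (j - 1L) * d + l
      # response row t predicts time t + d; regressor value is x_j[t + d - l]
      X[, col] <- panel$values[(d - l + 1L):(n - l), j]
      map[[col]] <- list(series = panel$names[[j]], series_index = j, lag = l)
    }
  }
  column_map <- dplyr::bind_rows(lapply(map, tibble::as_tibble))
  column_map$column <- seq_len(d * p)

  structure(
    list(
      X = X,
      y = panel$values[(d + 1L):n, target],
      column_map = column_map,
      target = target,
      target_name = panel$names[[target]],
      family = panel$families[[target]],
      d = d, p = p, n = n,
      selected = seq_len(p)
    ),
    class = "lag_design"
  )
}

resolve_series <- function(panel, target) {
  if (is.character(target)) {
    idx <- match(target, panel$names)
    if (is.na(idx)) stop("unknown series '", target, "'", call. = FALSE)
    return(idx)
  }
  target <- as.integer(target)
  if (length(target) != 1L || is.na(target) ||
      target < 1L || target > ncol(panel$values)) {
    stop("`target` out of range", call. = FALSE)
  }
  target
}

#' Restrict a full lagged design to a candidate parent set
#'
#' Keeps exactly the column blocks of the selected series, preserving the
#' block order of the full design. An empty candidate set yields a
#' zero-column matrix (the intercept-free null model).
#'
#' @param full A `lag_design` built by [build_lag_design()] over all `p`
#'   series.
#' @param Q Logical (or 0/1) vector of length `p`; `Q[j]` selects series `j`
#'   as a candidate parent. Self-loops are allowed.
#' @return A `lag_design` whose `X` has `d * sum(Q)` columns.
#' @export
subset_design <- function(full, Q) {
  stopifnot(inherits(full, "lag_design"))
  Q <- as.logical(Q)
  if (length(Q) != full$p || anyNA(Q)) {
    stop("`Q` must be a logical vector of length p = ", full$p, call. = FALSE)
  }
  sel <- which(Q)
  cols <- as.vector(outer(seq_len(full$d), (sel - 1L) * full$d, `+`))
  cols <- sort(cols)
  out <- full
  out$X <- full$X[, cols, drop = FALSE]
  out$column_map <- full$column_map[cols, , drop = FALSE]
  out$selected <- sel
  out
}

#' @export
print.lag_design <- function(x, ...) {
  cat("<lag_design> target '", x$target_name, "' (", x$family, "), lag ",
      x$d, ": ", nrow(x$X), " x ", ncol(x$X), " design\n", sep = "")
  invisible(x)
}
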