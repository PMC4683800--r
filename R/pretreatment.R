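#' Savitzky-Golay smoothing and derivatives
#'
#' Per-spectrum local polynomial filtering: within a sliding window of
#' `window` points a polynomial of degree `polyorder` is fitted by least
#' squares and its value (or `deriv`-th derivative) at the window center
#' replaces the point. Edges are handled by fitting the polynomial on the
#' window truncated to the available points. Derivatives are divided by
#' `step_nm^deriv` so they are expressed per nm and comparable across grids.
#'
#' @param X Spectra matrix (samples x points) or a single numeric vector.
#' @param window Odd window length in points (e.g. 9 or 11).
#' @param polyorder Polynomial degree; must be < `window` and >= `deriv`.
#' @param deriv Derivative order 0, 1 or 2.
#' @param step_nm Grid increment used to scale derivatives (default 1).
#' @return Filtered matrix of the same shape as `X`.
#' @export
sg_filter <- function(X, window, polyorder = if (deriv == 2) 3 else 2,
                      deriv = 0, step_nm = 1) {
  if (window %% 2 == 0) stop("window length must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1)
  n <- ncol(X)
  if (window > n) stop("window longer than the spectrum")
  h <- (window - 1L) %/% 2L

  # projection row mapping window values -> deriv-th derivative at position
  # `at` (offset units); premultiplied by deriv! for the polynomial derivative
  proj_row <- function(offsets, at) {
    A <- outer(offsets, 0:polyorder, `^`)
    G <- solve(crossprod(A), t(A))   # (polyorder+1) x window
    factorial(deriv) * G[deriv + 1L, ]
  }

  interior <- proj_row(-h:h, 0)
  out <- matrix(0, nrow(X), n)
  # interior via filter-style matrix product over shifted columns
  idx <- (h + 1L):(n - h)
  acc <- matrix(0, nrow(X), length(idx))
  for (j in seq_len(window)) {
    acc <- acc + interior[j] * X[, idx + (j - h - 1L), drop = FALSE]
  }
  out[, idx] <- acc
  # edges: truncated windows
  for (p in seq_len(h)) {
    offs <- (1L - p):h                      # left edge, position p
    out[, p] <- X[, seq_len(length(offs)), drop = FALSE] %*% proj_row(offs, 0)
    offs_r <- -h:(n - (n - p + 1L))          # right edge, position n-p+1
    cols <- (n - length(offs_r) + 1L):n
    out[, n - p + 1L] <- X[, cols, drop = FALSE] %*% proj_row(offs_r, 0)
  }
  out <- out / step_nm^deriv
  dimnames(out) <- dimnames(X)
  if (vec) out[1, ] else out
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum to mean 0 and sample standard deviation 1,
#' removing per-spectrum multiplicative and additive scatter effects without
#' reference to any other spectrum.
#'
#' @param X Spectra matrix (samples x points).
#' @param tol Minimum admissible row standard deviation.
#' @return Transformed matrix.
#' @export
snv <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  bad <- which(s <= tol)
  if (length(bad)) {
    nm <- rownames(X)[bad[1]]
    stop("near-constant spectrum cannot be SNV-transformed: sample ",
         if (is.null(nm)) bad[1] else nm)
  }
  (X - mu) / s
}

#' Unit-norm normalization
#'
#' Scales each spectrum to unit Euclidean norm. (Vendor software offers
#' several "normalization" variants; this package fixes the meaning to the
#' L2 norm.)
#'
#' @param X Spectra matrix.
#' @param tol Minimum admissible row norm.
#' @return Transformed matrix.
#' @export
normalize_rows <- function(X, tol = 1e-12) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm <= tol)) stop("zero spectrum cannot be normalized")
  X / nrm
}

#' Multiplicative scatter correction
#'
#' `msc_fit` stores the calibration mean spectrum as the scatter reference;
#' `msc_apply` regresses each spectrum on that reference (slope + intercept,
#' ordinary least squares) and returns `(spectrum - intercept) / slope`.
#' New spectra are corrected with the stored calibration reference only, so
#' no validation-set statistics leak into the transform.
#'
#' @param X_cal Calibration spectra (>= 2 rows).
#' @return `msc_fit`: a `fitted_pretreatment` holding the reference spectrum.
#' @export
msc_fit <- function(X_cal) {
  X_cal <- as.matrix(X_cal)
  if (nrow(X_cal) < 2) stop("MSC needs at least 2 calibration spectra")
  fitted_pretreatment("msc", list(reference = colMeans(X_cal)),
                      n_cal = nrow(X_cal))
}

#' @rdname msc_fit
#' @param fitted Result of `msc_fit`.
#' @param X Spectra to correct.
#' @param tol Minimum admissible |slope|.
#' @export
msc_apply <- function(fitted, X, tol = 1e-10) {
  stopifnot(inherits(fitted, "fitted_pretreatment"), fitted$method == "msc")
  X <- as.matrix(X)
  ref <- fitted$state$reference
  if (ncol(X) != length(ref)) stop("spectrum length does not match reference")
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  slope <- (X %*% rc) / denom
  if (any(abs(slope) < tol)) stop("MSC slope below tolerance for some sample")
  intercept <- rowMeans(X) - slope * mean(ref)
  out <- (X - as.vector(intercept)) / as.vector(slope)
  dimnames(out) <- dimnames(X)
  out
}

#' Orthogonal signal correction
#'
#' Removes from the spectra the dominant variation that is orthogonal to the
#' response, before calibration. Per component: the leading principal score
#' of the (centered) calibration spectra is projected orthogonal to the
#' centered response, a weight vector `w` is computed as the minimum-norm
#' solution of `X w = t` (so scores are exactly reproducible on the
#' calibration set), and the score/loading pair is deflated from `X`. The
#' stored weights and loadings replay the removal on new spectra using
#' calibration state only.
#'
#' @param X_cal Calibration spectra.
#' @param c_cal Calibration concentrations.
#' @param n_components Number of orthogonal components to remove (>= 1).
#' @param ridge Relative ridge added to `X X^T` for the minimum-norm solve.
#' @return A `fitted_pretreatment` with weights/loadings; apply with
#'   [osc_apply()].
#' @export
osc_fit <- function(X_cal, c_cal, n_components = 1, ridge = 1e-10) {
  X_cal <- as.matrix(X_cal)
  n <- nrow(X_cal)
  if (length(c_cal) != n) stop("c_cal length must match rows of X_cal")
  if (n_components < 1) stop("n_components must be >= 1")
  x_mean <- colMeans(X_cal)
  Xc <- sweep(X_cal, 2, x_mean)
  yc <- c_cal - mean(c_cal)
  yss <- sum(yc^2)
  if (yss <= 0) stop("response has zero variance")
  W <- P <- vector("list", n_components)
  for (a in seq_len(n_components)) {
    sv <- svd(Xc, nu = 1, nv = 0)
    t0 <- sv$u[, 1] * sv$d[1]
    # orthogonalize the score against the response
    t_orth <- t0 - yc * sum(yc * t0) / yss
    # minimum-norm w with Xc w = t_orth (rows of Xc span the score space)
    G <- tcrossprod(Xc)
    diag(G) <- diag(G) + ridge * mean(diag(G))
    w <- crossprod(Xc, solve(G, t_orth))
    tt <- Xc %*% w
    p <- crossprod(Xc, tt) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, p)
    W[[a]] <- as.vector(w)
    P[[a]] <- as.vector(p)
  }
  fitted_pretreatment("osc",
                      list(x_mean = x_mean, weights = W, loadings = P,
                           n_components = n_components),
                      n_cal = n)
}

#' @rdname osc_fit
#' @param fitted Result of `osc_fit`.
#' @param X Spectra to correct (calibration or new).
#' @export
osc_apply <- function(fitted, X) {
  stopifnot(inherits(fitted, "fitted_pretreatment"), fitted$method == "osc")
  X <- as.matrix(X)
  st <- fitted$state
  Xc <- sweep(X, 2, st$x_mean)
  for (a in seq_len(st$n_components)) {
    tt <- Xc %*% st$weights[[a]]
    Xc <- Xc - tcrossprod(tt, st$loadings[[a]])
  }
  out <- sweep(Xc, 2, st$x_mean, `+`)
  dimnames(out) <- dimnames(X)
  out
}

#' Wavelet denoising of spectra
#'
#' Per-spectrum discrete wavelet transform (Daubechies family, periodic
#' convolution after symmetric padding to a multiple of `2^level`), soft
#' thresholding of the detail coefficients with the universal threshold
#' `sigma * sqrt(2 log n)` where `sigma` is estimated from the median
#' absolute deviation of the finest-level details, and reconstruction to the
#' original length.
#'
#' @param X Spectra matrix or vector.
#' @param wavelet Wavelet name; `"db4"` (default), `"db2"` or `"haar"`.
#' @param level Decomposition depth; default `floor(log2(n)) - 4`, at least 1.
#' @param threshold `"universal"` (default) or a fixed numeric threshold.
#' @return Denoised matrix of the same shape.
#' @export
wavelet_denoise <- function(X, wavelet = "db4", level = NULL,
                            threshold = "universal") {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1)
  n <- ncol(X)
  h <- wavelet_filter(wavelet)
  if (is.null(level)) level <- max(1L, floor(log2(n)) - 4L)
  level <- as.integer(level)
  if (2^level > n) stop("decomposition level too deep for ", n, " points")
  out <- t(apply(X, 1, function(x) dwt_denoise_one(x, h, level, threshold)))
  dimnames(out) <- dimnames(X)
  if (vec) out[1, ] else out
}

# orthonormal scaling filters
wavelet_filter <- function(name) {
  switch(tolower(name),
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314453414, 0.83651630373780772,
            0.22414386804201339, -0.12940952255126037),
    db4 = c(0.23037781330889650, 0.71484657055291564,
            0.63088076792985890, -0.02798376941685985,
            -0.18703481171909308, 0.03084138183556076,
            0.03288301166688520, -0.01059740178506903),
    stop("unknown wavelet name: ", name)
  )
}

# single-level periodic analysis/synthesis
dwt_step <- function(s, h) {
  N <- length(s)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  half <- N %/% 2L
  a <- d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% N) + 1L
    a[k] <- sum(h * s[idx])
    d[k] <- sum(g * s[idx])
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h) {
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  N <- 2L * length(a)
  s <- numeric(N)
  for (k in seq_along(a)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% N) + 1L
    s[idx] <- s[idx] + h * a[k] + g * d[k]
  }
  s
}

dwt_denoise_one <- function(x, h, level, threshold) {
  n <- length(x)
  block <- 2L^level
  n_pad <- ceiling(n / block) * block
  pad <- n_pad - n
  # symmetric (reflective) padding on the right
  xs <- if (pad > 0) c(x, x[n:(n - pad + 1L)]) else x
  details <- vector("list", level)
  a <- xs
  for (l in seq_len(level)) {
    st <- dwt_step(a, h)
    a <- st$a
    details[[l]] <- st$d
  }
  thr <- if (identical(threshold, "universal")) {
    sigma <- stats::median(abs(details[[1]])) / 0.6745
    sigma * sqrt(2 * log(n_pad))
  } else as.numeric(threshold)
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  details <- lapply(details, soft)
  for (l in rev(seq_len(level))) a <- idwt_step(a, details[[l]], h)
  a[seq_len(n)]
}

#' Pretreatment specification and fitted state
#'
#' `pretreatment_spec` declares one stage of the pretreatment ladder;
#' `pipeline_fit` fits an ordered list of stages on the calibration data
#' (left to right, each stage consuming the previous stage's output) and
#' `pipeline_apply` replays the stored state on any spectra. Only MSC and
#' OSC carry calibration state; all other stages are stateless row-wise
#' transforms, so fitted pipelines never use statistics of the set they are
#' applied to.
#'
#' @param method One of `"raw"`, `"sg"`, `"sg1d"`, `"sg2d"`, `"snv"`,
#'   `"msc"`, `"osc"`, `"wds"`, `"normalize"`.
#' @param ... Method parameters: `window`/`polyorder` for the SG family,
#'   `n_components` for OSC, `wavelet`/`level`/`threshold` for WDS.
#' @return An object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(method, ...) {
  method <- match.arg(method, c("raw", "sg", "sg1d", "sg2d", "snv", "msc",
                                "osc", "wds", "normalize"))
  params <- list(...)
  defaults <- switch(method,
    sg = list(window = 9, polyorder = 2),
    sg1d = list(window = 11, polyorder = 2),
    sg2d = list(window = 11, polyorder = 3),
    osc = list(n_components = 1),
    wds = list(wavelet = "db4", level = NULL, threshold = "universal"),
    list()
  )
  params <- utils::modifyList(defaults, params)
  if (method %in% c("sg", "sg1d", "sg2d")) {
    if (params$window %% 2 == 0) stop("SG window must be odd")
    if (params$window < params$polyorder + 2) {
      stop("SG window must be >= polyorder + 2")
    }
  }
  if (method == "osc" && params$n_components < 1) {
    stop("OSC needs n_components >= 1")
  }
  structure(list(method = method, params = params),
            class = "pretreatment_spec")
}

fitted_pretreatment <- function(method, state, n_cal, params = list()) {
  structure(list(method = method, state = state, params = params,
                 n_cal = n_cal),
            class = "fitted_pretreatment")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  p <- if (length(x$params)) {
    paste0("(", paste(names(x$params), unlist(lapply(x$params, format)),
                      sep = "=", collapse = ", "), ")")
  } else ""
  cat("<pretreatment_spec> ", x$method, p, "\n", sep = "")
  invisible(x)
}

#' A readable label for a pretreatment spec
#' @param spec A `pretreatment_spec`.
#' @return Character scalar such as `"SG(9)"` or `"OSC1"`.
#' @export
pretreatment_label <- function(spec) {
  switch(spec$method,
    raw = "Raw",
    sg = sprintf("SG(%d)", spec$params$window),
    sg1d = sprintf("SG(%d)+1D", spec$params$window),
    sg2d = sprintf("SG(%d)+2D", spec$params$window),
    snv = "SNV",
    msc = "MSC",
    osc = sprintf("OSC%d", spec$params$n_components),
    wds = "WDS",
    normalize = "Normalize"
  )
}

#' @rdname pretreatment_spec
#' @param specs Ordered list of `pretreatment_spec`.
#' @param X_cal Calibration spectra.
#' @param c_cal Calibration concentrations (required only if OSC appears).
#' @param step_nm Grid step for derivative scaling.
#' @return `pipeline_fit`: object of class `fitted_pipeline`.
#' @export
pipeline_fit <- function(specs, X_cal, c_cal = NULL, step_nm = 1) {
  if (inherits(specs, "pretreatment_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "pretreatment_spec")))
  X <- as.matrix(X_cal)
  fitted <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    f <- switch(sp$method,
      raw = fitted_pretreatment("raw", list(), nrow(X)),
      sg = fitted_pretreatment("sg", list(), nrow(X), sp$params),
      sg1d = fitted_pretreatment("sg1d", list(), nrow(X), sp$params),
      sg2d = fitted_pretreatment("sg2d", list(), nrow(X), sp$params),
      snv = fitted_pretreatment("snv", list(), nrow(X)),
      normalize = fitted_pretreatment("normalize", list(), nrow(X)),
      wds = fitted_pretreatment("wds", list(), nrow(X), sp$params),
      msc = msc_fit(X),
      osc = {
        if (is.null(c_cal)) stop("OSC in the pipeline requires c_cal")
        osc_fit(X, c_cal, sp$params$n_components)
      }
    )
    f$step_nm <- step_nm
    fitted[[i]] <- f
    X <- apply_one(f, X)
  }
  structure(list(stages = fitted, specs = specs, step_nm = step_nm),
            class = "fitted_pipeline")
}

apply_one <- function(f, X) {
  switch(f$method,
    raw = X,
    sg = sg_filter(X, f$params$window, f$params$polyorder, 0, f$step_nm),
    sg1d = sg_filter(X, f$params$window, f$params$polyorder, 1, f$step_nm),
    sg2d = sg_filter(X, f$params$window, f$params$polyorder, 2, f$step_nm),
    snv = snv(X),
    normalize = normalize_rows(X),
    wds = wavelet_denoise(X, f$params$wavelet, f$params$level,
                          f$params$threshold),
    msc = msc_apply(f, X),
    osc = osc_apply(f, X)
  )
}

#' @rdname pretreatment_spec
#' @param pipeline A `fitted_pipeline`.
#' @param X Spectra to transform.
#' @export
pipeline_apply <- function(pipeline, X) {
  stopifnot(inherits(pipeline, "fitted_pipeline"))
  X <- as.matrix(X)
  for (f in pipeline$stages) X <- apply_one(f, X)
  X
}
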