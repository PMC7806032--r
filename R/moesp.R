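#' Block-Hankel matrix of a multichannel series
#'
#' Stacks `s` block rows of the series: block row `i` holds the samples
#' `i, ..., i + N - s` of all channels (channel-major within each block), so
#' the result has `s * m` rows and `N - s + 1` columns for an N x m series.
#'
#' @param data Numeric vector or N x m matrix (channels in columns).
#' @param s Number of block rows (>= 1).
#' @return A `(s m) x (N - s + 1)` matrix.
#' @examples
#' block_hankel(c(1, 2, 3, 4), 2)  # rbind(1:3, 2:4)
#' @export
block_hankel <- function(data, s) {
  data <- as.matrix(data)
  N <- nrow(data); m <- ncol(data)
  if (s < 1 || s != round(s)) stop("s must be a positive integer")
  if (N < s) stop("series length (", N, ") shorter than s (", s, ")")
  nc <- N - s + 1L
  H <- matrix(0, s * m, nc)
  for (i in seq_len(s))
    H[(i - 1L) * m + seq_len(m), ] <- t(data[i + 0:(nc - 1L), , drop = FALSE])
  H
}

#' Fit a discrete-time state-space model by MOESP subspace identification
#'
#' Ordinary MOESP (Multivariable Output-Error State-sPace): input and output
#' block-Hankel matrices are stacked and LQ-factorized; the SVD of the part
#' of the output rows orthogonal to the input rows (the L22 block) estimates
#' the extended observability matrix and yields the singular-value spectrum
#' used for order selection. `C` is the first block row of the rank-`order`
#' column basis, `A` is solved from the shift invariance of the observability
#' matrix by least squares, and `B`, `D` and the initial state are obtained
#' by linear least squares of the simulated response against the measured
#' output. The procedure is deterministic: refitting the same data gives the
#' same model (up to the state basis, which is fixed by the SVD).
#'
#' When the identified `A` has eigenvalues outside the unit circle — which
#' happens when the best causal map is near-marginal and noise pushes the
#' estimate across the stability boundary — the simulated response used to
#' estimate `B`, `D`, `x0` (and any long-horizon prediction) diverges. By
#' default such eigenvalues are reflected into the unit disk
#' (`lambda -> 1 / Conj(lambda)`, preserving the frequency), a standard
#' stabilization for output-error subspace fits; set `stabilize = FALSE` for
#' the raw estimate.
#'
#' @param u Input series: N x m matrix (or vector).
#' @param y Output series: N x p matrix (or vector), same N.
#' @param order Model order n (default 3).
#' @param s Number of block rows (default 10; must exceed `order`).
#' @param rate_hz Optional sampling rate stored in the model.
#' @param stabilize Reflect unstable eigenvalues of `A` into the unit disk
#'   before the `B`/`D`/`x0` stage (default TRUE).
#' @return Object of class `moesp` with components `A`, `B`, `C`, `D`, `x0`,
#'   `sv` (singular-value spectrum), `order`, `m`, `p`, `s`, `fitted`,
#'   `residuals` and `n_samples`. Methods: [print.moesp()],
#'   [summary.moesp()], [coef.moesp()], [predict.moesp()], `fitted()`,
#'   `residuals()`.
#' @examples
#' set.seed(1)
#' u <- rnorm(500)
#' y <- as.numeric(stats::filter(u, 0.9, method = "recursive"))
#' fit <- moesp(u, y, order = 1)
#' eigen(fit$A)$values  # ~0.9
#' @export
moesp <- function(u, y, order = 3, s = 10, rate_hz = NULL, stabilize = TRUE) {
  u <- as.matrix(u); y <- as.matrix(y)
  N <- nrow(u); m <- ncol(u); p <- ncol(y)
  if (nrow(y) != N) stop("u and y must have the same number of samples")
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  if (s < order + 1) stop("need s >= order + 1 block rows")
  if (N < 2 * s * (m + p))
    stop("series too short for identification: need at least 2*s*(m+p) = ",
         2 * s * (m + p), " samples, got ", N)

  U <- block_hankel(u, s)
  Y <- block_hankel(y, s)
  # project the output rows onto the orthogonal complement of the input row
  # space (the L22 block of the LQ factorization, computed via an SVD of U
  # so rank-deficient inputs -- e.g. duplicated channels -- are handled
  # exactly); its left singular vectors estimate the extended observability
  # matrix
  su <- svd(t(U), nv = 0)
  r <- sum(su$d > max(dim(U)) * .Machine$double.eps * max(su$d, 0))
  YP <- if (r > 0) {
    P <- su$u[, seq_len(r), drop = FALSE]
    Y - (Y %*% P) %*% t(P)
  } else Y
  sv <- svd(YP)
  d <- sv$d

  yscale <- sqrt(mean(y^2))
  degenerate <- yscale == 0 || d[1] <= 1e-13 * max(1, yscale) * sqrt(N)
  if (degenerate) {
    # no signal in the output: return the zero model of the requested order
    A <- matrix(0, order, order)
    C <- matrix(0, p, order)
  } else {
    if (d[order] / d[1] < 1e-12)
      stop("ill-conditioned fit: observability singular value ", order,
           " is numerically zero; reduce the order or enrich the input")
    Gam <- sv$u[, seq_len(order), drop = FALSE] %*%
      diag(sqrt(d[seq_len(order)]), order)
    C <- Gam[seq_len(p), , drop = FALSE]
    G1 <- Gam[seq_len(p * (s - 1)), , drop = FALSE]
    G2 <- Gam[p + seq_len(p * (s - 1)), , drop = FALSE]
    qa <- qr(G1)
    if (qa$rank < order)
      stop("ill-conditioned fit: shift-invariance system for A is rank ",
           "deficient (rank ", qa$rank, " < order ", order, ")")
    A <- qr.coef(qa, G2)
    if (stabilize) A <- stabilize_A(A)
  }

  th <- estimate_bdx0(A, C, u, y)
  fitted <- ss_output_cpp(A, th$B, C, th$D, u, th$x0)
  structure(list(A = A, B = th$B, C = C, D = th$D, x0 = th$x0,
                 sv = d, order = order, m = m, p = p, s = s,
                 rate_hz = rate_hz, n_samples = N,
                 fitted = fitted, residuals = y - fitted,
                 call = match.call()),
            class = "moesp")
}

# Reflect eigenvalues outside the unit circle to 1/Conj(lambda) (same
# frequency, stable modulus). Leaves already-stable matrices untouched up to
# the identity, so exact recovery of stable systems is unaffected. Falls back
# to uniform shrinkage if the eigenvector matrix is numerically singular.
stabilize_A <- function(A, margin = 1 - 1e-10) {
  ev <- eigen(A)
  mods <- Mod(ev$values)
  if (all(mods <= 1)) return(A)
  lam <- ev$values
  out <- mods > 1
  lam[out] <- margin / Conj(lam[out])
  As <- tryCatch({
    V <- ev$vectors
    Re(V %*% diag(lam, length(lam)) %*% solve(V))
  }, error = function(e) NULL)
  if (is.null(As) || !all(is.finite(As)))
    As <- A * (margin / max(mods))
  As
}

# B, D and x0 are linear in the output once A and C are fixed: build the
# regressor from elementary responses (one short simulation per basis entry)
# and solve one least-squares problem. Rank-deficient cases (e.g. zero
# output) fall back to the minimum contribution via NA -> 0.
estimate_bdx0 <- function(A, C, u, y) {
  N <- nrow(u); m <- ncol(u); p <- nrow(C); n <- nrow(A)
  Phi <- matrix(0, N * p, n + n * m + p * m)
  zed <- matrix(0, N, 1)
  Bz <- matrix(0, n, 1); Dz <- matrix(0, p, 1)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    Phi[, i] <- as.vector(ss_output_cpp(A, Bz, C, Dz, zed, e))
  }
  col <- n
  for (j in seq_len(m)) for (i in seq_len(n)) {
    e <- matrix(0, n, 1); e[i, 1] <- 1
    col <- col + 1L
    Phi[, col] <- as.vector(ss_output_cpp(A, e, C, Dz,
                                          u[, j, drop = FALSE], numeric(n)))
  }
  for (j in seq_len(m)) for (i in seq_len(p)) {
    col <- col + 1L
    tmp <- matrix(0, N, p); tmp[, i] <- u[, j]
    Phi[, col] <- as.vector(tmp)
  }
  th <- qr.coef(qr(Phi), as.vector(y))
  th[is.na(th)] <- 0
  list(x0 = th[seq_len(n)],
       B = matrix(th[n + seq_len(n * m)], n, m),
       D = matrix(th[n + n * m + seq_len(p * m)], p, m))
}

#' Select a model order from the singular-value spectrum
#'
#' Default criterion: the largest gap in the log singular values (optionally
#' capped). `criterion = "fixed:<n>"` returns `<n>` regardless of the
#' spectrum — the pipeline default is `"fixed:3"`, a third-order model.
#'
#' @param sv Non-negative, non-increasing singular values.
#' @param criterion `"gap"` or `"fixed:<n>"`.
#' @param max_order Cap on the returned order (gap criterion only).
#' @return Integer order.
#' @examples
#' select_order(c(10, 5, 2, 1e-9, 1e-10))  # 3
#' select_order(c(10, 5), criterion = "fixed:3")  # 3
#' @export
select_order <- function(sv, criterion = "gap", max_order = NULL) {
  if (!length(sv)) stop("empty singular-value spectrum")
  if (is.character(criterion) && grepl("^fixed:", criterion)) {
    n <- as.integer(sub("^fixed:", "", criterion))
    if (is.na(n) || n < 1) stop("bad fixed order in criterion '", criterion, "'")
    return(n)
  }
  if (max(sv) < .Machine$double.eps)
    stop("degenerate data: all singular values below machine tolerance")
  k <- length(sv) - 1L
  if (!is.null(max_order)) k <- min(k, as.integer(max_order))
  if (k < 1) return(1L)
  svp <- pmax(sv, .Machine$double.xmin)
  drops <- log(svp[seq_len(k)]) - log(svp[1L + seq_len(k)])
  which.max(drops)
}

#' @export
print.moesp <- function(x, ...) {
  cat(sprintf("MOESP state-space model: order %d, %d input / %d output channels\n",
              x$order, x$m, x$p))
  cat("  singular values:", paste(signif(head(x$sv, 6), 3), collapse = ", "),
      if (length(x$sv) > 6) "...\n" else "\n")
  v <- tryCatch(vaf(x$fitted, x$fitted + x$residuals), error = function(e) NA)
  if (!is.na(v)) cat(sprintf("  training VAF: %.2f%%\n", v))
  invisible(x)
}

#' @export
summary.moesp <- function(object, ...) {
  y <- object$fitted + object$residuals
  per <- tryCatch(attr(vaf(object$fitted, y), "per_channel"),
                  error = function(e) rep(NA_real_, object$p))
  structure(list(order = object$order, m = object$m, p = object$p,
                 s = object$s, n_samples = object$n_samples,
                 eigenvalues = eigen(object$A, only.values = TRUE)$values,
                 sv = object$sv, per_channel_vaf = per,
                 n_parameters = object$order * object$m +
                   object$p * object$m + object$order),
            class = "summary.moesp")
}

#' @export
print.summary.moesp <- function(x, ...) {
  cat(sprintf("MOESP model summary: order %d (m = %d, p = %d, s = %d), %d samples\n",
              x$order, x$m, x$p, x$s, x$n_samples))
  cat(sprintf("  free parameters in B, D, x0 stage: %d\n", x$n_parameters))
  cat("  eigenvalues of A:",
      paste(format(zapsmall(x$eigenvalues, 6)), collapse = ", "), "\n")
  cat("  per-channel training VAF (%):",
      paste(sprintf("%.2f", x$per_channel_vaf), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.moesp <- function(object, ...)
  object[c("A", "B", "C", "D", "x0")]

#' @export
fitted.moesp <- function(object, ...) object$fitted

#' @export
residuals.moesp <- function(object, ...) object$residuals

#' Predict the output of a fitted state-space model
#'
#' Iterates `x(k+1) = A x(k) + B u(k)`, `y(k) = C x(k) + D u(k)` from `x0`
#' (zero by default; pass `object$x0` to reproduce the training fit).
#'
#' @param object A [moesp()] model.
#' @param u Input series, N x m.
#' @param x0 Initial state (default zero).
#' @param ... Unused.
#' @return N x p matrix of predicted outputs.
#' @export
predict.moesp <- function(object, u, x0 = NULL, ...) {
  u <- as.matrix(u)
  if (ncol(u) != object$m)
    stop("input has ", ncol(u), " channels, model expects ", object$m)
  if (is.null(x0)) x0 <- numeric(object$order)
  if (length(x0) != object$order) stop("x0 length must equal the model order")
  ss_output_cpp(object$A, object$B, object$C, object$D, u, as.numeric(x0))
}

#' Markov parameters (impulse-response coefficients) of a state-space model
#'
#' Returns `D, CB, CAB, ..., C A^(k-2) B` — similarity-invariant fingerprints
#' of the model, useful for comparing fits that may differ in state basis.
#'
#' @param object A [moesp()] model or a list with `A`, `B`, `C`, `D`.
#' @param n_terms Number of terms (default 20).
#' @return List of p x m matrices.
#' @export
markov_params <- function(object, n_terms = 20) {
  A <- object$A; B <- object$B; C <- object$C; D <- object$D
  out <- vector("list", n_terms)
  out[[1]] <- D
  Ak <- diag(nrow(A))
  for (k in seq_len(n_terms - 1)) {
    out[[k + 1]] <- C %*% Ak %*% B
    Ak <- Ak %*% A
  }
  out
}

#' Variance accounted for (VAF)
#'
#' Per output channel, `100 * (1 - var(y_hat - y) / var(y))` with the
#' population variance convention (divide by N); the pooled value is the
#' variance-weighted mean across channels, i.e.
#' `100 * (1 - sum(var(err)) / sum(var(y)))`. 100 indicates a perfect
#' prediction of all variability; 0 means no meaningful prediction; values
#' can be negative for predictions worse than the mean.
#'
#' @param y_hat Predicted series (vector or N x p matrix).
#' @param y Measured series, same shape; every channel must have positive
#'   variance.
#' @return Pooled VAF in percent, with attribute `per_channel`.
#' @examples
#' y <- cbind(1:4)
#' vaf(y, y)            # 100
#' vaf(0 * y, y)        # 0
#' @export
vaf <- function(y_hat, y) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!all(dim(y_hat) == dim(y))) stop("y_hat and y must have the same shape")
  popvar <- function(x) mean((x - mean(x))^2)
  vy <- apply(y, 2, popvar)
  if (any(vy <= 0))
    stop("undefined VAF: an output channel has zero variance")
  ve <- apply(y_hat - y, 2, popvar)
  per <- 100 * (1 - ve / vy)
  structure(100 * (1 - sum(ve) / sum(vy)), per_channel = per)
}

#' Estimate foot acceleration from hip, head or fused sensing
#'
#' Fits a MOESP state-space model with the selected sensor channels as input
#' (3 channels for hip or head, 6 stacked for fusion) and the 3-axis foot
#' acceleration as output, then scores the in-sample (identification) VAF of
#' the prediction. `per_axis = TRUE` instead fits three independent
#' single-input single-output models (axis to axis) and pools their VAF.
#'
#' @param recording A `perch_recording`.
#' @param source "hip", "head" or "fusion".
#' @param order Model order (default 3).
#' @param s Block rows for the subspace step (default 10).
#' @param window Optional `c(t0, t1)` in seconds restricting the fit.
#' @param train_samples Optional cap: fit and score on the first
#'   `train_samples` samples of the window only.
#' @param per_axis Fit per-axis SISO models instead of one MIMO model.
#' @return Object of class `perch_vaf`: `source`, `per_axis_vaf`,
#'   `pooled_vaf`, `n_train` and the fitted `model` (or list of models).
#' @export
estimate_foot_acc <- function(recording, source = c("hip", "head", "fusion"),
                              order = 3, s = 10, window = NULL,
                              train_samples = NULL, per_axis = FALSE) {
  if (!inherits(recording, "perch_recording")) stop("recording must be a perch_recording")
  source <- match.arg(source)
  rate <- recording$rate_hz
  N <- nrow(recording$foot)
  idx <- seq_len(N)
  if (!is.null(window)) {
    i0 <- max(1L, as.integer(floor(window[1] * rate)) + 1L)
    i1 <- min(N, as.integer(floor(window[2] * rate)))
    if (i1 <= i0) stop("window outside the recording")
    idx <- i0:i1
  }
  if (!is.null(train_samples)) {
    if (train_samples > length(idx))
      stop("train_samples exceeds the window length")
    idx <- idx[seq_len(train_samples)]
  }
  u <- switch(source,
              hip = recording$hip[idx, , drop = FALSE],
              head = recording$head[idx, , drop = FALSE],
              fusion = cbind(recording$hip[idx, , drop = FALSE],
                             recording$head[idx, , drop = FALSE]))
  y <- recording$foot[idx, , drop = FALSE]

  if (per_axis) {
    models <- lapply(1:3, function(a)
      moesp(u[, a, drop = FALSE], y[, a, drop = FALSE], order = order, s = s,
            rate_hz = rate))
    popvar <- function(x) mean((x - mean(x))^2)
    vy <- vapply(1:3, function(a) popvar(y[, a]), numeric(1))
    ve <- vapply(models, function(mfit) popvar(mfit$residuals), numeric(1))
    per <- 100 * (1 - ve / vy)
    pooled <- 100 * (1 - sum(ve) / sum(vy))
    model <- models
  } else {
    model <- moesp(u, y, order = order, s = s, rate_hz = rate)
    v <- vaf(model$fitted, y)
    per <- attr(v, "per_channel")
    pooled <- as.numeric(v)
  }
  structure(list(source = source,
                 per_axis_vaf = setNames(per, c("x", "y", "z")),
                 pooled_vaf = pooled, n_train = length(idx),
                 per_axis_fit = per_axis, model = model),
            class = "perch_vaf")
}

#' @export
print.perch_vaf <- function(x, ...) {
  cat(sprintf("Foot-acceleration estimate from %s sensing (%d samples%s)\n",
              x$source, x$n_train,
              if (isTRUE(x$per_axis_fit)) ", per-axis SISO" else ""))
  cat(sprintf("  pooled VAF %.2f%% (per axis: %s)\n", x$pooled_vaf,
              paste(sprintf("%s %.2f", names(x$per_axis_vaf), x$per_axis_vaf),
                    collapse = ", ")))
  invisible(x)
}

#' Save / load a fitted state-space model as JSON
#'
#' @param model A [moesp()] model.
#' @param path JSON file path.
#' @return `write_moesp` returns `path` invisibly; `read_moesp` a `moesp`
#'   object (without fitted values, which belong to the training data).
#' @export
write_moesp <- function(model, path) {
  jsonlite::write_json(list(A = model$A, B = model$B, C = model$C, D = model$D,
                            x0 = model$x0, sv = model$sv, order = model$order,
                            m = model$m, p = model$p, s = model$s,
                            rate_hz = model$rate_hz),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_moesp
#' @export
read_moesp <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  structure(list(A = mat(j$A), B = mat(j$B), C = mat(j$C), D = mat(j$D),
                 x0 = as.numeric(j$x0), sv = as.numeric(j$sv),
                 order = j$order, m = j$m, p = j$p, s = j$s,
                 rate_hz = j$rate_hz, n_samples = NA_integer_,
                 fitted = NULL, residuals = NULL),
            class = "moesp")
}
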