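#' Fit a PLS regression model (NIPALS)
#'
#' Partial least squares regression of a single response on a (typically
#' wide, collinear) descriptor matrix, by the NIPALS algorithm with
#' mean-centered X and y. Optional column scaling is off by default
#' (CoMFA-style fields share units). The fit is deterministic.
#'
#' @param X numeric matrix, n x p (kept descriptor columns).
#' @param y numeric response vector (pK_D), length n.
#' @param n_components number of latent variables; at most
#'   `min(n - 1, p)`.
#' @param scale logical; if TRUE, columns of X are scaled to unit variance
#'   (zero-variance columns are left unscaled).
#' @return object of class `pls_model` with centering/scaling vectors,
#'   weights/loadings, per-component coefficient matrix and the
#'   `n_components`-component regression vector `coefficients`.
#' @export
fit_pls <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (sd(y) == 0) stop("constant response")
  max_nc <- min(n - 1L, p)
  if (n_components < 1L || n_components > max_nc)
    stop("n_components out of range [1, ", max_nc, "]")

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  x_scale <- rep(1, p)
  if (scale) {
    s <- apply(X, 2, sd)
    x_scale <- ifelse(s > 0, s, 1)
  }
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, `/`)
  yc <- y - y_mean

  W <- matrix(0, p, n_components)   # X weights
  P <- matrix(0, p, n_components)   # X loadings
  Q <- numeric(n_components)        # y loadings
  Tm <- matrix(0, n, n_components)  # scores
  Xd <- Xc; yd <- yc
  actual <- 0L
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break  # X deflated to noise: no further components
    w <- w / wn
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yd * t_) / tt
    W[, a] <- w; P[, a] <- p_; Q[a] <- q_; Tm[, a] <- t_
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q_ * t_
    actual <- a
  }
  if (actual == 0L) stop("X carries no covariance with y")
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  Q <- Q[seq_len(actual)]
  Tm <- Tm[, seq_len(actual), drop = FALSE]

  # R = W (P'W)^{-1}: weights mapping original (centered) X to scores;
  # coefficients for k components are R[,1:k] %*% Q[1:k]
  Rmat <- W %*% solve(crossprod(P, W))
  coef_by_ncomp <- sapply(seq_len(actual), function(k)
    drop(Rmat[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)]))
  coef_by_ncomp <- matrix(coef_by_ncomp, nrow = p)

  structure(list(
    n_components = actual, requested_components = n_components,
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
    weights = W, loadings = P, y_loadings = Q, scores = Tm,
    coef_by_ncomp = coef_by_ncomp,
    coefficients = coef_by_ncomp[, actual]
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d descriptor column(s)\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict with a PLS model
#'
#' `y_hat = y_mean + ((x - x_mean)/x_scale) . coefficients`.
#'
#' @param object a `pls_model`.
#' @param newdata numeric vector (one row) or matrix with the kept-column
#'   layout of the training matrix.
#' @param n_components predict with the first k components (default: all
#'   fitted components).
#' @param ... unused.
#' @return numeric vector of predicted pK_D.
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("column layout mismatch: expected ", length(object$x_mean),
         " columns, got ", ncol(newdata))
  k <- if (is.null(n_components)) object$n_components else n_components
  if (k < 1L || k > object$n_components) stop("n_components out of range")
  b <- object$coef_by_ncomp[, k]
  Xc <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_scale, `/`)
  drop(object$y_mean + Xc %*% b)
}

#' Leave-one-out cross-validation (q2 and SDEP)
#'
#' Each sample is predicted by a model refit without it. `q2 = 1 -
#' PRESS/SS_tot` with SS_tot about the full-set mean (the standard CoMFA
#' convention); `sdep = sqrt(PRESS/n)`.
#'
#' @inheritParams fit_pls
#' @return list with `q2`, `sdep` and the vector of LOO `predictions`.
#' @export
loo_validate <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples for LOO")
  preds <- loo_predictions(X, y, n_components, scale = scale)
  press <- sum((y - preds)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(q2 = 1 - press / ss_tot, sdep = sqrt(press / n), predictions = preds)
}

# LOO predictions for every component count 1..n_components at once
# (columns of the returned matrix); literal per-sample refits.
loo_prediction_matrix <- function(X, y, n_components, scale = FALSE) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, n_components)
  for (i in seq_len(n)) {
    m <- fit_pls(X[-i, , drop = FALSE], y[-i], n_components, scale = scale)
    for (k in seq_len(min(n_components, m$n_components)))
      out[i, k] <- predict(m, X[i, ], n_components = k)
    if (m$n_components < n_components)
      out[i, (m$n_components + 1L):n_components] <- out[i, m$n_components]
  }
  out
}

loo_predictions <- function(X, y, n_components, scale = FALSE) {
  loo_prediction_matrix(X, y, n_components, scale = scale)[, n_components]
}

#' Select the number of PLS components by LOO q2
#'
#' Scans 1..`max_components` and returns the count maximizing leave-one-out
#' q2; ties (within 1e-10) are broken toward fewer components.
#'
#' @inheritParams fit_pls
#' @param max_components largest component count to consider (capped at
#'   `min(n - 2, p)` so every LOO refit is feasible).
#' @return integer, the selected component count.
#' @export
select_components <- function(X, y, max_components, scale = FALSE) {
  X <- as.matrix(X)
  if (max_components < 1L) stop("max_components must be >= 1")
  kmax <- min(max_components, nrow(X) - 2L, ncol(X))
  pm <- loo_prediction_matrix(X, y, kmax, scale = scale)
  ss_tot <- sum((y - mean(y))^2)
  q2 <- vapply(seq_len(kmax), function(k)
    1 - sum((y - pm[, k])^2) / ss_tot, numeric(1))
  min(which(q2 >= max(q2) - 1e-10))
}

# Training r2 of a fitted model
training_r2 <- function(model, X, y) {
  yhat <- predict(model, X)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' External validation (q2_ext and SDEP_ext)
#'
#' Predicts a held-out set and reports `q2_ext = 1 - PRESS_ext /
#' sum((y_test - mean(y_train))^2)` (training-mean denominator, the
#' standard QSAR convention) and `sdep_ext = sqrt(PRESS_ext / n_test)`.
#'
#' @param model a fitted `pls_model`.
#' @param X_test,y_test held-out descriptor rows and responses.
#' @param y_train_mean mean of the training responses.
#' @return list with `q2_ext`, `sdep_ext`, `predictions`.
#' @export
external_validate <- function(model, X_test, y_test, y_train_mean) {
  preds <- predict(model, X_test)
  press <- sum((y_test - preds)^2)
  ss <- sum((y_test - y_train_mean)^2)
  list(q2_ext = 1 - press / ss, sdep_ext = sqrt(press / length(y_test)),
       predictions = preds)
}

#' Grouped train/test split by ligand identity
#'
#' All records sharing a `ligand_id` land on the same side of the split
#' (the dataset contains the same ligand in several complexes; splitting
#' within a ligand would leak information). The split is seeded and targets
#' `test_fraction` of the records.
#'
#' @param ligand_ids character vector, one per record.
#' @param test_fraction fraction of records for the test side.
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
grouped_split <- function(ligand_ids, test_fraction = 0.2, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n <- length(ligand_ids)
  groups <- unique(ligand_ids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- sample(groups)
  target <- test_fraction * n
  test_groups <- character(0)
  n_test <- 0
  for (g in groups) {
    if (n_test >= target) break
    test_groups <- c(test_groups, g)
    n_test <- n_test + sum(ligand_ids == g)
  }
  test <- which(ligand_ids %in% test_groups)
  if (length(test) == 0L || length(test) == n)
    stop("degenerate split: empty train or test side")
  list(train = setdiff(seq_len(n), test), test = test)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run the three QSAR model protocols
#'
#' Protocol 1 trains on the full dataset (components chosen by LOO q2) and
#' reports training r2 plus LOO q2/SDEP. Protocol 2 fits on a seeded
#' ligand-grouped 80/20 split and reports external q2_ext/SDEP_ext on the
#' held-out 20%. Protocol 3 refits on the full dataset using the component
#' count selected in protocol 2.
#'
#' @param descriptors a `descriptor_matrix` (see
#'   [assemble_descriptor_matrix()]), or a plain matrix if `y` and
#'   `ligand_ids` are given.
#' @param y pK_D vector (taken from `descriptors` if absent).
#' @param ligand_ids ligand identifiers for the grouped split.
#' @param split_seed seed for the protocol-2 split.
#' @param test_fraction held-out fraction for protocol 2.
#' @param max_components upper bound for component selection.
#' @param scale passed to [fit_pls()].
#' @return list of class `protocol_reports` with elements `model1`,
#'   `model2`, `model3`; each carries `model`, `stats` and `split`.
#' @export
run_protocols <- function(descriptors, y = NULL, ligand_ids = NULL,
                          split_seed = 1, test_fraction = 0.2,
                          max_components = 8, scale = FALSE) {
  if (inherits(descriptors, "descriptor_matrix")) {
    X <- descriptors$X
    if (is.null(y)) y <- descriptors$y
    if (is.null(ligand_ids)) ligand_ids <- descriptors$ligand_ids
  } else X <- as.matrix(descriptors)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 records")
  if (is.null(ligand_ids)) ligand_ids <- as.character(seq_len(n))

  # Model 1: full dataset, internal validation
  nc1 <- select_components(X, y, max_components, scale = scale)
  m1 <- fit_pls(X, y, nc1, scale = scale)
  loo1 <- loo_validate(X, y, nc1, scale = scale)
  model1 <- list(protocol = "model1", model = m1,
                 stats = list(r2 = training_r2(m1, X, y),
                              q2 = loo1$q2, sdep = loo1$sdep),
                 split = list(train = seq_len(n), test = integer(0)))

  # Model 2: 80/20 ligand-grouped split, external validation
  sp <- grouped_split(ligand_ids, test_fraction, split_seed)
  Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
  nc2 <- select_components(Xtr, ytr, max_components, scale = scale)
  m2 <- fit_pls(Xtr, ytr, nc2, scale = scale)
  loo2 <- loo_validate(Xtr, ytr, nc2, scale = scale)
  ext <- external_validate(m2, X[sp$test, , drop = FALSE], y[sp$test],
                           mean(ytr))
  model2 <- list(protocol = "model2", model = m2,
                 stats = list(r2 = training_r2(m2, Xtr, ytr),
                              q2 = loo2$q2, sdep = loo2$sdep,
                              q2_ext = ext$q2_ext, sdep_ext = ext$sdep_ext),
                 split = sp)

  # Model 3: full dataset with protocol-2 parameters
  nc3 <- min(m2$n_components, n - 1L, ncol(X))
  m3 <- fit_pls(X, y, nc3, scale = scale)
  loo3 <- loo_validate(X, y, nc3, scale = scale)
  model3 <- list(protocol = "model3", model = m3,
                 stats = list(r2 = training_r2(m3, X, y),
                              q2 = loo3$q2, sdep = loo3$sdep),
                 split = list(train = seq_len(n), test = integer(0)))

  structure(list(model1 = model1, model2 = model2, model3 = model3),
            class = "protocol_reports")
}

#' @export
print.protocol_reports <- function(x, ...) {
  cat("<protocol_reports>\n")
  for (nm in names(x)) {
    s <- x[[nm]]$stats
    line <- sprintf("  %s: ncomp=%d r2=%.3f q2=%.3f sdep=%.3f",
                    nm, x[[nm]]$model$n_components, s$r2, s$q2, s$sdep)
    if (!is.null(s$q2_ext))
      line <- paste0(line, sprintf(" q2_ext=%.3f sdep_ext=%.3f",
                                   s$q2_ext, s$sdep_ext))
    cat(line, "\n")
  }
  invisible(x)
}

#' Serialize fitted models and descriptor layout to JSON
#'
#' @param reports a `protocol_reports`.
#' @param descriptors the `descriptor_matrix` the models were fit on.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_model_json <- function(reports, descriptors, file) {
  doc <- list(
    schema = "groovebind-qsar-model/1",
    grid = list(origin = descriptors$grid$origin,
                spacing = descriptors$grid$spacing,
                dims = descriptors$grid$dims),
    min_sigma = descriptors$min_sigma,
    kept_mask = which(descriptors$kept_mask),
    models = lapply(reports, function(r) list(
      protocol = r$protocol,
      n_components = r$model$n_components,
      x_mean = r$model$x_mean,
      x_scale = r$model$x_scale,
      y_mean = r$model$y_mean,
      coefficients = r$model$coefficients,
      stats = r$stats
    ))
  )
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
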