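# Latent-variable discriminant modelling: NIPALS PLS1 PLS-DA, Trygg-Wold
# OPLS-DA, VIP scores, cross-validated Q2 and label-permutation validation.
# The two-class response is encoded {0,1} and centered (PLS1: single
# response). A fixed sign convention (the feature with the largest absolute
# X-loading gets a positive loading) makes fits bit-reproducible.

# ---- internals -------------------------------------------------------------

# Match metadata labels to the sample order of an abundance table; plain
# label vectors are taken as already aligned with the rows of X.
align_labels <- function(x, y) {
  if (inherits(y, "sample_metadata")) {
    if (inherits(x, "abundance_table")) {
      idx <- match(ab_samples(x), y$sample_id)
      if (anyNA(idx)) {
        stop("table sample(s) missing from metadata: ",
             paste(utils::head(ab_samples(x)[is.na(idx)], 5), collapse = ", "),
             call. = FALSE)
      }
      return(y$group[idx])
    }
    return(y$group)
  }
  y
}

encode_labels <- function(y) {
  if (inherits(y, "sample_metadata")) y <- y$group
  y <- as.character(y)
  if (anyNA(y)) stop("class labels contain missing values", call. = FALSE)
  lv <- sort(unique(y))
  if (length(lv) != 2) stop("exactly two classes are required", call. = FALSE)
  if (setequal(lv, c("case", "control"))) lv <- c("control", "case")
  list(y01 = as.numeric(y == lv[2L]), negative = lv[1L], positive = lv[2L])
}

prep_x <- function(x) {
  if (inherits(x, "abundance_table")) x <- t(ab_values(x))
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("X must be numeric", call. = FALSE)
  if (ncol(x) == 0) stop("X has no features", call. = FALSE)
  x
}

center_scale <- function(X, scale) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (scale) {
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
    Xc <- sweep(Xc, 2L, scl, "/")
  } else {
    scl <- rep(1, ncol(X))
  }
  list(X = Xc, center = ctr, scale = scl)
}

# Flip the signs of one component so that the feature with the largest |p|
# has positive loading; t, w, p and q flip together, leaving t p' and t q
# invariant.
fix_sign <- function(w, t, p, q) {
  j <- which.max(abs(p))
  if (p[j] < 0) list(w = -w, t = -t, p = -p, q = -q)
  else list(w = w, t = t, p = p, q = q)
}

# NIPALS PLS1 on centered X / centered y. Returns unit-norm weights W,
# X-loadings P, y-loadings q (vector), scores T, and the deflated residuals.
nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); Q <- numeric(ncomp)
  Xd <- X; yd <- y
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-12) break
    pl <- crossprod(Xd, tt)[, 1L] / t2
    ql <- sum(yd * tt) / t2
    s <- fix_sign(w, tt, pl, ql)
    Xd <- Xd - tcrossprod(s$t, s$p)
    yd <- yd - s$q * s$t
    a <- k
    W[, k] <- s$w; P[, k] <- s$p; Tm[, k] <- s$t; Q[k] <- s$q
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       Tm = Tm[, seq_len(a), drop = FALSE], Q = Q[seq_len(a)],
       Xres = Xd, yres = yd, ncomp = a)
}

# Trygg-Wold orthogonal signal correction: removes up to n_orth components of
# y-orthogonal structured variation from centered X.
osc_filter <- function(X, y, n_orth) {
  p <- ncol(X)
  Wo <- matrix(0, p, max(n_orth, 0L)); Po <- matrix(0, p, max(n_orth, 0L))
  To <- matrix(0, nrow(X), max(n_orth, 0L))
  Xd <- X
  k <- 0L
  while (k < n_orth) {
    w <- crossprod(Xd, y)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- Xd %*% w
    pl <- crossprod(Xd, tt)[, 1L] / sum(tt^2)
    wo <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break  # no y-orthogonal structure left
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to)[, 1L] / sum(to^2)
    s <- fix_sign(wo, to, po, 0)
    Xd <- Xd - tcrossprod(s$t, s$p)
    k <- k + 1L
    Wo[, k] <- s$w; Po[, k] <- s$p; To[, k] <- s$t
  }
  list(X = Xd, W_orth = Wo[, seq_len(k), drop = FALSE],
       P_orth = Po[, seq_len(k), drop = FALSE],
       T_orth = To[, seq_len(k), drop = FALSE], n_orth = k)
}

# Fit the full model (no CV) on raw X with internal centering/scaling.
fit_core <- function(X, y01, model_kind, ncomp, n_orth, scale) {
  cs <- center_scale(X, scale)
  yc <- y01 - mean(y01)
  ssx <- sum(cs$X^2)
  ssy <- sum(yc^2)
  if (model_kind == "oplsda") {
    osc <- osc_filter(cs$X, yc, n_orth)
    pls <- nipals_pls1(osc$X, yc, 1L)
    r2x_orth <- if (osc$n_orth > 0) {
      colSums(osc$T_orth^2) * colSums(osc$P_orth^2) / ssx
    } else numeric(0)
  } else {
    osc <- list(W_orth = NULL, P_orth = NULL, T_orth = NULL, n_orth = 0L)
    pls <- nipals_pls1(cs$X, yc, ncomp)
    r2x_orth <- numeric(0)
  }
  if (pls$ncomp == 0) stop("no predictive component could be extracted", call. = FALSE)
  r2x_pred <- vapply(seq_len(pls$ncomp), function(a) {
    sum(pls$Tm[, a]^2) * sum(pls$P[, a]^2) / ssx
  }, numeric(1))
  yhat <- pls$Tm %*% pls$Q
  r2y <- 1 - sum((yc - yhat)^2) / ssy
  list(model_kind = model_kind, W = pls$W, P = pls$P, Q = pls$Q, Tm = pls$Tm,
       W_orth = osc$W_orth, P_orth = osc$P_orth, T_orth = osc$T_orth,
       ncomp = pls$ncomp, n_orth = osc$n_orth,
       center = cs$center, scale = cs$scale, y_mean = mean(y01),
       R2X = sum(r2x_pred) + sum(r2x_orth), R2X_pred = r2x_pred,
       R2X_orth = r2x_orth, R2Y = r2y)
}

# Predict the (0/1-scale) response for new raw X rows.
predict_core <- function(fit, Xnew) {
  Xc <- sweep(sweep(Xnew, 2L, fit$center), 2L, fit$scale, "/")
  if (fit$n_orth > 0) {
    for (k in seq_len(fit$n_orth)) {
      to <- Xc %*% fit$W_orth[, k]
      Xc <- Xc - tcrossprod(to, fit$P_orth[, k])
    }
  }
  yhat <- rep(0, nrow(Xc))
  for (a in seq_len(fit$ncomp)) {
    tt <- Xc %*% fit$W[, a]
    Xc <- Xc - tcrossprod(tt, fit$P[, a])
    yhat <- yhat + tt[, 1L] * fit$Q[a]
  }
  yhat + fit$y_mean
}

# Deterministic interleaved ("venetian blinds") folds after a seeded shuffle;
# refolds with a warning when some fold misses a class.
make_folds <- function(y01, k, seed) {
  n <- length(y01)
  k <- min(k, n)
  for (try in 0:99) {
    perm <- with_seed(seed + try, sample.int(n))
    fold <- integer(n)
    fold[perm] <- rep_len(seq_len(k), n)
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y01[fold == f])) == 2L
    }, logical(1)))
    if (ok) {
      if (try > 0) warning("refolded ", try, " time(s) so every fold holds both classes",
                           call. = FALSE)
      return(fold)
    }
  }
  stop("could not assign cross-validation folds containing both classes", call. = FALSE)
}

q2_for <- function(X, y01, model_kind, ncomp, n_orth, scale, folds) {
  press <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fit_core(X[tr, , drop = FALSE], y01[tr], model_kind, ncomp, n_orth, scale)
    pred <- predict_core(fit, X[!tr, , drop = FALSE])
    press <- press + sum((y01[!tr] - pred)^2)
  }
  1 - press / sum((y01 - mean(y01))^2)
}

# ---- exported interface ----------------------------------------------------

#' Cross-validated Q2 of a PLS-DA / OPLS-DA model
#'
#' \eqn{Q^2 = 1 - PRESS/SS} with the total sum of squares taken about the
#' centered 0/1 response and PRESS accumulated over held-out folds. Folds are
#' interleaved over the sample order after a seeded shuffle, so results are
#' deterministic; folds missing a class trigger a re-shuffle with a warning.
#'
#' @param x samples-by-features matrix or an [abundance_table()]
#'   (features x samples, transposed internally).
#' @param y two-class labels (or a [sample_metadata()]).
#' @param ncomp number of predictive components (OPLS-DA always uses 1).
#' @param model_kind `"plsda"` or `"oplsda"`.
#' @param n_orth orthogonal components for OPLS-DA.
#' @param cv_folds number of folds (default 7).
#' @param scale auto-scale within each training fold.
#' @param cv_seed seed for the fold shuffle.
#' @return The Q2 scalar (can be negative for uninformative models).
#' @export
cross_validated_q2 <- function(x, y, ncomp = 1, model_kind = c("plsda", "oplsda"),
                               n_orth = 0, cv_folds = 7, scale = FALSE,
                               cv_seed = 1L) {
  model_kind <- match.arg(model_kind)
  y <- align_labels(x, y)
  X <- prep_x(x)
  enc <- encode_labels(y)
  folds <- make_folds(enc$y01, cv_folds, cv_seed)
  q2_for(X, enc$y01, model_kind, ncomp, n_orth, scale, folds)
}

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' Partial least squares discriminant analysis for two classes. Components
#' are added while the cross-validated Q2 improves by more than
#' `min_q2_gain`, up to `max_components`; at least one predictive component is
#' always fitted. Successive score vectors are mutually orthogonal and the
#' weight vectors have unit norm.
#'
#' @inheritParams cross_validated_q2
#' @param max_components upper bound on predictive components.
#' @param min_q2_gain component-entry rule: keep adding while the Q2 gain
#'   exceeds this value.
#' @return A fitted model of class `pls_model` carrying weights (`W`),
#'   loadings (`P`, `Q`), scores (`Tm`), centering/scaling vectors, `R2X`,
#'   `R2Y`, `Q2`, per-component `q2_path`, and per-feature `vip`.
#' @export
fit_plsda <- function(x, y, max_components = 5, cv_folds = 7, scale = FALSE,
                      min_q2_gain = 0.01, cv_seed = 1L) {
  y <- align_labels(x, y)
  X <- prep_x(x)
  enc <- encode_labels(y)
  if (nrow(X) != length(enc$y01)) stop("X rows and labels differ in length", call. = FALSE)
  folds <- make_folds(enc$y01, cv_folds, cv_seed)
  max_components <- min(max_components, nrow(X) - 1L, ncol(X))
  q2_path <- numeric(0)
  ncomp <- 1L
  q2_path[1L] <- q2_for(X, enc$y01, "plsda", 1L, 0L, scale, folds)
  while (ncomp < max_components) {
    q2_next <- q2_for(X, enc$y01, "plsda", ncomp + 1L, 0L, scale, folds)
    if (q2_next - q2_path[ncomp] > min_q2_gain) {
      ncomp <- ncomp + 1L
      q2_path[ncomp] <- q2_next
    } else break
  }
  fit <- fit_core(X, enc$y01, "plsda", ncomp, 0L, scale)
  finalize_model(fit, X, enc, q2_path, cv_folds, cv_seed, scale)
}

#' Fit an OPLS-DA model (Trygg-Wold orthogonal signal correction)
#'
#' Removes class-orthogonal structured variation from X (weights
#' \eqn{w_{orth} \propto p - (w'p)w}, removed recursively), then fits a single
#' predictive PLS component on the filtered matrix. With `n_orth = "auto"`,
#' orthogonal components are added while the cross-validated Q2 improves by
#' more than `min_q2_gain`. With `n_orth = 0` the model coincides with
#' one-component PLS-DA.
#'
#' @inheritParams fit_plsda
#' @param n_orth number of orthogonal components, or `"auto"`.
#' @param max_orth cap for the auto search.
#' @return A `pls_model`; predictive scores are in `Tm`, orthogonal scores in
#'   `T_orth`. VIP is computed on the predictive component only.
#' @export
fit_oplsda <- function(x, y, n_orth = "auto", cv_folds = 7, scale = FALSE,
                       min_q2_gain = 0.01, max_orth = 5, cv_seed = 1L) {
  y <- align_labels(x, y)
  X <- prep_x(x)
  enc <- encode_labels(y)
  if (nrow(X) != length(enc$y01)) stop("X rows and labels differ in length", call. = FALSE)
  folds <- make_folds(enc$y01, cv_folds, cv_seed)
  if (identical(n_orth, "auto")) {
    max_orth <- min(max_orth, nrow(X) - 2L)
    k <- 0L
    q2_path <- q2_for(X, enc$y01, "oplsda", 1L, 0L, scale, folds)
    while (k < max_orth) {
      q2_next <- q2_for(X, enc$y01, "oplsda", 1L, k + 1L, scale, folds)
      if (q2_next - q2_path[k + 1L] > min_q2_gain) {
        k <- k + 1L
        q2_path[k + 1L] <- q2_next
      } else break
    }
    n_orth <- k
  } else {
    n_orth <- as.integer(n_orth)
    q2_path <- q2_for(X, enc$y01, "oplsda", 1L, n_orth, scale, folds)
  }
  fit <- fit_core(X, enc$y01, "oplsda", 1L, n_orth, scale)
  finalize_model(fit, X, enc, q2_path, cv_folds, cv_seed, scale)
}

finalize_model <- function(fit, X, enc, q2_path, cv_folds, cv_seed, scale) {
  fit$n <- nrow(X); fit$p <- ncol(X)
  fit$feature_ids <- colnames(X)
  fit$classes <- c(negative = enc$negative, positive = enc$positive)
  fit$y01 <- enc$y01
  fit$Q2 <- q2_path[length(q2_path)]
  fit$q2_path <- q2_path
  fit$cv <- list(folds = cv_folds, seed = cv_seed)
  fit$scaled_internally <- scale
  class(fit) <- "pls_model"
  fit$vip <- vip_scores(fit)
  fit
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<%s> n=%d p=%d | %d predictive + %d orthogonal component(s)\n",
              toupper(x$model_kind), x$n, x$p, x$ncomp, x$n_orth))
  cat(sprintf("  R2X=%.3f R2Y=%.3f Q2=%.3f (positive class: %s)\n",
              x$R2X, x$R2Y, x$Q2, x$classes["positive"]))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}, \quad
#'   SS_a = q_a^2 t_a' t_a} summed over the predictive components (for
#' OPLS-DA the single predictive component; orthogonal components are
#' excluded unless `include_orthogonal = TRUE`). The weights are unit-norm,
#' so mean(VIP^2) = 1 for every fitted model.
#'
#' @param model a fitted `pls_model`.
#' @param include_orthogonal also count orthogonal components in the
#'   weighting (off by default).
#' @return Named per-feature VIP vector.
#' @export
vip_scores <- function(model, include_orthogonal = FALSE) {
  if (!inherits(model, "pls_model")) stop("'model' must be a fitted pls_model", call. = FALSE)
  W <- model$W
  ss <- model$Q^2 * colSums(model$Tm^2)
  if (include_orthogonal && model$n_orth > 0) {
    # orthogonal components have zero y-loading; weight them by their X sum
    # of squares instead so they can only dilute importance
    ss_o <- colSums(model$T_orth^2) * colSums(model$P_orth^2) / model$p
    W <- cbind(W, model$W_orth)
    ss <- c(ss, ss_o)
  }
  p <- nrow(W)
  vip <- sqrt(p * as.numeric(W^2 %*% ss) / sum(ss))
  stats::setNames(vip, model$feature_ids)
}

#' Label-permutation validation of a discriminant model
#'
#' Fits the model on the true labels, then refits it (with the same number of
#' components) on `n_perm` random label permutations, recording R2Y and
#' cross-validated Q2 against the absolute correlation between permuted and
#' original labels. The empirical p-value for Q2 uses the add-one estimator
#' \eqn{(\#\{Q^2_{perm} \ge Q^2_{orig}\} + 1)/(n_{perm} + 1)}. Two validity
#' flags summarise the plot: all permuted Q2 below the original, and the
#' intercept at zero label-correlation of the Q2 regression line (fitted
#' through the permuted points plus the original) at most 0.05.
#'
#' @inheritParams fit_plsda
#' @param model_kind `"plsda"` or `"oplsda"`.
#' @param n_perm number of permutations (>= 1), conventionally 99.
#' @param seed seed for the label permutations.
#' @param ... passed to [fit_plsda()] / [fit_oplsda()].
#' @return A list of class `permutation_report`: `n_perm`, `original` (R2Y,
#'   Q2), `perms` (data frame of label_cor, R2Y, Q2), `p_q2`, `q2_intercept`,
#'   and `valid` flags.
#' @export
permutation_test <- function(x, y, model_kind = c("plsda", "oplsda"),
                             n_perm = 99, seed = 1L, cv_folds = 7,
                             scale = FALSE, ...) {
  model_kind <- match.arg(model_kind)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  y <- align_labels(x, y)
  X <- prep_x(x)
  enc <- encode_labels(y)
  orig <- if (model_kind == "plsda") {
    fit_plsda(X, y, cv_folds = cv_folds, scale = scale, ...)
  } else {
    fit_oplsda(X, y, cv_folds = cv_folds, scale = scale, ...)
  }
  n <- length(enc$y01)
  perm_idx <- with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  folds <- make_folds(enc$y01, cv_folds, orig$cv$seed)
  rows <- lapply(perm_idx, function(idx) {
    yp <- enc$y01[idx]
    fit <- fit_core(X, yp, model_kind, orig$ncomp, orig$n_orth, scale)
    # permuting labels keeps class balance, so the original fold skeleton may
    # lose a class under yp; refold quietly in that case
    fl <- tryCatch({
      ok <- all(vapply(unique(folds), function(f) length(unique(yp[folds == f])) == 2L,
                       logical(1)))
      if (ok) folds else suppressWarnings(make_folds(yp, cv_folds, orig$cv$seed))
    }, error = function(e) NULL)
    q2 <- if (is.null(fl)) NA_real_ else {
      q2_for(X, yp, model_kind, orig$ncomp, orig$n_orth, scale, fl)
    }
    c(label_cor = abs(stats::cor(yp, enc$y01)), R2Y = fit$R2Y, Q2 = q2)
  })
  perms <- as.data.frame(do.call(rbind, rows))
  q2p <- perms$Q2[!is.na(perms$Q2)]
  p_q2 <- (sum(q2p >= orig$Q2) + 1) / (length(q2p) + 1)
  reg <- stats::lm(q2 ~ r, data = data.frame(r = c(perms$label_cor, 1),
                                             q2 = c(perms$Q2, orig$Q2)))
  intercept <- unname(stats::coef(reg)[1L])
  structure(list(n_perm = n_perm,
                 model_kind = model_kind,
                 original = list(R2Y = orig$R2Y, Q2 = orig$Q2,
                                 ncomp = orig$ncomp, n_orth = orig$n_orth),
                 perms = perms,
                 p_q2 = p_q2,
                 q2_intercept = intercept,
                 valid = c(all_q2_below = all(q2p < orig$Q2),
                           intercept_ok = intercept <= 0.05)),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("<permutation_report> %s, %d permutations\n", x$model_kind, x$n_perm))
  cat(sprintf("  original R2Y=%.3f Q2=%.3f | p(Q2)=%.4g | Q2 intercept=%.3f\n",
              x$original$R2Y, x$original$Q2, x$p_q2, x$q2_intercept))
  cat(sprintf("  valid: all permuted Q2 below original = %s, intercept <= 0.05 = %s\n",
              x$valid["all_q2_below"], x$valid["intercept_ok"]))
  invisible(x)
}
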