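# The 3-DOF proportional myoelectric controller: posture/direction
# enumeration, effort-vector targets, repetition selection, and a
# single-hidden-layer feed-forward network (14 hidden nodes) mapping the
# channel WFL vector to simultaneous joint-angle velocities.

#' Enumerate the trained hand postures as direction vectors
#'
#' All single and paired combinations of the three DOFs (hand open-close,
#' wrist flex-extend, pronate-supinate): every vector in `{-1, 0, +1}^3` with
#' exactly one or two nonzero entries, in a fixed deterministic order. There
#' are 18 such postures (3^3 - 1 all-zero - 2^3 all-nonzero).
#'
#' @return An 18 x 3 integer matrix, one direction vector per row.
#' @export
#' @examples
#' nrow(enumerate_postures())  # 18
enumerate_postures <- function() {
  g <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1))
  nz <- rowSums(g != 0)
  g <- g[nz %in% c(1, 2), , drop = FALSE]
  g <- g[order(rowSums(g != 0), g[, 1], g[, 2], g[, 3]), ]
  dimnames(g) <- list(NULL, c("hand_oc", "wrist_fe", "pro_sup"))
  g
}

#' Effort-vector training targets for one trial
#'
#' The target posture's 3-element direction vector scaled at each time point
#' by the mean WFL amplitude across all channels: `e(t) = d * mean_ch WFL(t)`.
#' Effort is zero whenever the features are zero, and doubles when the
#' features double.
#'
#' @param features channels x time WFL matrix in uV.
#' @param direction length-3 vector with entries in `{-1, 0, +1}`.
#' @return A 3 x time effort matrix.
#' @export
#' @examples
#' build_effort_targets(matrix(2, 4, 3), c(1, 0, -1))
build_effort_targets <- function(features, direction) {
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("need at least one channel")
  stopifnot(length(direction) == 3, all(direction %in% c(-1, 0, 1)))
  outer(as.numeric(direction), colMeans(features))
}

#' One controller training trial
#'
#' @param posture_id identifier of the prompted posture.
#' @param direction length-3 direction vector in `{-1, 0, +1}`.
#' @param features channels x time WFL matrix.
#' @return A `training_trial` list with the derived `effort` targets.
#' @export
training_trial <- function(posture_id, direction, features) {
  features <- as.matrix(features)
  structure(list(posture_id = posture_id, direction = direction,
                 features = features,
                 effort = build_effort_targets(features, direction)),
            class = "training_trial")
}

#' Partition ten repetitions into excluded / training / validation sets
#'
#' Scores each repetition's per-channel mean-WFL activation pattern by its
#' Pearson correlation with the across-repetition median pattern. The three
#' least similar repetitions are excluded, the four most similar form the
#' training set, and the remaining three the validation set. Ties in
#' similarity are broken by repetition index, with lower indices excluded
#' first; the partition is deterministic.
#'
#' @param reps a list of exactly 10 [training_trial()]s (or channels x time
#'   feature matrices) for one posture.
#' @return A list with integer index vectors `train` (4), `validation` (3),
#'   `excluded` (3), and the `similarity` scores.
#' @export
select_repetitions <- function(reps) {
  if (length(reps) != 10) stop("repetition selection expects exactly 10 repetitions")
  pattern <- sapply(reps, function(r) {
    f <- if (inherits(r, "training_trial")) r$features else as.matrix(r)
    rowMeans(f)
  })
  med <- apply(pattern, 1, stats::median)
  sim <- apply(pattern, 2, function(p) {
    if (stats::sd(p) == 0 || stats::sd(med) == 0) return(0)
    stats::cor(p, med)
  })
  ord <- order(-sim, -seq_along(sim))
  list(train = sort(ord[1:4]), validation = sort(ord[5:7]),
       excluded = sort(ord[8:10]), similarity = sim)
}

# ---- feed-forward network internals ------------------------------------

ann_forward <- function(w, z) {
  a1 <- tanh(w$W1 %*% z + w$b1)
  list(a1 = a1, y = w$W2 %*% a1 + w$b2)
}

ann_loss_grad <- function(w, z, target) {
  fw <- ann_forward(w, z)
  e <- fw$y - target
  n <- length(e)
  dy <- 2 * e / n
  da1 <- crossprod(w$W2, dy)
  dz1 <- da1 * (1 - fw$a1^2)
  list(loss = mean(e^2),
       grad = list(W1 = dz1 %*% t(z), b1 = rowSums(dz1),
                   W2 = dy %*% t(fw$a1), b2 = rowSums(dy)))
}

ann_init <- function(n_in, n_hidden, n_out = 3) {
  list(W1 = matrix(stats::rnorm(n_hidden * n_in, sd = 1 / sqrt(n_in)),
                   n_hidden, n_in),
       b1 = numeric(n_hidden),
       W2 = matrix(stats::rnorm(n_out * n_hidden, sd = 1 / sqrt(n_hidden)),
                   n_out, n_hidden),
       b2 = numeric(n_out))
}

#' Train the 3-DOF proportional ANN controller
#'
#' Fits a single-hidden-layer feed-forward regressor (tanh hidden units,
#' linear outputs, mean-squared-error loss) from the per-window channel WFL
#' vector to the 3-element effort vector. Inputs are standardized per channel
#' and targets scaled to unit magnitude using training statistics. Training
#' uses full-batch Adam with early stopping: validation RMSE is evaluated
#' every `eval_every` iterations and training stops after `patience`
#' evaluations without improvement, keeping the best weights. Identical seeds
#' give identical weights.
#'
#' After fitting, per-direction deadband thresholds are calibrated so that an
#' all-zero input decodes to zero velocity, and per-direction gains are
#' scaled so a typical full-effort command drives about `max_velocity` of
#' joint range per second.
#'
#' @param train,validation lists of [training_trial()]s.
#' @param hidden_nodes hidden layer width (the study used 14).
#' @param seed integer seed for weight initialization.
#' @param input_channels channel indices used as inputs (artifact-affected
#'   channels are excluded upstream); default all channels.
#' @param max_iter,eval_every,patience,learn_rate optimizer settings.
#' @param max_velocity full-effort velocity target for gain calibration, in
#'   joint range per second.
#' @return An `ann_controller`: weights, standardization stats, input
#'   channels, `per_direction_gain` and `per_direction_threshold` (length 6,
#'   ordered dof1+, dof1-, dof2+, dof2-, dof3+, dof3-), and
#'   `validation_rmse`.
#' @export
train_ann <- function(train, validation, hidden_nodes = 14, seed = 1,
                      input_channels = NULL, max_iter = 3000,
                      eval_every = 25, patience = 10, learn_rate = 0.01,
                      max_velocity = 1) {
  if (length(train) == 0) stop("training set is empty")
  feat <- function(trials) do.call(cbind, lapply(trials, function(tr)
    tr$features[input_channels %||% seq_len(nrow(tr$features)), , drop = FALSE]))
  eff <- function(trials) do.call(cbind, lapply(trials, `[[`, "effort"))
  x_tr <- feat(train); y_tr <- eff(train)
  if (all(x_tr == 0)) stop("degenerate training features (all zero)")
  x_va <- feat(validation); y_va <- eff(validation)

  mu <- rowMeans(x_tr)
  sdv <- pmax(apply(x_tr, 1, stats::sd), 1e-8)
  scale_in <- function(x) (x - mu) / sdv
  y_scale <- max(abs(y_tr))
  if (y_scale == 0) y_scale <- 1
  z_tr <- scale_in(x_tr); t_tr <- y_tr / y_scale
  z_va <- scale_in(x_va); t_va <- y_va / y_scale

  w <- with_seed(seed, ann_init(nrow(z_tr), hidden_nodes))
  m <- lapply(w, function(p) p * 0)
  v <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(w = w, rmse = Inf)
  stale <- 0L
  for (it in seq_len(max_iter)) {
    lg <- ann_loss_grad(w, z_tr, t_tr)
    for (nm in names(w)) {
      g <- lg$grad[[nm]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
      mhat <- m[[nm]] / (1 - b1^it)
      vhat <- v[[nm]] / (1 - b2^it)
      w[[nm]] <- w[[nm]] - learn_rate * mhat / (sqrt(vhat) + eps)
    }
    if (it %% eval_every == 0) {
      rmse <- sqrt(mean((ann_forward(w, z_va)$y - t_va)^2))
      if (rmse < best$rmse * (1 - 1e-4)) {
        best <- list(w = w, rmse = rmse)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  }
  w <- best$w

  # deadband calibration: rest (all-zero features) must decode to zero
  r0 <- as.numeric(abs(ann_forward(w, scale_in(matrix(0, length(mu), 1)))$y))
  thresholds <- rep(pmax(1.5 * r0, 0.02), each = 2)  # same for + and -
  # gain calibration: 95th-percentile effort drives ~max_velocity range/s
  s_d <- apply(abs(t_tr), 1, stats::quantile, probs = 0.95)
  gains <- rep(max_velocity / pmax(s_d, 0.05), each = 2)
  structure(list(weights = w, mu = mu, sd = sdv, y_scale = y_scale,
                 input_channels = input_channels,
                 hidden_nodes = hidden_nodes,
                 per_direction_gain = gains,
                 per_direction_threshold = thresholds,
                 validation_rmse = best$rmse),
            class = "ann_controller")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ann_controller <- function(x, ...) {
  cat(sprintf("<ann_controller> %d inputs -> %d tanh hidden -> 3 DOF, val RMSE %.4f\n",
              length(x$mu), x$hidden_nodes, x$validation_rmse))
  invisible(x)
}

#' Decode a WFL feature vector into 3-DOF joint velocities
#'
#' Runs the network forward and applies the per-direction deadband and gain:
#' for each DOF, a raw output `r` with `|r|` below the threshold of its
#' sign's direction gives zero velocity; otherwise the velocity is
#' `gain * (|r| - threshold) * sign(r)`, which is continuous at the
#' threshold.
#'
#' @param controller an `ann_controller` from [train_ann()].
#' @param features channel WFL vector (length matching the controller's
#'   inputs) or a channels x time matrix.
#' @param raw if `TRUE`, return the raw network outputs without
#'   deadband/gain.
#' @return A length-3 velocity vector (or 3 x time matrix), in joint range
#'   per second.
#' @export
decode <- function(controller, features, raw = FALSE) {
  stopifnot(inherits(controller, "ann_controller"))
  x <- if (is.matrix(features)) features else matrix(features, ncol = 1)
  if (nrow(x) != length(controller$mu))
    stop("feature dimensionality does not match the controller's inputs")
  z <- (x - controller$mu) / controller$sd
  r <- ann_forward(controller$weights, z)$y
  if (raw) return(if (ncol(r) == 1) as.numeric(r) else r)
  v <- apply_deadband(r, controller$per_direction_gain,
                      controller$per_direction_threshold)
  if (ncol(v) == 1) as.numeric(v) else v
}

# r: 3 x T raw outputs; gains/thresholds length 6 (dof1+, dof1-, ...)
apply_deadband <- function(r, gains, thresholds) {
  v <- r * 0
  for (d in 1:3) {
    pos <- 2 * d - 1; neg <- 2 * d
    rp <- r[d, ]
    idx <- ifelse(rp >= 0, pos, neg)
    thr <- thresholds[idx]
    g <- gains[idx]
    v[d, ] <- ifelse(abs(rp) < thr, 0, g * (abs(rp) - thr) * sign(rp))
  }
  v
}
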