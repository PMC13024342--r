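# Cross-modal feature alignment: two modality encoders trained with weighted
# cross-entropy, center loss, cross-modal consistency loss and a
# domain-adversarial loss behind a gradient reversal layer, plus pseudo-MCI
# manifold interpolation to compensate for the missing MCI class in EEG.

CLASS_LEVELS <- c("AD", "HC", "MCI")

#' Alignment network configuration
#'
#' @param subspace_dim Shared subspace width (default 128).
#' @param speech_hidden First-layer width of the speech encoder (default 256).
#' @param eeg_hidden First-layer width of the EEG encoder; `NULL` selects 64
#'   for inputs up to 64 dims and 512 otherwise.
#' @param dropout Dropout rate (default 0.2).
#' @param lambda_center,lambda_domain,lambda_consist Loss weights
#'   (defaults 0.05, 0.1, 5.0).
#' @param grl_ceiling Final gradient-reversal factor (default 0.1); the
#'   factor ramps from 0 to this value over training.
#' @param grl_schedule `"linear"` ramp (default) or the sigmoidal
#'   `"dann"` ramp.
#' @param beta_a,beta_b Beta parameters for the pseudo-MCI mixing
#'   coefficient (default Beta(2, 2)).
#' @param pseudo_weight Down-weighting of pseudo-MCI anchors in the
#'   classification and center losses (default 0.5); 0 disables them.
#' @param lr Initial Adam learning rate (default 0.001), halved every
#'   `lr_step` epochs (default 30).
#' @param weight_decay L2 coefficient (default 0.001).
#' @param center_lr Learning rate of the separate SGD optimizer on the
#'   class centers (default 0.5).
#' @param epochs Training epochs (default 200).
#' @param batch_size Speech batch size (default 64).
#' @param seed Integer seed.
#' @return A list of class `alignment_config`.
#' @export
alignment_config <- function(subspace_dim = 128, speech_hidden = 256,
                             eeg_hidden = NULL, dropout = 0.2,
                             lambda_center = 0.05, lambda_domain = 0.1,
                             lambda_consist = 5.0, grl_ceiling = 0.1,
                             grl_schedule = c("linear", "dann"),
                             beta_a = 2, beta_b = 2, pseudo_weight = 0.5,
                             lr = 0.001, weight_decay = 0.001,
                             center_lr = 0.5, lr_step = 30,
                             epochs = 200, batch_size = 64, seed = 1) {
  stopifnot(lambda_center >= 0, lambda_domain >= 0, lambda_consist >= 0,
            subspace_dim > 0, beta_a > 0, beta_b > 0)
  structure(list(subspace_dim = subspace_dim, speech_hidden = speech_hidden,
                 eeg_hidden = eeg_hidden, dropout = dropout,
                 lambda_center = lambda_center, lambda_domain = lambda_domain,
                 lambda_consist = lambda_consist, grl_ceiling = grl_ceiling,
                 grl_schedule = match.arg(grl_schedule),
                 beta_a = beta_a, beta_b = beta_b,
                 pseudo_weight = pseudo_weight, lr = lr,
                 weight_decay = weight_decay, center_lr = center_lr,
                 lr_step = lr_step, epochs = epochs, batch_size = batch_size,
                 seed = seed),
            class = "alignment_config")
}

#' Gradient reversal layer (forward pass)
#'
#' Identity in the forward direction; during backpropagation the incoming
#' gradient is multiplied by `-lambda_factor` (see [grl_backward()]).
#'
#' @param x Input (any numeric array).
#' @param lambda_factor Nonnegative reversal scale.
#' @return `x`, unchanged.
#' @export
grl <- function(x, lambda_factor) {
  stopifnot(lambda_factor >= 0)
  x
}

#' Gradient reversal layer (backward pass)
#'
#' @param grad Incoming gradient.
#' @param lambda_factor Nonnegative reversal scale.
#' @return `-lambda_factor * grad`.
#' @export
grl_backward <- function(grad, lambda_factor) {
  stopifnot(lambda_factor >= 0)
  -lambda_factor * grad
}

# GRL ramp: fraction p in [0, 1] of training completed -> factor
grl_factor <- function(p, ceiling, schedule = "linear") {
  if (schedule == "linear") ceiling * p
  else ceiling * (2 / (1 + exp(-10 * p)) - 1)
}

#' Class-weighted cross-entropy
#'
#' Cross-entropy with per-class weights equal to the reciprocal of the class
#' proportions, normalized by the total weight present in the batch (so
#' balanced classes reduce to the unweighted mean cross-entropy).
#'
#' @param logits `n x 3` matrix of unnormalized scores, columns ordered
#'   AD, HC, MCI.
#' @param labels Character/factor labels in `c("AD", "HC", "MCI")`.
#' @param class_proportions Named positive proportions summing to 1 for
#'   every class appearing in `labels`.
#' @param sample_weights Optional extra per-sample weights (default 1).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(logits, labels, class_proportions,
                                   sample_weights = NULL) {
  labels <- as.character(labels)
  if (!all(labels %in% names(class_proportions))) {
    stop("missing class proportion for some labels", call. = FALSE)
  }
  if (any(class_proportions <= 0)) stop("proportions must be positive", call. = FALSE)
  P <- row_softmax(logits)
  yi <- match(labels, CLASS_LEVELS)
  w <- 1 / as.numeric(class_proportions[labels])
  if (!is.null(sample_weights)) w <- w * sample_weights
  ce <- -log(pmax(P[cbind(seq_along(yi), yi)], 1e-12))
  sum(w * ce) / sum(w)
}

# gradient of weighted_cross_entropy w.r.t. logits
wce_grad <- function(logits, labels, class_proportions, sample_weights = NULL) {
  labels <- as.character(labels)
  P <- row_softmax(logits)
  yi <- match(labels, CLASS_LEVELS)
  w <- 1 / as.numeric(class_proportions[labels])
  if (!is.null(sample_weights)) w <- w * sample_weights
  G <- P
  G[cbind(seq_along(yi), yi)] <- G[cbind(seq_along(yi), yi)] - 1
  G * (w / sum(w))
}

#' Center loss
#'
#' Mean Euclidean distance (first power) between latent features and their
#' class centers.
#'
#' @param Z `n x d` latent matrix.
#' @param labels Labels in `c("AD", "HC", "MCI")`.
#' @param centers `3 x d` matrix of class centers, rows ordered AD, HC, MCI.
#' @param sample_weights Optional per-sample weights (default 1).
#' @return Scalar loss.
#' @export
center_loss <- function(Z, labels, centers, sample_weights = NULL) {
  yi <- match(as.character(labels), CLASS_LEVELS)
  if (anyNA(yi)) stop("unknown label", call. = FALSE)
  D <- Z - centers[yi, , drop = FALSE]
  dist <- sqrt(rowSums(D^2))
  w <- if (is.null(sample_weights)) rep(1, nrow(Z)) else sample_weights
  sum(w * dist) / sum(w)
}

# gradients of center_loss w.r.t. Z and centers
center_loss_grads <- function(Z, labels, centers, sample_weights = NULL, eps = 1e-8) {
  yi <- match(as.character(labels), CLASS_LEVELS)
  D <- Z - centers[yi, , drop = FALSE]
  dist <- pmax(sqrt(rowSums(D^2)), eps)
  w <- if (is.null(sample_weights)) rep(1, nrow(Z)) else sample_weights
  coef <- w / (sum(w) * dist)
  dZ <- D * coef
  dC <- matrix(0, nrow(centers), ncol(centers))
  for (k in seq_len(nrow(centers))) {
    sel <- yi == k
    if (any(sel)) dC[k, ] <- -colSums(dZ[sel, , drop = FALSE])
  }
  list(dZ = dZ, dC = dC)
}

#' Cross-modal consistency loss
#'
#' For every class present in both modality batches (MCI is always masked),
#' the mean squared error between the speech and EEG class-mean latent
#' vectors, averaged over such classes.  Returns 0 with attribute
#' `skipped = TRUE` when no class overlaps.
#'
#' @param Z_speech,Z_eeg Latent matrices.
#' @param y_speech,y_eeg Corresponding labels.
#' @return Scalar loss with attribute `skipped`.
#' @export
consistency_loss <- function(Z_speech, y_speech, Z_eeg, y_eeg) {
  shared <- setdiff(intersect(unique(as.character(y_speech)),
                              unique(as.character(y_eeg))), "MCI")
  if (length(shared) == 0 || nrow(Z_speech) == 0 || nrow(Z_eeg) == 0) {
    return(structure(0, skipped = TRUE))
  }
  vals <- vapply(shared, function(k) {
    ms <- colMeans(Z_speech[y_speech == k, , drop = FALSE])
    me <- colMeans(Z_eeg[y_eeg == k, , drop = FALSE])
    mean((ms - me)^2)
  }, numeric(1))
  structure(mean(vals), skipped = FALSE)
}

# gradients of consistency_loss w.r.t. both latent matrices
consistency_grads <- function(Z_speech, y_speech, Z_eeg, y_eeg) {
  dZs <- Z_speech * 0; dZe <- Z_eeg * 0
  shared <- setdiff(intersect(unique(as.character(y_speech)),
                              unique(as.character(y_eeg))), "MCI")
  if (length(shared) == 0) return(list(dZs = dZs, dZe = dZe))
  d <- ncol(Z_speech); K <- length(shared)
  for (k in shared) {
    ss <- y_speech == k; se <- y_eeg == k
    ms <- colMeans(Z_speech[ss, , drop = FALSE])
    me <- colMeans(Z_eeg[se, , drop = FALSE])
    g <- 2 * (ms - me) / (d * K)
    dZs[ss, ] <- dZs[ss, , drop = FALSE] + rep(g / sum(ss), each = sum(ss))
    dZe[se, ] <- dZe[se, , drop = FALSE] - rep(g / sum(se), each = sum(se))
  }
  list(dZs = dZs, dZe = dZe)
}

#' Pseudo-MCI manifold interpolation
#'
#' Convex combination `alpha * z_AD + (1 - alpha) * z_HC` of same-batch AD
#' and HC latents, synthesizing transitional-state anchors on the disease
#' continuum.
#'
#' @param z_AD,z_HC Latent vectors (or matrices with matching shape).
#' @param alpha Mixing coefficient strictly inside (0, 1); during training
#'   it is drawn from a Beta distribution.
#' @return The interpolated latent(s).
#' @export
pseudo_mci <- function(z_AD, z_HC, alpha) {
  if (any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  }
  alpha * z_AD + (1 - alpha) * z_HC
}

#' Total alignment loss
#'
#' Exact weighted sum
#' `L_cls + lambda_center * L_center + lambda_domain * L_domain +
#'  lambda_consist * L_consist`.
#'
#' @param L_cls,L_center,L_domain,L_consist Component values.
#' @param cfg An [alignment_config()].
#' @return Scalar total loss.
#' @export
total_loss <- function(L_cls, L_center, L_domain, L_consist, cfg) {
  L_cls + cfg$lambda_center * L_center + cfg$lambda_domain * L_domain +
    cfg$lambda_consist * L_consist
}

#' Asymmetric paired batch iterator
#'
#' Speech is the primary modality: one epoch covers every speech row exactly
#' once in shuffled batches.  EEG is auxiliary: an independent iterator
#' cycles through the EEG rows, reshuffling whenever it is exhausted, so no
#' EEG row is starved.
#'
#' @param n_speech,n_eeg Row counts.
#' @param batch_size Speech batch size; the EEG side receives
#'   `min(batch_size, n_eeg)` rows per batch.
#' @param seed Integer seed.
#' @return List of batches, each a list with integer index vectors `speech`
#'   and `eeg`.
#' @export
paired_batches <- function(n_speech, n_eeg, batch_size = 64, seed = 1) {
  stopifnot(n_speech > 0, n_eeg > 0)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  ord <- sample(n_speech)
  sp <- split(ord, ceiling(seq_along(ord) / batch_size))
  eeg_bs <- min(batch_size, n_eeg)
  pool <- sample(n_eeg)
  out <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    while (length(pool) < eeg_bs) pool <- c(pool, sample(n_eeg))
    out[[i]] <- list(speech = sp[[i]], eeg = pool[seq_len(eeg_bs)])
    pool <- pool[-seq_len(eeg_bs)]
  }
  out
}

# build one modality encoder
.make_encoder <- function(d_in, hidden, out, dropout) {
  list(nn_dense(d_in, hidden), nn_batchnorm(hidden), nn_act("relu"),
       nn_dropout(dropout), nn_dense(hidden, out))
}

#' Train the cross-modal alignment network
#'
#' Maps speech (AD/MCI/HC) and EEG (AD/HC) feature tables into a shared
#' subspace with a weighted cross-entropy classifier, center loss with
#' separately-optimized class centers, a cross-modal consistency loss, a
#' domain discriminator behind a gradient reversal layer whose factor ramps
#' from 0 to `grl_ceiling`, and pseudo-MCI interpolation between same-batch
#' HC and AD latents.
#'
#' @param speech_table,eeg_table Feature tables with a `label` column.
#' @param cfg An [alignment_config()].
#' @return An object of class `alignment_model` containing both encoders,
#'   the classifier, the domain discriminator, class centers and the
#'   per-epoch loss history.
#' @export
train_alignment <- function(speech_table, eeg_table, cfg = alignment_config()) {
  stopifnot(inherits(cfg, "alignment_config"))
  fs <- feature_matrix(speech_table)
  fe <- feature_matrix(eeg_table)
  ys <- as.character(speech_table$label)
  ye <- as.character(eeg_table$label)
  if (!all(ys %in% CLASS_LEVELS)) stop("speech labels must be AD/HC/MCI", call. = FALSE)
  if (!all(ye %in% c("AD", "HC"))) stop("EEG labels must be AD/HC", call. = FALSE)
  if (!all(CLASS_LEVELS %in% ys)) {
    stop("speech training data must contain all three classes", call. = FALSE)
  }
  d_s <- ncol(fs$X); d_e <- ncol(fe$X); d_z <- cfg$subspace_dim
  eeg_hidden <- if (is.null(cfg$eeg_hidden)) { if (d_e <= 64) 64 else 512 } else cfg$eeg_hidden

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)

  enc_s <- .make_encoder(d_s, cfg$speech_hidden, d_z, cfg$dropout)
  enc_e <- .make_encoder(d_e, eeg_hidden, d_z, cfg$dropout)
  clf <- list(nn_dense(d_z, 3))
  disc <- list(nn_dense(d_z, 64), nn_act("relu"), nn_dense(64, 1))
  centers <- matrix(stats::rnorm(3 * d_z, sd = 0.1), 3, d_z,
                    dimnames = list(CLASS_LEVELS, NULL))

  st_s <- adam_init(enc_s); st_e <- adam_init(enc_e)
  st_c <- adam_init(clf); st_d <- adam_init(disc)

  props <- table(factor(ys, CLASS_LEVELS)) / length(ys)
  props <- stats::setNames(as.numeric(props), CLASS_LEVELS)

  history <- vector("list", cfg$epochs)
  step <- 0
  for (ep in seq_len(cfg$epochs)) {
    lr <- cfg$lr * 0.5^((ep - 1) %/% cfg$lr_step)
    lam_p <- grl_factor(if (cfg$epochs > 1) (ep - 1) / (cfg$epochs - 1) else 1,
                        cfg$grl_ceiling, cfg$grl_schedule)
    batches <- paired_batches(nrow(fs$X), nrow(fe$X), cfg$batch_size,
                              seed = cfg$seed + ep)
    acc <- c(L_cls = 0, L_center = 0, L_domain = 0, L_consist = 0, L_total = 0)
    for (bt in batches) {
      Xb_s <- fs$X[bt$speech, , drop = FALSE]; yb_s <- ys[bt$speech]
      Xb_e <- fe$X[bt$eeg, , drop = FALSE]; yb_e <- ye[bt$eeg]
      f_s <- nn_forward(enc_s, Xb_s, training = TRUE)
      f_e <- nn_forward(enc_e, Xb_e, training = TRUE)
      Zs <- f_s$out; Ze <- f_e$out
      ns <- nrow(Zs); ne <- nrow(Ze)

      # --- pseudo-MCI anchors from pooled same-batch HC/AD latents
      Zall <- rbind(Zs, Ze); yall <- c(yb_s, yb_e)
      i_ad <- which(yall == "AD"); i_hc <- which(yall == "HC")
      npseudo <- if (cfg$pseudo_weight > 0) min(length(i_ad), length(i_hc)) else 0L
      if (npseudo > 0) {
        pick_ad <- sample(i_ad, npseudo)
        pick_hc <- sample(i_hc, npseudo)
        alpha <- stats::rbeta(npseudo, cfg$beta_a, cfg$beta_b)
        alpha <- pmin(pmax(alpha, 1e-6), 1 - 1e-6)
        Zp <- pseudo_mci(Zall[pick_ad, , drop = FALSE],
                         Zall[pick_hc, , drop = FALSE], alpha)
      } else {
        Zp <- matrix(0, 0, d_z)
      }

      # --- classification loss over speech + EEG + pseudo latents
      Zcls <- rbind(Zall, Zp)
      ycls <- c(yall, rep("MCI", npseudo))
      wcls <- c(rep(1, ns + ne), rep(cfg$pseudo_weight, npseudo))
      f_c <- nn_forward(clf, Zcls, training = TRUE)
      L_cls <- weighted_cross_entropy(f_c$out, ycls, props, wcls)
      dlogits <- wce_grad(f_c$out, ycls, props, wcls)
      b_c <- nn_backward(clf, f_c$caches, dlogits)
      dZ_cls <- b_c$dX

      # --- center loss (same sample set and weights)
      L_center <- center_loss(Zcls, ycls, centers, wcls)
      g_cen <- center_loss_grads(Zcls, ycls, centers, wcls)

      # --- consistency loss (real latents only)
      L_consist <- as.numeric(consistency_loss(Zs, yb_s, Ze, yb_e))
      g_con <- consistency_grads(Zs, yb_s, Ze, yb_e)

      # --- domain-adversarial loss on real latents behind the GRL
      Zd <- grl(Zall, lam_p)
      f_d <- nn_forward(disc, Zd, training = TRUE)
      dom_y <- c(rep(0, ns), rep(1, ne))
      pd <- sigmoid(f_d$out[, 1])
      L_domain <- -mean(dom_y * log(pmax(pd, 1e-12)) +
                        (1 - dom_y) * log(pmax(1 - pd, 1e-12)))
      dlog_d <- matrix((pd - dom_y) / length(dom_y), ncol = 1)
      b_d <- nn_backward(disc, f_d$caches, dlog_d)
      # reversed, scaled gradient into the encoders
      dZ_dom <- grl_backward(b_d$dX, lam_p) * cfg$lambda_domain

      # --- assemble encoder gradients
      dZ_all <- dZ_cls[seq_len(ns + ne), , drop = FALSE] +
        cfg$lambda_center * g_cen$dZ[seq_len(ns + ne), , drop = FALSE] +
        dZ_dom
      if (npseudo > 0) {
        dZp <- dZ_cls[(ns + ne) + seq_len(npseudo), , drop = FALSE] +
          cfg$lambda_center * g_cen$dZ[(ns + ne) + seq_len(npseudo), , drop = FALSE]
        # route pseudo gradients back to their source latents
        for (q in seq_len(npseudo)) {
          dZ_all[pick_ad[q], ] <- dZ_all[pick_ad[q], ] + alpha[q] * dZp[q, ]
          dZ_all[pick_hc[q], ] <- dZ_all[pick_hc[q], ] + (1 - alpha[q]) * dZp[q, ]
        }
      }
      dZs <- dZ_all[seq_len(ns), , drop = FALSE] + cfg$lambda_consist * g_con$dZs
      dZe <- dZ_all[ns + seq_len(ne), , drop = FALSE] + cfg$lambda_consist * g_con$dZe

      b_s <- nn_backward(enc_s, f_s$caches, dZs)
      b_e <- nn_backward(enc_e, f_e$caches, dZe)

      step <- step + 1
      u <- adam_step(enc_s, b_s$grads, st_s, step, lr, weight_decay = cfg$weight_decay)
      enc_s <- u$layers; st_s <- u$state
      u <- adam_step(enc_e, b_e$grads, st_e, step, lr, weight_decay = cfg$weight_decay)
      enc_e <- u$layers; st_e <- u$state
      u <- adam_step(clf, b_c$grads, st_c, step, lr, weight_decay = cfg$weight_decay)
      clf <- u$layers; st_c <- u$state
      # discriminator learns the (weighted) domain loss with the plain sign
      gd <- lapply(b_d$grads, function(g) if (is.null(g)) NULL else lapply(g, function(m) cfg$lambda_domain * m))
      u <- adam_step(disc, gd, st_d, step, lr, weight_decay = cfg$weight_decay)
      disc <- u$layers; st_d <- u$state
      # centers: separate SGD directly on the (unweighted) center loss
      centers <- centers - cfg$center_lr * g_cen$dC

      L_tot <- total_loss(L_cls, L_center, L_domain, L_consist, cfg)
      acc <- acc + c(L_cls, L_center, L_domain, L_consist, L_tot)
    }
    nb <- length(batches)
    acc <- unname(acc)
    history[[ep]] <- tibble::tibble(
      epoch = ep, L_cls = acc[1] / nb, L_center = acc[2] / nb,
      L_domain = acc[3] / nb, L_consist = acc[4] / nb,
      L_total = acc[5] / nb, lr = lr, lambda_grl = lam_p)
    enc_s <- nn_refresh_bn(enc_s, fs$X)
    enc_e <- nn_refresh_bn(enc_e, fe$X)
  }

  structure(list(encoder_speech = enc_s, encoder_eeg = enc_e,
                 classifier = clf, discriminator = disc, centers = centers,
                 config = cfg, class_proportions = props,
                 speech_features = fs$feature_names,
                 eeg_features = fe$feature_names,
                 history = dplyr::bind_rows(history)),
            class = "alignment_model")
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf("<alignment_model> speech %d-d and EEG %d-d -> shared %d-d subspace (%d epochs)\n",
              length(x$speech_features), length(x$eeg_features),
              x$config$subspace_dim, nrow(x$history)))
  invisible(x)
}

#' Encode a feature table into the aligned subspace
#'
#' Deterministic at inference: dropout off, batch-norm running statistics.
#'
#' @param model An `alignment_model`.
#' @param table Feature table of the named modality.
#' @param modality `"speech"` or `"eeg"`.
#' @return Tibble of metadata columns plus `A1..A<subspace_dim>`.
#' @export
align_encode <- function(model, table, modality = c("speech", "eeg")) {
  stopifnot(inherits(model, "alignment_model"))
  modality <- match.arg(modality)
  fm <- feature_matrix(table)
  expected <- if (modality == "speech") model$speech_features else model$eeg_features
  if (!identical(fm$feature_names, expected)) {
    stop("feature columns do not match the ", modality, " encoder", call. = FALSE)
  }
  enc <- if (modality == "speech") model$encoder_speech else model$encoder_eeg
  Z <- nn_forward(enc, fm$X, training = FALSE)$out
  colnames(Z) <- paste0("A", seq_len(ncol(Z)))
  dplyr::bind_cols(fm$meta, tibble::as_tibble(Z))
}
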