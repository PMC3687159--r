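# The structurally constrained feed-forward model. One input node per
# upper-layer TF, one hidden node per middle-layer TF, a single linear
# output. Input-to-hidden connectivity is masked by the cascade's edges:
# masked weights are pinned to exactly zero and are not part of the free
# parameter vector, so they stay zero before, during and after training.
# Hidden activation is the logistic sigmoid; the output is linear. Training
# minimizes mean squared error by Levenberg-Marquardt with an analytic
# Jacobian and validation-based early stopping.

#' Initialize a masked network for a cascade
#'
#' Free parameters (unmasked input weights, hidden biases, output weights,
#' output bias) are drawn i.i.d. uniform on \[-0.5, 0.5\] from a seeded
#' generator; masked entries are exactly 0. The free-parameter count is
#' `|input_edges| + 2 * |middle_tfs| + 1`.
#'
#' @param cascade A [cascade()] object.
#' @param seed Integer seed.
#' @return An object of class `cascade_ann`: list with `cascade`, `mask`
#'   (upper x middle 0/1), `W_in`, `b_mid`, `w_out`, `b_out`.
#' @export
init_ann <- function(cascade, seed = 1) {
  nu <- length(cascade$upper_tfs)
  nm <- length(cascade$middle_tfs)
  mask <- matrix(0, nu, nm, dimnames = list(cascade$upper_tfs,
                                            cascade$middle_tfs))
  mask[cbind(match(cascade$input_edges$upper, cascade$upper_tfs),
             match(cascade$input_edges$middle, cascade$middle_tfs))] <- 1
  n_free <- sum(mask) + 2 * nm + 1
  theta <- with_seed(seed, stats::runif(n_free, -0.5, 0.5))
  ann <- structure(list(cascade = cascade, mask = mask,
                        W_in = matrix(0, nu, nm,
                                      dimnames = dimnames(mask)),
                        b_mid = numeric(nm), w_out = numeric(nm),
                        b_out = 0),
                   class = "cascade_ann")
  set_free_params(ann, theta)
}

#' Number of free (trainable) parameters of a network
#' @param ann A `cascade_ann`.
#' @return Integer count: `|input_edges| + 2 * |middle_tfs| + 1`.
#' @export
n_free_params <- function(ann) {
  as.integer(sum(ann$mask) + 2 * length(ann$b_mid) + 1)
}

# Pack the free parameters into a vector; fixed order: unmasked W_in entries
# (column-major), b_mid, w_out, b_out.
get_free_params <- function(ann) {
  c(ann$W_in[ann$mask == 1], ann$b_mid, ann$w_out, ann$b_out)
}

set_free_params <- function(ann, theta) {
  nm <- length(ann$b_mid)
  nw <- sum(ann$mask)
  abort_if(length(theta) != nw + 2 * nm + 1,
           "parameter vector has wrong length")
  ann$W_in[ann$mask == 1] <- theta[seq_len(nw)]
  ann$b_mid <- theta[nw + seq_len(nm)]
  ann$w_out <- theta[nw + nm + seq_len(nm)]
  ann$b_out <- theta[nw + 2 * nm + 1]
  ann
}

#' Forward pass of a masked network
#'
#' `h = logsig(X W_in + b_mid)`, `y = h w_out + b_out`; the hidden layer is
#' logistic-sigmoid, the output strictly linear.
#'
#' @param ann A `cascade_ann`.
#' @param X Numeric matrix, samples x upper TFs, columns in `upper_tfs`
#'   order.
#' @return Numeric vector of predictions, one per sample.
#' @export
ann_forward <- function(ann, X) {
  X <- as.matrix(X)
  bad <- which(!is.finite(X), arr.ind = TRUE)
  abort_if(nrow(bad) > 0, "non-finite input at sample %d", bad[1, 1])
  h <- logsig(sweep(X %*% ann$W_in, 2, ann$b_mid, "+"))
  drop(h %*% ann$w_out) + ann$b_out
}

# Hidden activations and the n x p Jacobian of predictions w.r.t. the free
# parameter vector (closed-form logsig chain). Residuals r = pred - y share
# this Jacobian.
ann_jacobian <- function(ann, X) {
  n <- nrow(X)
  nm <- length(ann$b_mid)
  H <- logsig(sweep(X %*% ann$W_in, 2, ann$b_mid, "+"))
  D <- H * (1 - H)
  cols_w <- vector("list", nm)
  cols_b <- matrix(0, n, nm)
  for (j in seq_len(nm)) {
    free_i <- which(ann$mask[, j] == 1)
    dz <- ann$w_out[j] * D[, j]
    cols_w[[j]] <- X[, free_i, drop = FALSE] * dz
    cols_b[, j] <- dz
  }
  # column-major order over the mask matches get_free_params()
  J <- cbind(do.call(cbind, cols_w), cols_b, H, rep(1, n))
  dimnames(J) <- NULL
  list(H = H, J = J)
}

#' Training hyperparameters for Levenberg-Marquardt
#'
#' @param max_epochs Maximum training epochs (default 100).
#' @param lambda0 Initial damping factor (default 1e-3).
#' @param lambda_up Damping multiplier on a rejected step (default 10).
#' @param lambda_down Damping multiplier on an accepted step (default 0.1).
#' @param val_patience Consecutive epochs without validation-MSE improvement
#'   before stopping (default 6).
#' @param goal_mse Training-MSE goal; reaching it stops training (default 0).
#' @param max_retries Damping retries within one epoch before giving up
#'   (default 10).
#' @param lambda_max Damping overflow bound; training stops beyond it
#'   (default 1e10).
#' @return A list of class `train_params`.
#' @export
train_params <- function(max_epochs = 100, lambda0 = 1e-3, lambda_up = 10,
                         lambda_down = 0.1, val_patience = 6, goal_mse = 0,
                         max_retries = 10, lambda_max = 1e10) {
  abort_if(lambda0 <= 0, "lambda0 must be > 0")
  abort_if(!(lambda_up > 1 && lambda_down < 1 && lambda_down > 0),
           "require lambda_up > 1 > lambda_down > 0")
  structure(list(max_epochs = max_epochs, lambda0 = lambda0,
                 lambda_up = lambda_up, lambda_down = lambda_down,
                 val_patience = val_patience, goal_mse = goal_mse,
                 max_retries = max_retries, lambda_max = lambda_max),
            class = "train_params")
}

#' Train a masked network by Levenberg-Marquardt
#'
#' Each epoch solves `(J'J + lambda I) delta = J'r` over the free parameters
#' only (masked weights are excluded from the parameter vector entirely) and
#' accepts the step iff the training MSE decreases, lowering the damping;
#' otherwise the damping is raised and the step retried a bounded number of
#' times. Training stops at `max_epochs`, at `goal_mse`, on damping overflow,
#' or after `val_patience` epochs without validation improvement. The
#' parameters with the best validation MSE seen are returned (early
#' stopping), not the last epoch's.
#'
#' @param ann A `cascade_ann` from [init_ann()].
#' @param X_train,y_train Training design (samples x upper TFs) and targets.
#' @param X_val,y_val Optional validation design and targets; when absent,
#'   best-so-far tracking falls back to the training MSE.
#' @param params A [train_params()] object.
#' @return List with `ann` (trained network, best-validation weights),
#'   `trace` (data frame: epoch, train_mse, val_mse, lambda, accepted) and
#'   `stop_reason`.
#' @export
train_lm <- function(ann, X_train, y_train, X_val = NULL, y_val = NULL,
                     params = train_params()) {
  X_train <- as.matrix(X_train)
  abort_if(nrow(X_train) < 1, "need >= 1 training sample")
  abort_if(length(y_train) != nrow(X_train),
           "y_train length does not match X_train")
  has_val <- !is.null(X_val) && nrow(as.matrix(X_val)) > 0
  if (has_val) X_val <- as.matrix(X_val)

  theta <- get_free_params(ann)
  p <- length(theta)
  lambda <- params$lambda0

  mse_of <- function(th, X, y) {
    a <- set_free_params(ann, th)
    mean((ann_forward(a, X) - y)^2)
  }
  train_mse <- mse_of(theta, X_train, y_train)
  val_mse <- if (has_val) mse_of(theta, X_val, y_val) else train_mse
  best_theta <- theta
  best_val <- val_mse
  bad_epochs <- 0L
  stop_reason <- "max_epochs"
  trace <- vector("list", params$max_epochs)

  for (epoch in seq_len(params$max_epochs)) {
    if (train_mse <= params$goal_mse) { stop_reason <- "goal_mse"; break }
    cur <- set_free_params(ann, theta)
    jac <- ann_jacobian(cur, X_train)
    r <- drop(jac$H %*% cur$w_out) + cur$b_out - y_train
    A <- crossprod(jac$J)
    g <- crossprod(jac$J, r)
    accepted <- FALSE
    for (try in seq_len(params$max_retries)) {
      delta <- tryCatch(solve(A + lambda * diag(p), g),
                        error = function(e) NULL)
      if (is.null(delta)) {
        lambda <- lambda * params$lambda_up
        if (lambda > params$lambda_max) break
        next
      }
      cand <- theta - drop(delta)
      cand_mse <- mse_of(cand, X_train, y_train)
      if (is.finite(cand_mse) && cand_mse < train_mse) {
        theta <- cand
        train_mse <- cand_mse
        lambda <- max(lambda * params$lambda_down, 1e-12)
        accepted <- TRUE
        break
      }
      lambda <- lambda * params$lambda_up
      if (lambda > params$lambda_max) break
    }
    val_mse <- if (has_val) mse_of(theta, X_val, y_val) else train_mse
    trace[[epoch]] <- data.frame(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse, lambda = lambda,
                                 accepted = accepted)
    if (val_mse < best_val) {
      best_val <- val_mse
      best_theta <- theta
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
    }
    if (lambda > params$lambda_max) { stop_reason <- "lambda_overflow"; break }
    if (!accepted) { stop_reason <- "no_step"; break }
    if (bad_epochs >= params$val_patience) {
      stop_reason <- "val_patience"
      break
    }
  }
  list(ann = set_free_params(ann, best_theta),
       trace = do.call(rbind, Filter(Negate(is.null), trace)),
       stop_reason = stop_reason)
}

#' Serialize a trained network to a text file
#'
#' Stores the cascade wiring, the mask and the flat free-parameter vector as
#' one JSON record, so a fitted model can be reloaded exactly.
#'
#' @param ann A `cascade_ann`.
#' @param path Output path.
#' @return Invisibly, `ann`.
#' @export
write_ann <- function(ann, path) {
  rec <- list(target_gene = ann$cascade$target_gene,
              middle_tfs = ann$cascade$middle_tfs,
              upper_tfs = ann$cascade$upper_tfs,
              edge_upper = ann$cascade$input_edges$upper,
              edge_middle = ann$cascade$input_edges$middle,
              category = ann$cascade$category,
              source_module = ann$cascade$source_module,
              theta = get_free_params(ann))
  writeLines(jsonlite::toJSON(rec, auto_unbox = FALSE, digits = I(17),
                              na = "null"), path)
  invisible(ann)
}

#' Read a trained network written by [write_ann()]
#' @param path Input path.
#' @return A `cascade_ann`.
#' @export
read_ann <- function(path) {
  rec <- jsonlite::fromJSON(paste(readLines(path), collapse = ""))
  cs <- cascade(target_gene = rec$target_gene, middle_tfs = rec$middle_tfs,
                upper_tfs = rec$upper_tfs,
                input_edges = data.frame(upper = rec$edge_upper,
                                         middle = rec$edge_middle,
                                         stringsAsFactors = FALSE),
                category = if (is.null(rec$category)) NA_character_
                           else rec$category,
                source_module = if (is.null(rec$source_module)) NA_integer_
                                else rec$source_module)
  set_free_params(init_ann(cs, seed = 0), rec$theta)
}
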