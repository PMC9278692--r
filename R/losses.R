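# The five-term training objective. Each loss is a standalone operation so
# alternates can be swapped in; the training loop composes them with the
# analytic gradients defined alongside.

as_patch <- function(x) {
  if (is.matrix(x)) x
  else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L)
    matrix(x, dim(x)[1], dim(x)[2])
  else stop("expected a 2D patch (matrix or HxWx1 array)")
}

#' Loss weights of the five-term objective
#'
#' Defaults follow the published hyper-parameter summary: cycle 10, all
#' other terms 1.
#' @param cycle,adv,grad,idem,tv non-negative weights.
#' @return named numeric vector of class `loss_weights`.
#' @export
loss_weights <- function(cycle = 10, adv = 1, grad = 1, idem = 1, tv = 1) {
  w <- c(cycle = cycle, adv = adv, grad = grad, idem = idem, tv = tv)
  if (any(w < 0)) stop("loss weights must be >= 0")
  structure(w, class = c("loss_weights", "numeric"))
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between a patch and its cyclic reconstruction
#' (through a generator and its inverse).
#' @param x original patch; `x_cyclic` its reconstruction (same shape).
#' @param x_cyclic cyclically reconstructed patch.
#' @return scalar >= 0; 0 iff the cycle is exact.
#' @export
loss_cycle <- function(x, x_cyclic) {
  x <- as_patch(x); x_cyclic <- as_patch(x_cyclic)
  if (!identical(dim(x), dim(x_cyclic))) stop("patch shapes differ")
  mean(abs(x - x_cyclic))
}

#' Least-squares adversarial loss
#'
#' The discriminator minimises `mean((real - 1)^2) + mean(fake^2)`; the
#' generator minimises `mean((fake - 1)^2)`.
#' @param score_fake discriminator score map on generated patches.
#' @param score_real score map on real patches (discriminator role only).
#' @param role "generator" or "discriminator".
#' @return scalar >= 0.
#' @export
loss_adv <- function(score_fake, score_real = NULL,
                     role = c("generator", "discriminator")) {
  role <- match.arg(role)
  if (role == "generator") return(mean((score_fake - 1)^2))
  if (is.null(score_real)) stop("discriminator role needs real scores")
  mean((score_real - 1)^2) + mean(score_fake^2)
}

patch_diffs <- function(m) {
  h <- nrow(m); w <- ncol(m)
  list(dx = m[, 2:w, drop = FALSE] - m[, 1:(w - 1), drop = FALSE],
       dy = m[2:h, , drop = FALSE] - m[1:(h - 1), , drop = FALSE])
}

#' Gradient loss
#'
#' Mean absolute difference between the finite-difference gradient
#' magnitudes of input and output (x and y difference images averaged);
#' preserves edges while being invariant to intensity offsets.
#' @param input,output patches of the same shape.
#' @return scalar >= 0.
#' @export
loss_grad <- function(input, output) {
  input <- as_patch(input); output <- as_patch(output)
  if (!identical(dim(input), dim(output))) stop("patch shapes differ")
  di <- patch_diffs(input); do <- patch_diffs(output)
  (mean(abs(abs(di$dx) - abs(do$dx))) + mean(abs(abs(di$dy) - abs(do$dy)))) / 2
}

#' Idempotence loss
#'
#' A generator applied to an image already in its target domain should
#' change nothing: mean absolute difference between `g(y)` and `y`.
#' @param g a trained generator (see [build_generator()]) or any function
#'   mapping a patch to a patch.
#' @param y patch drawn from the generator's target domain.
#' @return scalar >= 0; 0 when `g` is the identity on `y`.
#' @export
loss_idem <- function(g, y) {
  y <- as_patch(y)
  gy <- if (is.function(g)) g(y) else generator_apply(g, y)
  mean(abs(as_patch(gy) - y))
}

#' Anisotropic total-variation loss
#'
#' Sum of absolute neighbour differences along x and y, normalised by the
#' pixel count; discourages spurious high-frequency texture.
#' @param output patch.
#' @return scalar >= 0; 0 for constant patches.
#' @export
loss_tv <- function(output) {
  m <- as_patch(output)
  d <- patch_diffs(m)
  (sum(abs(d$dx)) + sum(abs(d$dy))) / length(m)
}

#' Weighted total objective
#'
#' @param terms named list/vector with elements `cycle`, `adv`, `grad`,
#'   `idem`, `tv` (unweighted per-term values).
#' @param weights a [loss_weights()].
#' @return list with `total` and the weighted `breakdown`.
#' @export
total_objective <- function(terms, weights = loss_weights()) {
  nm <- c("cycle", "adv", "grad", "idem", "tv")
  if (!all(nm %in% names(terms))) stop("terms must name cycle/adv/grad/idem/tv")
  contrib <- vapply(nm, function(k) unname(weights[k] * terms[[k]]), 0)
  list(total = sum(contrib), breakdown = contrib)
}

# ---- analytic gradients used by the training loop ---------------------------

d_l1 <- function(out, ref) sign(out - ref) / length(out)

d_lsgan_gen <- function(score) 2 * (score - 1) / length(score)

# d loss_grad / d output (input fixed)
d_loss_grad_out <- function(input, output) {
  inm <- as_patch(input); om <- as_patch(output)
  di <- patch_diffs(inm); do <- patch_diffs(om)
  g <- matrix(0, nrow(om), ncol(om))
  sx <- sign(abs(do$dx) - abs(di$dx)) * sign(do$dx) / (2 * length(do$dx))
  sy <- sign(abs(do$dy) - abs(di$dy)) * sign(do$dy) / (2 * length(do$dy))
  w <- ncol(om); h <- nrow(om)
  g[, 2:w] <- g[, 2:w] + sx; g[, 1:(w - 1)] <- g[, 1:(w - 1)] - sx
  g[2:h, ] <- g[2:h, ] + sy; g[1:(h - 1), ] <- g[1:(h - 1), ] - sy
  g
}

d_loss_tv_out <- function(output) {
  om <- as_patch(output)
  d <- patch_diffs(om)
  g <- matrix(0, nrow(om), ncol(om))
  sx <- sign(d$dx) / length(om); sy <- sign(d$dy) / length(om)
  w <- ncol(om); h <- nrow(om)
  g[, 2:w] <- g[, 2:w] + sx; g[, 1:(w - 1)] <- g[, 1:(w - 1)] - sx
  g[2:h, ] <- g[2:h, ] + sy; g[1:(h - 1), ] <- g[1:(h - 1), ] - sy
  g
}
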