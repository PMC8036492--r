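# Intensity-based registration: multi-resolution maximisation of
# cross-correlation over parameterised transforms, plus a demons-style
# non-parametric refinement. Any engine meeting the same contract
# (similarity never decreases, known motions recovered) would be
# interchangeable here.

# normalized cross-correlation between a warped moving image and the fixed
# samples; `fix_vals` are the fixed intensities at the sample points.
ncc_value <- function(warped, fix_vals) {
  s <- stats::sd(warped)
  if (!is.finite(s) || s == 0) return(-1)
  stats::cor(warped, fix_vals)
}

# Images arrive intensity-normalised, so the (brain-extracted) background
# is a non-zero constant; shift it back to exactly zero — taken from the
# corner voxel, which is always outside the head — so that zero-filled
# out-of-bounds samples blend seamlessly and brain masking is trivial.
.rezero <- function(v) {
  bg <- v$data[1, 1, 1]
  if (bg != 0 && mean(v$data == bg) > 0.05) v$data <- v$data - bg
  v
}

# Downsample both images to `spc` mm with a matched pre-blur, and return
# sample points (world), fixed values and moving array for fast NCC evals.
# `stride` keeps full image resolution but samples only every stride-th
# head voxel of the fixed grid (cheap sharp refinement level).
.reg_level <- function(moving, fixed, spc, stride = 1L, sigma = NULL) {
  moving <- .rezero(moving); fixed <- .rezero(fixed)
  blur <- function(v, s) {
    if (s <= 0) return(v)
    out <- v
    out$data <- array(cpp_gauss_blur3(as.double(v$data), dim(v$data),
                                      rep(s, 3) / v$spacing), dim(v$data))
    out
  }
  if (is.null(sigma)) sigma <- spc / 2
  f <- blur(fixed, sigma)
  m <- blur(moving, sigma)
  if (!all(abs(fixed$spacing - spc) < 1e-9)) {
    f <- resample_isotropic(f, spc, order = 1L)
    m <- resample_isotropic(m, spc, order = 1L)
  }
  idx <- grid_index(dim(f$data))
  keep <- which(f$data != 0)
  if (stride > 1L && length(keep) > 2000L)
    keep <- keep[as.logical(rowSums(idx[keep, , drop = FALSE] %% stride) == 0)]
  if (length(keep) < 100) keep <- seq_len(nrow(idx))
  list(fixed = f, moving = m,
       wpts = vox_to_world(f, idx[keep, , drop = FALSE]),
       fvals = as.double(f$data)[keep])
}

.reg_objective <- function(level, center, npar) {
  force(level); force(center)
  function(par) {
    full <- numeric(npar)
    full[seq_along(par)] <- par
    A <- params_to_affine(full, center)
    mpts <- cbind(level$wpts, 1) %*% t(A)
    mvox <- world_to_vox(level$moving, mpts[, 1:3, drop = FALSE])
    w <- cpp_interp3(as.double(level$moving$data), dim(level$moving$data),
                     mvox, 3L, 0)
    -ncc_value(w, level$fvals)
  }
}

# analytic gradient of -NCC w.r.t. the transform parameters: chain rule
# through the exact derivative of the trilinear interpolant.
.reg_gradient <- function(level, center, npar) {
  m <- level$moving
  md <- dim(m$data)
  Minv <- solve(m$xform)[1:3, 1:3]
  fc <- level$fvals - mean(level$fvals)
  fc <- fc / sqrt(sum(fc^2))
  wpts1 <- cbind(level$wpts, 1)
  function(par) {
    full <- numeric(npar)
    full[seq_along(par)] <- par
    A <- params_to_affine(full, center)
    mvox <- world_to_vox(m, (wpts1 %*% t(A))[, 1:3, drop = FALSE])
    vg <- cpp_interp3_grad(as.double(m$data), md, mvox, 0, order = 3L)
    w <- vg[, 1]
    wc <- w - mean(w)
    nw <- sqrt(sum(wc^2))
    if (nw == 0) return(numeric(length(par)))
    wc <- wc / nw
    n <- sum(wc * fc)
    dndw <- (fc - n * wc) / nw
    gv <- vg[, 2:4, drop = FALSE]
    out <- numeric(length(par))
    h <- 1e-6
    for (p in seq_along(par)) {
      e <- full; e[p] <- e[p] + h
      dA <- (params_to_affine(e, center) - A) / h
      dxi <- (wpts1 %*% t(dA))[, 1:3, drop = FALSE] %*% t(Minv)
      out[p] <- -sum(dndw * rowSums(gv * dxi))
    }
    out
  }
}

# monotone steepest descent with backtracking in parscale-normalised
# space; robust to the kinks of the piecewise-linear interpolation
# objective where curvature-based line searches can stall.
.descend <- function(obj, grad, par, scales, maxit, tol = 1e-9) {
  x <- par / scales
  fo <- function(x) obj(x * scales)
  go <- function(x) grad(x * scales) * scales
  f <- fo(x)
  step <- 0.1
  for (it in seq_len(maxit)) {
    g <- go(x)
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-14)
      return(list(par = x * scales, value = f, converged = TRUE))
    d <- -g / gn
    improved <- FALSE
    while (step > 1e-7) {
      f2 <- fo(x + step * d)
      if (is.finite(f2) && f2 < f - 1e-12) {
        x <- x + step * d
        f <- f2
        step <- step * 1.6
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved)
      return(list(par = x * scales, value = f, converged = TRUE))
    if (step * gn < tol)
      return(list(par = x * scales, value = f, converged = TRUE))
  }
  list(par = x * scales, value = f, converged = FALSE)
}

.check_degenerate <- function(moving, fixed) {
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("cannot register constant (degenerate) images")
}

# staged optimisation: derivative-free Nelder-Mead on the coarse levels
# (captures large motions), BFGS with the analytic NCC gradient on the
# finer levels (sharp, reliable convergence of rotations and scales).
.reg_optimize <- function(moving, fixed, center, npar, stages, maxit) {
  par <- numeric(npar)
  scales <- c(rep(1, 3), rep(0.02, 3), rep(0.02, 3), rep(0.02, 3))[seq_len(npar)]
  conv_warn <- FALSE
  last <- length(stages)
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    lvl <- .reg_level(moving, fixed, st$spc,
                      if (is.null(st$stride)) 1L else st$stride,
                      sigma = st$sigma)
    obj <- .reg_objective(lvl, center, npar)
    if (identical(st$method, "grad")) {
      grad <- .reg_gradient(lvl, center, npar)
      k <- max(st$subsets)
      k0 <- par[seq_len(k)]
      fit <- stats::optim(k0, obj, gr = grad, method = "BFGS",
                          control = list(maxit = maxit,
                                         parscale = scales[seq_len(k)],
                                         reltol = 1e-10))
      if (fit$convergence != 0 && si == last) conv_warn <- TRUE
      best <- if (fit$value <= obj(k0)) fit$par else k0
      # BFGS line searches occasionally stall where the sampled objective
      # is locally rough; a short monotone backtracking polish recovers
      res <- .descend(obj, grad, best, scales[seq_len(k)], 50L)
      if (res$value <= obj(best)) best <- res$par
      par[seq_len(k)] <- best
    } else {
      for (k in st$subsets) {
        fit <- stats::optim(par[seq_len(k)], function(p) {
          q <- par; q[seq_len(k)] <- p; obj(q[seq_len(k)])
        }, method = "Nelder-Mead",
        control = list(maxit = maxit, parscale = scales[seq_len(k)],
                       reltol = 1e-7))
        if (fit$convergence != 0 && si == last) conv_warn <- TRUE
        if (fit$value <= obj(par[seq_len(k)])) par[seq_len(k)] <- fit$par
      }
    }
  }
  if (conv_warn)
    warning("registration optimizer hit its iteration limit; returning best transform found")
  par
}

#' Affine atlas-to-subject registration
#'
#' Estimates the 12-parameter affine (translation, rotation, per-axis
#' scale, shear) maximising the cross-correlation between the warped
#' moving image and the fixed image, coarse-to-fine (4 mm then 2 mm
#' grids, each pre-blurred), growing the parameter set translation ->
#' rigid -> similarity -> full affine. Both inputs are expected to be
#' intensity-normalised and isotropically resampled.
#'
#' @param moving,fixed [volume]s; `moving` is mapped onto `fixed`.
#' @param maxit Nelder-Mead iteration cap per stage.
#' @return A [spatial_transform] (fixed-world to moving-world).
#' @export
register_affine <- function(moving, fixed, maxit = 400) {
  .check_degenerate(moving, fixed)
  center <- grid_center(fixed)
  stages <- list(list(spc = 4, subsets = c(3, 6, 9)),
                 list(spc = 2, subsets = 12, method = "grad"))
  par <- .reg_optimize(moving, fixed, center, 12L, stages, maxit)
  spatial_transform(params_to_affine(par, center))
}

#' Rigid (6-parameter) registration
#'
#' Same engine as [register_affine] restricted to rotation plus
#' translation; used by the test-retest protocol to co-register repeat
#' scans of one subject.
#'
#' @inheritParams register_affine
#' @return A rigid [spatial_transform]; the linear block has all singular
#'   values equal to 1.
#' @export
rigid_register <- function(moving, fixed, maxit = 400) {
  .check_degenerate(moving, fixed)
  center <- grid_center(fixed)
  stages <- list(list(spc = 4, subsets = c(3, 6)),
                 list(spc = 2, subsets = 6, method = "grad"),
                 list(spc = 1, subsets = 6, stride = 2L,
                      sigma = 1.0, method = "grad"))
  par <- .reg_optimize(moving, fixed, center, 6L, stages, maxit)
  spatial_transform(params_to_affine(par, center))
}

#' Non-linear registration refinement
#'
#' Refines an affine initialisation with a dense displacement field using
#' a demons-style iteration (intensity-difference forces projected on the
#' warped-image gradient, Gaussian field regularisation) on a 2 mm grid,
#' then upsamples the field to the fixed grid. If the refined field does
#' not improve cross-correlation over the affine alone, a zero field is
#' returned with a warning.
#'
#' @param moving,fixed [volume]s, as in [register_affine].
#' @param init affine [spatial_transform] from [register_affine].
#' @param iters demons iterations.
#' @param sigma_field Gaussian regularisation SD of the field, in
#'   level-grid voxels.
#' @param step update step scale.
#' @return A [spatial_transform] carrying `init`'s affine plus a dense
#'   displacement field on `fixed`'s grid.
#' @export
register_nonlinear <- function(moving, fixed, init, iters = 30,
                               sigma_field = 1.5, step = 0.8) {
  .check_degenerate(moving, fixed)
  stopifnot(inherits(init, "spatial_transform"))
  spc <- 2
  lvl <- .reg_level(moving, fixed, spc)
  f <- lvl$fixed; m <- lvl$moving
  d <- dim(f$data)
  idx <- grid_index(d)
  wpts <- vox_to_world(f, idx)
  base <- cbind(wpts, 1) %*% t(init$affine)
  base <- base[, 1:3, drop = FALSE]
  disp <- matrix(0, nrow(base), 3)  # world mm
  fvec <- as.double(f$data)

  warp_now <- function() {
    mvox <- world_to_vox(m, base + disp)
    cpp_interp3(as.double(m$data), dim(m$data), mvox, 1L, 0)
  }
  grad3 <- function(arr) {
    a <- array(arr, d)
    g <- matrix(0, length(arr), 3)
    sh <- function(ax, by) {
      i <- lapply(d, seq_len)
      i[[ax]] <- pmin(pmax(i[[ax]] + by, 1L), d[ax])
      a[i[[1]], i[[2]], i[[3]]]
    }
    for (ax in 1:3)
      g[, ax] <- as.double(sh(ax, 1L) - sh(ax, -1L)) / (2 * spc)
    g
  }

  ncc0 <- ncc_value(warp_now()[f$data != 0], fvec[f$data != 0])
  for (it in seq_len(iters)) {
    w <- warp_now()
    diff <- fvec - w
    g <- grad3(w)
    gn2 <- rowSums(g^2)
    denom <- gn2 + diff^2 / (spc * spc)
    upd <- g * (diff / pmax(denom, 1e-8))
    # cap the per-iteration update at one level voxel
    un <- sqrt(rowSums(upd^2))
    cap <- un > spc
    if (any(cap)) upd[cap, ] <- upd[cap, ] * (spc / un[cap])
    disp <- disp + step * upd
    for (ax in 1:3)
      disp[, ax] <- cpp_gauss_blur3(disp[, ax], d, rep(sigma_field, 3))
  }
  ncc1 <- ncc_value(warp_now()[f$data != 0], fvec[f$data != 0])
  if (!is.finite(ncc1) || ncc1 < ncc0) {
    warning("non-linear refinement did not improve cross-correlation; keeping affine only")
    disp[] <- 0
  }

  # upsample the field to the fixed grid (per-component linear interp)
  df <- dim(fixed$data)
  out <- array(0, c(df, 3))
  idx_full <- grid_index(df)
  wfull <- vox_to_world(fixed, idx_full)
  lvox <- world_to_vox(f, wfull)
  for (ax in 1:3)
    out[, , , ax] <- array(cpp_interp3(disp[, ax], d, lvox, 1L, 0), df)
  spatial_transform(init$affine, out, fixed_geom = fixed)
}
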