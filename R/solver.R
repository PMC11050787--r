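# Quasi-static equilibrium solver for the force-controlled DOFs.
#
# Flexion is prescribed; the remaining coordinates are found by driving the
# generalized forces (contact + applied ligament wrench) to zero with a
# damped Newton iteration on a central-difference Jacobian. Generalized
# forces are obtained by projecting wrenches onto the numeric twist of each
# free coordinate, which accounts exactly for the kinematic coupling of the
# rotation sequence and the tibial-frame translation convention.

.POSE_COORDS <- c("flexion", "adduction", "internal", "ap", "ml", "dp")
.ANGLE_COORDS <- c("flexion", "adduction", "internal")

.pose_set <- function(pose, name, value) {
  pose[[name]] <- value
  pose
}

# Twist (v at reference point, omega) of each free coordinate, per mm for
# translations and per radian for rotations.
.free_twists <- function(pose, free_dofs, ref_point) {
  T0 <- pose_to_transform(pose)
  h <- 1e-6
  lapply(free_dofs, function(nm) {
    Tp <- pose_to_transform(.pose_set(pose, nm, pose[[nm]] + h))
    Tm <- pose_to_transform(.pose_set(pose, nm, pose[[nm]] - h))
    dR <- (Tp$R - Tm$R) / (2 * h)
    dt <- (Tp$t - Tm$t) / (2 * h)
    Om <- dR %*% t(T0$R)
    omega <- c(Om[3, 2], Om[1, 3], Om[2, 1])
    v <- dt + as.numeric(dR %*% crossprod(T0$R, ref_point - T0$t))
    if (nm %in% .ANGLE_COORDS) {
      omega <- omega * 180 / pi
      v <- v * 180 / pi
    }
    list(v = v, omega = omega)
  })
}

# Project a list of wrenches (force, moment about ref_point) onto the free
# coordinates. Units: N for translational coordinates, N mm for rotational.
.generalized_forces <- function(pose, free_dofs, wrenches, ref_point = c(0, 0, 0)) {
  tw <- .free_twists(pose, free_dofs, ref_point)
  vapply(seq_along(free_dofs), function(i) {
    sum(vapply(wrenches, function(w) {
      sum(w$force * tw[[i]]$v) + sum(w$moment * tw[[i]]$omega)
    }, 0))
  }, 0)
}

.residual_scale <- function(free_dofs, moment_arm = 30) {
  ifelse(free_dofs %in% .ANGLE_COORDS, 1 / moment_arm, 1)
}

.residual_converged <- function(r, free_dofs, tol_force, tol_moment) {
  ang <- free_dofs %in% .ANGLE_COORDS
  all(abs(r[!ang]) <= tol_force) && all(abs(r[ang]) <= tol_moment)
}

# Damped Newton (Levenberg-Marquardt trust region) on the scaled residual.
# residual_fn(pose) must return list(Q = numeric(free), ...extras).
.newton_equilibrium <- function(residual_fn, pose, free_dofs,
                                tol_force = 0.5, tol_moment = 50,
                                max_iter = 50) {
  fd_step <- rep(1e-3, length(free_dofs))
  scale <- .residual_scale(free_dofs)
  res <- residual_fn(pose)
  r <- res$Q
  best <- list(pose = pose, res = res, norm = sqrt(sum((r * scale)^2)))
  iter <- 0L
  lam <- 0
  converged <- .residual_converged(r, free_dofs, tol_force, tol_moment)

  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    J <- matrix(0, length(free_dofs), length(free_dofs))
    for (j in seq_along(free_dofs)) {
      nm <- free_dofs[j]
      rp <- residual_fn(.pose_set(pose, nm, pose[[nm]] + fd_step[j]))$Q
      rm <- residual_fn(.pose_set(pose, nm, pose[[nm]] - fd_step[j]))$Q
      J[, j] <- (rp - rm) / (2 * fd_step[j])
    }
    Js <- J * scale
    rs <- r * scale
    n <- length(rs)
    dref <- sqrt(max(colSums(Js^2), 1))

    improved <- FALSE
    for (k in 1:8) {
      dq <- tryCatch({
        if (lam == 0) as.numeric(qr.solve(Js, -rs))
        else as.numeric(qr.solve(rbind(Js, diag(sqrt(lam) * dref, n)),
                                 c(-rs, rep(0, n))))
      }, error = function(e) NULL)
      if (!is.null(dq) && all(is.finite(dq))) {
        # cap step size: 2 mm / 2 deg per coordinate per iteration
        cap <- max(abs(dq)) / 2
        if (cap > 1) dq <- dq / cap
        cand <- pose
        for (j in seq_along(free_dofs))
          cand[[free_dofs[j]]] <- pose[[free_dofs[j]]] + dq[j]
        cres <- residual_fn(cand)
        cnorm <- sqrt(sum((cres$Q * scale)^2))
        if (is.finite(cnorm) && cnorm < best$norm) {
          pose <- cand; res <- cres; r <- cres$Q
          best <- list(pose = pose, res = res, norm = cnorm)
          lam <- lam / 10
          if (lam < 1e-10) lam <- 0
          improved <- TRUE
          break
        }
      }
      lam <- if (lam == 0) 1e-4 else lam * 10
    }
    if (!improved) {
      # widen the difference step to average over mesh-facet kinks in the
      # contact gradient, then retry once with a fresh Jacobian
      if (fd_step[1] < 4e-3) {
        fd_step <- fd_step * 5
        lam <- 0
        next
      }
      break
    }
    converged <- .residual_converged(r, free_dofs, tol_force, tol_moment)
  }

  list(pose = best$pose, residual = best$res$Q, extras = best$res,
       converged = converged, iterations = iter,
       residual_norm = best$norm)
}
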