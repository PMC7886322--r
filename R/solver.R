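# Static, geometrically nonlinear solution of the loaded tendon.
#
# Total-Lagrangian Newton iteration: at each ramp step the residual
# r = f_ext - f_int(u) - f_iface(u) is driven below a relative tolerance.
# The sub-tendon interface is a set of matched node-pair penalties on the
# conforming interface surfaces: normal (n) and in-plane transverse (t2)
# relative displacements are penalised bilaterally (the "translational
# joint": separation and interpenetration are both resisted), while the
# longitudinal (t1) direction is free (frictionless), tied (bonded) or
# governed by an elastic-predictor/return-mapping Coulomb law (frictional).

#' Load case: isolated sub-tendon tension
#'
#' @param loaded character vector of sub-tendons receiving the proximal
#'   tensile force (usually one, loaded in isolation).
#' @param force force per loaded sub-tendon, N (default the 100 N used in
#'   the simulation protocol).
#' @param ramp_steps number of linear load increments.
#' @return a `load_case` object.
#' @export
load_case <- function(loaded, force = 100, ramp_steps = 10L) {
  stopifnot(all(loaded %in% SUB_TENDONS), force >= 0, ramp_steps >= 1)
  structure(list(loaded = loaded, force = force, ramp_steps = as.integer(ramp_steps)),
            class = "load_case")
}

#' Interface model between sub-tendons
#'
#' @param mode `"frictionless"`, `"frictional"` or `"bonded"`.
#' @param mu Coulomb friction coefficient (frictional mode only; the
#'   simulation protocol sweeps 0.2, 0.4, 0.6, 0.8, 1.0).
#' @param k_n,k_t normal / tangential penalty stiffness, MPa/mm per unit
#'   tributary area.
#' @return an `interface_model` object.
#' @export
interface_model <- function(mode = c("frictionless", "frictional", "bonded"),
                            mu = NULL, k_n = 1000, k_t = 1000) {
  mode <- match.arg(mode)
  if (mode == "frictional") {
    if (is.null(mu) || mu < 0) stop("frictional mode needs mu >= 0")
  } else mu <- NA_real_
  stopifnot(k_n > 0, k_t > 0)
  structure(list(mode = mode, mu = mu, k_n = k_n, k_t = k_t),
            class = "interface_model")
}

#' Penalty/return-mapping force update for one interface pair
#'
#' Pure function mapping the relative displacement of a node pair (side b
#' minus side a, expressed in the local frame) to the transmitted forces.
#' Normal (n) and transverse (t2) components are penalised bilaterally with
#' force -k * gap * area. Longitudinally (t1): frictionless transmits
#' nothing; bonded ties with the tangential penalty; frictional takes an
#' elastic trial force from the slip increment measured against the last
#' converged stick point and caps it at mu * |normal force| (slip).
#'
#' @param d relative displacement `c(n, t1, t2)` in mm.
#' @param interface an `interface_model`.
#' @param area tributary area of the pair, mm^2.
#' @param slip accumulated longitudinal slip at the last converged state, mm.
#' @return list with `normal_force` (N), `tangential_force` (`c(t1, t2)`,
#'   N) and `flag` (`"stick"` or `"slip"`, frictional mode only).
#' @export
interface_force_update <- function(d, interface, area, slip = 0) {
  stopifnot(inherits(interface, "interface_model"), length(d) == 3)
  if (any(!is.finite(d))) stop("non-finite relative displacement")
  kn <- interface$k_n * area
  kt <- interface$k_t * area
  fn <- -kn * d[1]
  ft2 <- -kt * d[3]
  flag <- NA_character_
  ft1 <- switch(interface$mode,
    frictionless = 0,
    bonded = -kt * d[2],
    frictional = {
      trial <- -kt * (d[2] - slip)
      cap <- interface$mu * abs(fn)
      if (abs(trial) <= cap) { flag <- "stick"; trial }
      else { flag <- "slip"; sign(trial) * cap }
    })
  list(normal_force = fn, tangential_force = c(ft1, ft2), flag = flag)
}

# Vectorised interface residual/stiffness over all pairs. Returns the global
# internal-force contribution, stiffness triplets, and the per-pair state.
# Convected pair frames: rebuild (n, t1, t2) from the deformed geometry of
# each pair's stored adjacent interface face, so a finite rotation of the
# stack does not convert true tangential sliding into parasitic normal
# penalty force. Frames are recomputed once per load increment and frozen
# during the Newton iterations (their within-step rotation is higher order).
interface_frames <- function(mesh, Umat) {
  pr <- mesh$interface_pairs
  if (length(pr$a) == 0)
    return(list(n = pr$normal, t1 = pr$t1, t2 = pr$t2))
  X <- mesh$nodes + Umat
  e1 <- X[pr$face_a[, 2], , drop = FALSE] - X[pr$face_a[, 1], , drop = FALSE]
  e2 <- X[pr$face_a[, 3], , drop = FALSE] - X[pr$face_a[, 1], , drop = FALSE]
  nc <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nc <- nc / sqrt(rowSums(nc^2))
  flip <- rowSums(nc * pr$normal) < 0
  nc[flip, ] <- -nc[flip, , drop = FALSE]
  t1c <- pr$t1_coef[, 1] * e1 + pr$t1_coef[, 2] * e2
  t1c <- t1c - rowSums(t1c * nc) * nc
  t1c <- t1c / sqrt(rowSums(t1c^2))
  t2c <- cbind(nc[, 2] * t1c[, 3] - nc[, 3] * t1c[, 2],
               nc[, 3] * t1c[, 1] - nc[, 1] * t1c[, 3],
               nc[, 1] * t1c[, 2] - nc[, 2] * t1c[, 1])
  list(n = nc, t1 = t1c, t2 = t2c)
}

interface_assemble <- function(mesh, U, interface, slip, want_state = TRUE,
                               frozen = NULL, frames = NULL) {
  pr <- mesh$interface_pairs
  P <- length(pr$a)
  N <- nrow(mesh$nodes)
  out <- list(f = numeric(3 * N), i = integer(0), j = integer(0), x = numeric(0),
              state = NULL, slip_new = slip)
  if (P == 0) return(out)
  ia <- 3 * (pr$a - 1); ib <- 3 * (pr$b - 1)
  Umat <- matrix(U, ncol = 3, byrow = TRUE)
  du <- Umat[pr$b, , drop = FALSE] - Umat[pr$a, , drop = FALSE]
  if (is.null(frames)) frames <- interface_frames(mesh, Umat)
  nc <- frames$n; t1c <- frames$t1; t2c <- frames$t2

  dn <- rowSums(du * nc)
  dt1 <- rowSums(du * t1c)
  dt2 <- rowSums(du * t2c)
  kn <- interface$k_n * pr$area
  kt <- interface$k_t * pr$area

  fn <- -kn * dn
  ft2 <- -kt * dt2
  kt1_eff <- numeric(P)
  flag <- rep(NA_character_, P)
  if (interface$mode == "frictionless") {
    ft1 <- numeric(P)
  } else if (interface$mode == "bonded") {
    ft1 <- -kt * dt1
    kt1_eff <- kt
  } else {
    trial <- -kt * (dt1 - slip)
    cap <- interface$mu * abs(fn)
    if (is.null(frozen)) {
      stick <- abs(trial) <= cap
      sgn <- sign(trial)
    } else {
      # frozen active set and cap near convergence (stops stick/slip
      # chattering; the normal force no longer moves appreciably there)
      stick <- frozen$stick
      sgn <- frozen$sgn
      cap <- frozen$cap
    }
    ft1 <- ifelse(stick, trial, sgn * cap)
    kt1_eff <- ifelse(stick, kt, 0)
    flag <- ifelse(stick, "stick", "slip")
    out$slip_new <- ifelse(stick, slip, dt1 + ft1 / kt)
    out$stick <- stick
    out$sgn <- sgn
    out$cap <- cap
  }

  # gradient of the pair energy w.r.t. u: +g on b rows, -g on a rows, where
  # g = -(fn n + ft1 t1 + ft2 t2) (the force transmitted onto side b).
  g <- -(fn * nc + ft1 * t1c + ft2 * t2c)
  # accumulate with duplicate-safe summation (a node can sit in several
  # pairs along the triple line between all three sub-tendons)
  idx <- c(rep(ib, 3) + rep(1:3, each = P), rep(ia, 3) + rep(1:3, each = P))
  val <- c(as.vector(g), -as.vector(g))
  f <- numeric(3 * N)
  acc <- rowsum(val, idx)
  f[as.integer(rownames(acc))] <- acc
  out$f <- f

  # 3x3 pair stiffness in global axes: kn n n' + kt1_eff t1 t1' + kt t2 t2'
  # frames are frozen within the iteration (their rotation contributes a
  # higher-order term the line search absorbs)
  Kblk <- matrix(0, P, 9)
  for (r in 1:3) for (c. in 1:3) {
    Kblk[, (r - 1) * 3 + c.] <- kn * nc[, r] * nc[, c.] +
      kt1_eff * t1c[, r] * t1c[, c.] + kt * t2c[, r] * t2c[, c.]
  }
  ii <- jj <- integer(0); xx <- numeric(0)
  for (r in 1:3) for (c. in 1:3) {
    v <- Kblk[, (r - 1) * 3 + c.]
    ii <- c(ii, ia + r, ib + r, ia + r, ib + r)
    jj <- c(jj, ia + c., ib + c., ib + c., ia + c.)
    xx <- c(xx, v, v, -v, -v)
  }
  out$i <- ii; out$j <- jj; out$x <- xx
  if (want_state)
    out$state <- tibble::tibble(pair = seq_len(P), normal_force = fn,
                                tangential_force_t1 = ft1,
                                tangential_force_t2 = ft2, flag = flag)
  out
}

# Cached triplet-to-CSC assembler: the kernel emits triplets in a fixed
# order, so the free-DOF filter, sorting permutation and column pointers are
# computed once per mesh; each Newton iteration only aggregates values
# (contiguous-group cumsum). Builds the reduced symmetric (free x free)
# upper-triangle matrix directly.
make_assembler <- function(i, j, free) {
  nred <- length(free)
  map <- integer(max(i, j))
  map[free] <- seq_len(nred)
  ir <- map[i]; jr <- map[j]
  keep <- which(ir > 0L & jr > 0L & ir <= jr)   # free-free, upper triangle
  key <- (as.numeric(jr[keep]) - 1) * nred + as.numeric(ir[keep])
  o <- order(key)
  ks <- key[o]
  uniq <- !duplicated(ks)
  ends <- c(which(uniq[-1]), length(ks))
  ukey <- ks[uniq]
  ii <- as.integer((ukey - 1) %% nred) + 1L
  jj <- (ukey - 1) %/% nred
  p <- as.integer(c(0, cumsum(tabulate(jj + 1L, nbins = nred))))
  sel <- keep[o]
  function(x) {
    cs <- cumsum(x[sel])
    xa <- diff(c(0, cs[ends]))
    Matrix::sparseMatrix(i = ii, p = p, x = xa, dims = c(nred, nred),
                         symmetric = TRUE)
  }
}

# Consistent nodal forces of a uniform traction on quadratic triangle faces:
# corners receive zero, midside nodes area/3 each.
face_traction_forces <- function(mesh, faces, total_force, direction = c(0, 0, 1)) {
  N <- nrow(mesh$nodes)
  areas <- apply(faces, 1, function(f) {
    p <- mesh$nodes[f[1:3], , drop = FALSE]
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
    sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1])^2)) / 2
  })
  t_mag <- total_force / sum(areas)
  fvec <- numeric(3 * N)
  for (r in seq_len(nrow(faces))) {
    for (mnode in faces[r, 4:6]) {
      idx <- 3 * (mnode - 1) + 1:3
      fvec[idx] <- fvec[idx] + direction * t_mag * areas[r] / 3
    }
  }
  fvec
}

face_area <- function(mesh, faces) {
  sum(apply(faces, 1, function(f) {
    p <- mesh$nodes[f[1:3], , drop = FALSE]
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
    sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1])^2)) / 2
  }))
}

#' Solve the static finite-element problem
#'
#' Ramps the proximal tensile tractions linearly over `load$ramp_steps`
#' increments; each increment is equilibrated by Newton iteration on the
#' total-Lagrangian residual until the relative residual falls below `tol`
#' (or `max_iter` is hit, which is an error). Distal faces of all
#' sub-tendons are fully fixed; the load is applied as a uniform traction
#' over the proximal face of each loaded sub-tendon, pulling along +z.
#'
#' @param mesh a `tendon_mesh`.
#' @param materials a `material_map`.
#' @param load a `load_case`.
#' @param interface an `interface_model`.
#' @param tol relative residual tolerance.
#' @param max_iter Newton iteration cap per ramp step.
#' @return a `solution_field`: nodal displacements `u` (N x 3, mm), element
#'   centroid Cauchy stresses `stress` (E x 6: 11,22,33,12,23,13, MPa), von
#'   Mises scalar `vm`, `interface_state`, convergence `log`, and the
#'   problem definition.
#' @export
solve_static <- function(mesh, materials, load, interface,
                         tol = 1e-6, max_iter = 50L, U0 = NULL) {
  stopifnot(inherits(mesh, "tendon_mesh"), inherits(materials, "material_map"),
            inherits(load, "load_case"), inherits(interface, "interface_model"))
  N <- nrow(mesh$nodes); E <- nrow(mesh$elements)
  C10e <- vapply(mesh$label, function(l) materials[[l]]$C10, numeric(1))
  D1e <- vapply(mesh$label, function(l) materials[[l]]$D1, numeric(1))

  fixed_nodes <- unique(unlist(lapply(
    mesh$face_sets[grepl("^distal_", names(mesh$face_sets))],
    as.vector)))
  if (!length(fixed_nodes)) stop("no distal face set: insufficient constraints")
  fixed <- sort(unique(as.vector(outer(3 * (fixed_nodes - 1), 1:3, `+`))))
  free <- setdiff(seq_len(3 * N), fixed)

  fext <- numeric(3 * N)
  for (st in load$loaded) {
    nm <- paste0("proximal_", st)
    if (!nm %in% names(mesh$face_sets))
      stop("loaded sub-tendon has no proximal face set: ", st)
    fext <- fext + face_traction_forces(mesh, mesh$face_sets[[nm]], load$force)
  }
  fref <- max(sqrt(sum(fext^2)), 1e-8)

  P <- length(mesh$interface_pairs$a)
  slip <- numeric(P)
  U <- if (is.null(U0)) numeric(3 * N) else as.numeric(t(U0))
  stopifnot(length(U) == 3 * N)
  log_rows <- list()
  chol_cache <- NULL
  iface <- NULL
  assembler <- NULL

  frozen <- NULL
  frames <- NULL
  residual_norm <- function(U, fs) {
    asm <- fe_assemble(mesh$nodes, mesh$elements, C10e, D1e, U, FALSE, FALSE)
    if (asm$detFmin <= 0) return(Inf)   # inverted trial state
    ia <- interface_assemble(mesh, U, interface, slip, want_state = FALSE,
                             frozen = frozen, frames = frames)
    r <- fs - asm$fint - ia$f
    sqrt(sum(r[free]^2))
  }

  log_step <- integer(0); log_iter <- integer(0); log_res <- numeric(0)
  alpha_start <- 1
  # adaptive incremental loading: the ramp size is a hint; increments are
  # halved on Newton failure (the twisted stack can demand very small first
  # steps while the geometric rotation develops) and re-grown on success
  lambda <- 0
  dl <- 1 / load$ramp_steps
  # warm starts only make sense near full load: fail fast instead of
  # bisecting toward zero load with a full-load displacement state
  dl_min <- if (is.null(U0)) 1 / (1024 * load$ramp_steps) else 1 / (4 * load$ramp_steps)
  U_conv <- U; U_prev_conv <- NULL; dl_prev <- NA
  step <- 0L
  while (lambda < 1 - 1e-12) {
    step <- step + 1L
    target <- min(1, lambda + dl)
    fs <- fext * target
    fnorm <- max(fref * target, 1e-8)
    # secant predictor along the load path
    U <- U_conv
    frames <- interface_frames(mesh, matrix(U_conv, ncol = 3, byrow = TRUE))
    if (!is.null(U_prev_conv) && !is.na(dl_prev)) {
      U_pred <- U_conv + (U_conv - U_prev_conv) * ((target - lambda) / dl_prev)
      if (residual_norm(U_pred, fs) < residual_norm(U, fs)) U <- U_pred
    }
    # frames are frozen for the whole increment, evaluated at the predictor
    # (tracking them inside Newton moves the line-search objective and
    # destabilises the increment)
    frames <- interface_frames(mesh, matrix(U, ncol = 3, byrow = TRUE))
    converged <- FALSE
    frozen <- NULL
    for (it in 0:max_iter) {
      first <- is.null(assembler)
      asm <- fe_assemble(mesh$nodes, mesh$elements, C10e, D1e, U, TRUE, first)
      if (any(asm$detJmin <= 0))
        stop(sprintf("element inversion at ramp step %d", step))
      iface <- interface_assemble(mesh, U, interface, slip, want_state = FALSE,
                                  frozen = frozen, frames = frames)
      r <- fs - asm$fint - iface$f
      rn <- sqrt(sum(r[free]^2)) / fnorm
      log_step <- c(log_step, step); log_iter <- c(log_iter, it)
      log_res <- c(log_res, rn)
      if (rn <= tol) { converged <- TRUE; break }
      if (it == 0L) rn0 <- rn
      if (it >= 15L && rn > 0.7 * rn0) break   # stalling: shrink the increment
      if (is.null(frozen) && interface$mode == "frictional" && rn < 1e-3)
        frozen <- list(stick = iface$stick, sgn = iface$sgn, cap = iface$cap)
      if (first)
        assembler <- make_assembler(c(asm$Ki, iface$i), c(asm$Kj, iface$j), free)
      Kff <- assembler(c(asm$Kx, iface$x))
      du <- tryCatch({
        # LDL' so that transiently indefinite tangents (unstable transverse
        # bending configurations along the rotation path) still factor
        chol_cache <- if (is.null(chol_cache)) Matrix::Cholesky(Kff, LDL = TRUE)
                      else update(chol_cache, Kff)
        du_try <- as.numeric(Matrix::solve(chol_cache, r[free]))
        if (!all(is.finite(du_try))) stop("LDL breakdown")
        du_try
      }, error = function(e) {
        chol_cache <<- NULL
        as.numeric(Matrix::solve(Kff, r[free]))
      })
      # geometric backtracking line search with a persistent starting step:
      # finite-rotation increments make the full Newton step overshoot on
      # twisted geometries, typically for a sustained stretch of iterations
      try_state <- function(alpha) {
        Utry <- U
        Utry[free] <- U[free] + alpha * du
        list(U = Utry, rn = residual_norm(Utry, fs) / fnorm, alpha = alpha)
      }
      alpha <- alpha_start
      best <- NULL
      repeat {
        cand <- try_state(alpha)
        if (is.finite(cand$rn) && cand$rn < rn * (1 - 1e-4 * alpha)) break
        if (is.finite(cand$rn) && (is.null(best) || cand$rn < best$rn)) best <- cand
        alpha <- alpha / 2
        if (alpha < 1 / 64) {
          if (!is.null(best) && best$rn < rn) cand <- best
          break
        }
      }
      alpha_start <- min(1, 2 * cand$alpha)
      U <- cand$U
    }
    if (!converged) {
      dl <- dl / 2
      if (dl < dl_min)
        stop(sprintf("Newton divergence at load factor %.4g (residual %.3g after %d iterations, minimum increment reached)",
                     target, rn, max_iter))
      next
    }
    slip <- iface$slip_new
    U_prev_conv <- U_conv; dl_prev <- target - lambda
    U_conv <- U
    lambda <- target
    dl <- min(dl * 2, 1 / load$ramp_steps)
  }
  U <- U_conv
  log_rows <- list(tibble::tibble(step = log_step, iter = log_iter,
                                  residual = log_res))

  asm <- fe_assemble(mesh$nodes, mesh$elements, C10e, D1e, U, FALSE)
  iface <- interface_assemble(mesh, U, interface, slip)
  vm <- von_mises_from_components(asm$stress)
  reaction <- (asm$fint + iface$f - fext)
  structure(list(u = matrix(U, ncol = 3, byrow = TRUE),
                 stress = asm$stress, vm = vm,
                 interface_state = iface$state,
                 log = do.call(rbind, log_rows),
                 mesh = mesh, load = load, interface = interface,
                 materials = materials, fext = fext,
                 reaction = matrix(reaction, ncol = 3, byrow = TRUE),
                 fixed_nodes = fixed_nodes),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf("<solution_field> %s interface, loaded %s: max |u| = %.4g mm, peak vM = %.4g MPa\n",
              x$interface$mode, paste(x$load$loaded, collapse = "+"),
              max(sqrt(rowSums(x$u^2))), max(x$vm)))
  invisible(x)
}

#' Global equilibrium residual of a converged solution
#'
#' Ratio of the out-of-balance force (reactions at the fixed distal faces
#' plus applied loads) to the applied load magnitude, per axis.
#'
#' @param solution a `solution_field`.
#' @return numeric length-3 relative residual.
#' @export
equilibrium_residual <- function(solution) {
  fixed <- solution$fixed_nodes
  reac <- colSums(solution$reaction[fixed, , drop = FALSE])
  applied <- colSums(matrix(solution$fext, ncol = 3, byrow = TRUE))
  abs(reac + applied) / max(sqrt(sum(applied^2)), 1e-12)
}

#' Solve the full interface-by-load grid
#'
#' @param mesh a `tendon_mesh`.
#' @param materials a `material_map`.
#' @param interfaces list of `interface_model`s (default the full sweep:
#'   frictionless, mu in 0.2..1.0, bonded).
#' @param loads list of `load_case`s (default each sub-tendon loaded in
#'   isolation at 100 N).
#' @param warm_start reuse each interface's converged displacement as the
#'   initial guess for the next interface of the same load case (single
#'   load application, fresh friction state; substantially faster on the
#'   full sweep and equivalent for the monotone proportional loading used
#'   here). Solves run stiffest-first (bonded, then descending friction,
#'   then frictionless) so the ramped cold start happens on the
#'   best-conditioned interface; results are returned in the given order.
#' @param ... passed to [solve_static()].
#' @return list of `solution_field`s with a `grid` attribute (tibble of
#'   interface mode, mu and loaded sub-tendon per solution, in order:
#'   load-major, interfaces in the given order within each load).
#' @export
run_load_cases <- function(mesh, materials, interfaces = default_interface_grid(),
                           loads = default_load_grid(), warm_start = TRUE, ...) {
  stopifnot(length(interfaces) > 0, length(loads) > 0)
  stiffness_rank <- function(ifc)
    switch(ifc$mode, bonded = 2, frictional = 1 + ifc$mu / 1e3, frictionless = 0)
  ord <- if (warm_start)
    order(-vapply(interfaces, stiffness_rank, numeric(1))) else seq_along(interfaces)
  sols <- list(); rows <- list()
  for (li in seq_along(loads)) {
    ld <- loads[[li]]
    U_prev <- NULL
    for (oi in ord) {
      ifc <- interfaces[[oi]]
      k <- (li - 1L) * length(interfaces) + oi
      ld_k <- if (!is.null(U_prev)) load_case(ld$loaded, ld$force, 1L) else ld
      sols[[k]] <- tryCatch({
        tryCatch(solve_static(mesh, materials, ld_k, ifc, U0 = U_prev, ...),
                 error = function(e) {
                   # a warm start that fails is retried cold with the full ramp
                   if (is.null(U_prev)) stop(e)
                   solve_static(mesh, materials, ld, ifc, ...)
                 })
      }, error = function(e)
        stop(sprintf("solver failed at interface=%s mu=%s loaded=%s: %s",
                     ifc$mode, format(ifc$mu), paste(ld$loaded, collapse = "+"),
                     conditionMessage(e))))
      if (warm_start) U_prev <- sols[[k]]$u
      rows[[k]] <- tibble::tibble(idx = k, interface = ifc$mode, mu = ifc$mu,
                                  loaded = paste(ld$loaded, collapse = "+"))
    }
  }
  attr(sols, "grid") <- do.call(rbind, rows[order(vapply(rows, `[[`, numeric(1), "idx"))])
  sols
}

#' Default interface sweep: frictionless, frictional mu 0.2-1.0, bonded
#' @param mu_values friction coefficients for the frictional rows.
#' @param k_n,k_t penalty stiffnesses passed to every model.
#' @export
default_interface_grid <- function(mu_values = c(0.2, 0.4, 0.6, 0.8, 1.0),
                                   k_n = 1000, k_t = 1000) {
  c(list(interface_model("frictionless", k_n = k_n, k_t = k_t)),
    lapply(mu_values, function(m) interface_model("frictional", mu = m, k_n = k_n, k_t = k_t)),
    list(interface_model("bonded", k_n = k_n, k_t = k_t)))
}

#' Default load grid: each sub-tendon loaded in isolation
#' @param force force per sub-tendon, N.
#' @param ramp_steps ramp increments per solve.
#' @export
default_load_grid <- function(force = 100, ramp_steps = 10L) {
  lapply(SUB_TENDONS, function(st) load_case(st, force, ramp_steps))
}
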