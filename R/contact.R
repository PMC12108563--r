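# penalty stiffness triplets for a set of node pairs: for each pair k,
# couple (u_slave - u_master) through the 3x3 block M_k (kn * n n^T for
# normal springs, kt * (I - n n^T) for tangential stick springs)
pair_penalty_matrix <- function(n_nodes, slave, master, blocks) {
  n3 <- 3L * n_nodes
  if (!length(slave))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n3, n3)))
  ti <- list(); tj <- list(); tx <- list()
  ds <- function(i) 3L * (slave - 1L) + i
  dm <- function(i) 3L * (master - 1L) + i
  for (i in 1:3) for (j in 1:3) {
    v <- blocks[, (i - 1L) * 3L + j]
    ti[[length(ti) + 1L]] <- c(ds(i), dm(i), ds(i), dm(i))
    tj[[length(tj) + 1L]] <- c(ds(j), dm(j), dm(j), ds(j))
    tx[[length(tx) + 1L]] <- c(v, v, -v, -v)
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(n3, n3))
}

#' Linear-elastic solve with a frictional (or bonded/ignored) contact pair
#'
#' Operates on a mesh whose contact interface was detached with
#' [split_interface()]. Normal behaviour is penalty-regularized
#' non-penetration ("hard contact" surrogate); tangential behaviour is
#' Coulomb friction with an iterative stick/slip active-set update. Mode
#' `"bonded"` ties the coincident pairs rigidly (multi-point constraints)
#' and mode `"ignored"` leaves the interface free.
#'
#' The penalty stiffness defaults to
#' `penalty_scale * max(E) / mean element edge` and is escalated tenfold
#' (up to 3 times) if the penetration tolerance of `1e-3 * mean edge` is
#' exceeded.
#'
#' @param mesh a [tet_mesh()] with `contact_pairs` (from
#'   [split_interface()]).
#' @param materials per-element material field.
#' @param lc a [load_case()]; `lc$contact$mode` selects the behaviour,
#'   `lc$contact$mu` the friction coefficient (default 0.3),
#'   `lc$contact$penalty_scale` the penalty factor (default 50).
#' @param max_iter active-set iteration cap.
#' @param tol relative contact-force convergence tolerance.
#' @return A `solution` as in [solve_linear()], with contact diagnostics
#'   (`contact_iterations`, `active_pairs`, `converged`, `penetration`).
#'   Non-convergence produces a warning and `converged = FALSE`, never a
#'   silent result.
#' @export
solve_contact <- function(mesh, materials, lc, max_iter = 100L, tol = 1e-6,
                          verbose = FALSE) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(lc, "load_case"))
  mode <- lc$contact$mode %||% "frictional"
  if (mode == "ignored") return(solve_linear(mesh, materials, lc))
  cp <- mesh$contact_pairs
  if (is.null(cp) || !length(cp$slave))
    stop("mesh has no contact pairs; run split_interface() first")
  if (mode == "bonded") {
    ties <- lc$ties
    for (k in seq_along(cp$slave))
      ties[[length(ties) + 1L]] <- list(slave = cp$slave[k],
                                        masters = cp$master[k], weights = 1)
    lc$ties <- ties
    return(solve_linear(mesh, materials, lc))
  }
  mu_f <- lc$contact$mu %||% 0.3
  scale <- lc$contact$penalty_scale %||% 50
  # mean corner edge length
  X <- mesh$nodes; el <- mesh$elements
  h <- mean(sqrt(rowSums((X[el[, 2], , drop = FALSE] -
                            X[el[, 1], , drop = FALSE])^2)))
  gap_tol <- 1e-3 * h
  # carry only pairs with a consistent tributary area (facet mid nodes);
  # corner pairs have zero consistent weight under uniform pressure
  wts <- cp$weight %||% rep(1, length(cp$slave))
  sel_w <- wts > 0
  cp <- list(slave = cp$slave[sel_w], master = cp$master[sel_w],
             normal = cp$normal[sel_w, , drop = FALSE],
             weight = wts[sel_w])
  # penalty stiffness per pair: (scale * E / h) per unit area, times the
  # pair's tributary area
  kn <- scale * max(materials$E) / h * cp$weight
  kt <- kn
  np <- length(cp$slave)
  nrm <- cp$normal
  # initial geometric gap along the normal (0 for coincident pairs);
  # normals point from master into slave, so gap grows when the slave
  # moves along +n
  g0 <- rowSums((X[cp$slave, , drop = FALSE] -
                   X[cp$master, , drop = FALSE]) * nrm)
  K0 <- assemble_stiffness(mesh, materials)
  f0 <- applied_loads(mesh, lc)
  n_nodes <- nrow(X)

  # Active-set iteration with radial-return friction. Initially-closed
  # pairs start active and sticking. Every active pair carries normal +
  # tangential penalty springs; the tangential spring is anchored at the
  # accumulated slip offset dtp. Pairs whose trial traction exceeds the
  # Coulomb limit mu * p_n have dtp moved so the spring carries exactly
  # the limit traction (radial return). Convergence requires a stable
  # open/stick/slip partition plus either stagnant contact forces or a
  # small Coulomb violation together with a stagnant displacement field.
  active <- g0 <= 1e-12
  stick <- rep(TRUE, np)
  that <- matrix(0, np, 3L)                # slip directions
  dtp <- matrix(0, np, 3L)                 # accumulated slip per pair
  prev_force <- matrix(0, np, 3L)
  prev_u <- NULL
  hist_x <- list(); hist_r <- list()       # Anderson mixing history
  converged <- FALSE
  escalations <- 0L
  it <- 0L
  sol <- NULL
  while (it < max_iter) {
    it <- it + 1L
    slip_a <- active & !stick
    blocks <- matrix(0, sum(active), 9L)
    if (any(active)) {
      na <- nrm[active, , drop = FALSE]
      for (i in 1:3) for (j in 1:3)
        blocks[, (i - 1L) * 3L + j] <-
          kn[active] * na[, i] * na[, j] +               # normal penalty
          kt[active] * ((i == j) - na[, i] * na[, j])    # tangential spring
    }
    Kc <- pair_penalty_matrix(n_nodes, cp$slave[active], cp$master[active],
                              blocks)
    f <- f0
    if (any(active)) {
      # tangential spring anchors: force on slave is -kt (dt - dtp)
      fa <- kt[active] * dtp[active, , drop = FALSE]
      for (i in 1:3) {
        f[3L * (cp$slave[active] - 1L) + i] <-
          f[3L * (cp$slave[active] - 1L) + i] + fa[, i]
        f[3L * (cp$master[active] - 1L) + i] <-
          f[3L * (cp$master[active] - 1L) + i] - fa[, i]
      }
    }
    sol <- solve_system(mesh, Matrix::forceSymmetric(K0 + Kc), f, lc)
    du <- sol$u[cp$slave, , drop = FALSE] - sol$u[cp$master, , drop = FALSE]
    gap <- g0 + rowSums(du * nrm)
    new_active <- gap < 0
    pn <- ifelse(new_active, kn * pmax(-gap, 0), 0)
    dt <- du - rowSums(du * nrm) * nrm
    # stick/slip partition from the trial traction of the stick spring
    trial <- dt - dtp
    trial <- trial - rowSums(trial * nrm) * nrm
    trial_n <- sqrt(rowSums(trial^2))
    tn <- kt * trial_n
    new_stick <- tn <= mu_f * pn | trial_n < 1e-14
    sl2 <- new_active & !new_stick
    new_that <- that
    if (any(sl2))
      new_that[sl2, ] <- trial[sl2, , drop = FALSE] / trial_n[sl2]
    # slip pairs store their total slip (no elastic tangential stretch
    # beyond the Coulomb limit), enabling a later return to stick
    new_dtp <- dtp
    if (any(sl2))
      new_dtp[sl2, ] <- dt[sl2, , drop = FALSE] -
        (mu_f * pn[sl2] / kt[sl2]) * new_that[sl2, , drop = FALSE]
    new_dtp[!new_active, ] <- 0
    # net contact force per pair for the convergence check
    force <- -pn * nrm
    force[sl2, ] <- force[sl2, , drop = FALSE] -
      mu_f * pn[sl2] * new_that[sl2, , drop = FALSE]
    stck2 <- new_active & new_stick
    force[stck2, ] <- force[stck2, , drop = FALSE] -
      kt[stck2] * trial[stck2, , drop = FALSE]
    dF <- max(abs(force - prev_force))
    ref <- max(1, max(abs(f0)))
    # typical contact force scale; pairs far below it are "marginal" and
    # may chatter between states without blocking convergence. A pair that
    # carried force in either the previous or the new state counts as a
    # real change.
    # the springs present in the solve may carry force (including tension
    # about to be released) that the net-force bookkeeping above does not
    # see; count it when judging whether a state flip matters
    spring_used <- ifelse(active, sqrt((kn * gap)^2 + (kt * trial_n)^2), 0)
    fscale <- max(abs(force), abs(prev_force), spring_used, 0)
    fpair <- pmax(abs(force[, 1]), abs(force[, 2]), abs(force[, 3]),
                  abs(prev_force[, 1]), abs(prev_force[, 2]),
                  abs(prev_force[, 3]), spring_used)
    changed <- (new_active != active) | (sl2 != slip_a)
    sets_stable <- !any(changed & fpair > 1e-3 * fscale)
    # Coulomb violation on slip pairs with non-negligible pressure
    viol <- if (any(sl2))
      max((tn[sl2] - mu_f * pn[sl2]) /
            pmax(mu_f * pn[sl2], 1e-3 * max(fscale, tol))) else 0
    du_stag <- if (is.null(prev_u)) Inf else
      max(abs(sol$u - prev_u)) / max(max(abs(sol$u)), 1e-30)
    prev_u <- sol$u
    if (verbose)
      message(sprintf(
        "it %2d: active %d stick %d slip %d dF %.3e viol %.2e stag %.2e %s",
        it, sum(new_active), sum(stck2), sum(sl2), dF, viol, du_stag,
        sets_stable))
    ok_forces <- dF <= tol * ref ||
      (viol <= 1e-3 && du_stag <= 1e-6) ||
      (dF <= 1e-4 * max(fscale, ref) && du_stag <= 1e-6)
    if (sets_stable && ok_forces) {
      pen <- max(c(0, -gap[new_active]))
      if (pen > gap_tol && escalations < 3L) {
        kn <- kn * 10; kt <- kn
        escalations <- escalations + 1L
      } else {
        converged <- TRUE
        break
      }
    }
    active <- new_active
    stick <- new_stick
    that <- new_that
    # Anderson-accelerated slip update: for a fixed partition the map
    # dtp -> new_dtp is affine, so mixing the recent residual history
    # converges far faster than plain (Picard) substitution
    r_flat <- as.vector(new_dtp - dtp)
    if (!sets_stable) { hist_x <- list(); hist_r <- list() }
    hist_x[[length(hist_x) + 1L]] <- as.vector(dtp)
    hist_r[[length(hist_r) + 1L]] <- r_flat
    if (length(hist_r) > 5L) { hist_x <- hist_x[-1]; hist_r <- hist_r[-1] }
    mdep <- length(hist_r) - 1L
    if (mdep >= 1L) {
      dR <- vapply(seq_len(mdep), function(j)
        hist_r[[j + 1L]] - hist_r[[j]], numeric(length(r_flat)))
      dX <- vapply(seq_len(mdep), function(j)
        hist_x[[j + 1L]] - hist_x[[j]], numeric(length(r_flat)))
      gam <- tryCatch(qr.solve(dR, r_flat), error = function(e) NULL)
      if (!is.null(gam) && all(is.finite(gam))) {
        dtp <- matrix(as.vector(dtp) + r_flat -
                        as.vector((dX + dR) %*% gam), np, 3L)
      } else dtp <- new_dtp
    } else dtp <- new_dtp
    prev_force <- force
  }
  if (!converged)
    warning(sprintf(
      "contact iteration did not converge in %d iterations (residual %.3e)",
      max_iter, if (is.null(sol)) NA_real_ else sol$residual))
  stress <- compute_stresses(mesh, materials, sol$u)
  du <- sol$u[cp$slave, , drop = FALSE] - sol$u[cp$master, , drop = FALSE]
  gap <- g0 + rowSums(du * nrm)
  structure(list(u = sol$u, stress = stress, reactions = sol$reactions,
                 applied = colSums(matrix(f0, ncol = 3L, byrow = TRUE)),
                 residual = sol$residual,
                 diagnostics = list(contact_iterations = it,
                                    active_pairs = sum(gap < 0),
                                    slip_pairs = sum(active & !stick),
                                    penetration = max(c(0, -gap)),
                                    converged = converged)),
            class = "solution")
}
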