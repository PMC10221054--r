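#' Finite-difference reference solution of the four-stream system
#'
#' Independent verification solver: discretises the same two-point boundary
#' value problem on a fine depth grid with an implicit midpoint scheme
#' (second-order accurate) and solves the resulting sparse banded linear
#' system.  The direct beam is propagated by the same discrete scheme
#' rather than its closed form, so every ingredient of the solution is
#' independent of [solve_stack()].
#'
#' @param stack A [canopy_stack()] with at least one layer.
#' @param geom A [geometry()].
#' @param incident Per-wavelength incident irradiance; defaults to 1.
#' @param n_steps Total number of depth steps across the stack (>= 1000).
#' @return A `"flux_profile"` restricted to the layer boundaries, same
#'   contract as [solve_stack()].
#' @export
fd_oracle_solve <- function(stack, geom, incident = NULL, n_steps = 10000L) {
  stopifnot(inherits(stack, "canopy_stack"), inherits(geom, "geometry"))
  if (n_steps < 1000L) stop("n_steps must be at least 1000")
  wl <- stack$soil$wavelength
  nw <- length(wl)
  if (is.null(incident)) incident <- rep(1, nw)
  if (length(incident) != nw) stop("incident must match the wavelength grid")

  layers <- stack$layers
  N <- length(layers)
  L <- vapply(layers, `[[`, numeric(1), "area_index")
  if (N == 0L) return(solve_stack(stack, geom, incident))
  pos <- L > 0
  total <- sum(L)
  if (total <= 0) return(solve_stack(stack, geom, incident))

  # distribute steps over layers proportionally (at least 2 per layer)
  steps <- pmax(2L, round(n_steps * L / total))
  steps[!pos] <- 0L
  cf <- stack_coefficients(stack, geom)
  r_s <- stack$soil$reflectance
  Es_top <- geom$direct_fraction * incident
  Ed_top <- (1 - geom$direct_fraction) * incident

  # cell-wise layer membership and step widths
  cell_layer <- rep(seq_len(N), steps)
  h <- rep(L[pos] / steps[pos], steps[pos])
  ncell <- length(h)
  nn <- ncell + 1L                    # nodes
  node_depth <- c(0, cumsum(h))
  boundary_nodes <- c(1L, cumsum(steps) + 1L)

  Es_mat <- matrix(0, nw, N + 1)
  Em_mat <- matrix(0, nw, N + 1)
  Ep_mat <- matrix(0, nw, N + 1)
  E0_top <- numeric(nw)

  for (j in seq_len(nw)) {
    a <- vapply(cf, function(x) x$a[j], numeric(1))
    sg <- vapply(cf, function(x) x$sigma[j], numeric(1))
    sfw <- vapply(cf, function(x) x$s[j], numeric(1))
    sbk <- vapply(cf, function(x) x$s_prime[j], numeric(1))
    kk <- vapply(cf, function(x) x$k[j], numeric(1))
    Kv <- vapply(cf, function(x) x$K[j], numeric(1))
    uu <- vapply(cf, function(x) x$u[j], numeric(1))
    vv <- vapply(cf, function(x) x$v[j], numeric(1))
    ww <- vapply(cf, function(x) x$w[j], numeric(1))

    # discrete direct beam: implicit midpoint per cell
    Es <- numeric(nn)
    Es[1] <- Es_top[j]
    fac <- (1 - kk[cell_layer] * h / 2) / (1 + kk[cell_layer] * h / 2)
    for (c in seq_len(ncell)) Es[c + 1] <- Es[c] * fac[c]
    Es_mid <- (Es[-1] + Es[-nn]) / 2

    # assemble sparse system in unknowns (E-_1, E+_1, ..., E-_nn, E+_nn)
    # node indices: E-_n at column 2n-1, E+_n at column 2n
    cc <- seq_len(ncell)
    al <- a[cell_layer]; sl <- sg[cell_layer]
    r_minus <- 2L * cc          # rows of the E- cell equations
    r_plus <- 2L * cc + 1L      # rows of the E+ cell equations
    trip_i <- c(1L,
                r_minus, r_minus, r_minus, r_minus,
                r_plus, r_plus, r_plus, r_plus,
                2L * nn, 2L * nn)
    trip_j <- c(1L,
                2L * cc - 1L, 2L * cc + 1L, 2L * cc, 2L * cc + 2L,
                2L * cc, 2L * cc + 2L, 2L * cc - 1L, 2L * cc + 1L,
                2L * nn, 2L * nn - 1L)
    trip_x <- c(1,
                -1 / h + al / 2, 1 / h + al / 2, -sl / 2, -sl / 2,
                -1 / h - al / 2, 1 / h - al / 2, sl / 2, sl / 2,
                1, -r_s[j])
    rhs <- numeric(2L * nn)
    rhs[1L] <- Ed_top[j]
    rhs[r_minus] <- sfw[cell_layer] * Es_mid
    rhs[r_plus] <- -sbk[cell_layer] * Es_mid
    rhs[2L * nn] <- r_s[j] * Es[nn]

    Msp <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                dims = c(2L * nn, 2L * nn))
    sol <- tryCatch(as.numeric(Matrix::solve(Msp, rhs)),
                    error = function(e) {
                      stop(sprintf("finite-difference system failed at wavelength %g nm: %s",
                                   wl[j], conditionMessage(e)))
                    })
    Emi <- sol[seq(1L, 2L * nn, by = 2L)]
    Epl <- sol[seq(2L, 2L * nn, by = 2L)]

    # viewer-direction flux, implicit midpoint upward sweep
    E0 <- numeric(nn)
    E0[nn] <- r_s[j] * (Es[nn] + Emi[nn])
    for (c in rev(seq_len(ncell))) {
      ly <- cell_layer[c]; hc <- h[c]
      S_mid <- ww[ly] * Es_mid[c] +
        vv[ly] * (Emi[c] + Emi[c + 1L]) / 2 +
        uu[ly] * (Epl[c] + Epl[c + 1L]) / 2
      E0[c] <- (E0[c + 1L] * (1 - hc * Kv[ly] / 2) + hc * S_mid) /
        (1 + hc * Kv[ly] / 2)
    }
    E0_top[j] <- E0[1L]

    Es_mat[j, ] <- Es[boundary_nodes]
    Em_mat[j, ] <- Emi[boundary_nodes]
    Ep_mat[j, ] <- Epl[boundary_nodes]
  }

  refl <- ifelse(incident > 0, E0_top / incident, NA_real_)
  structure(list(wavelength = wl, x = c(0, cumsum(L)), Es = Es_mat,
                 E_minus = Em_mat, E_plus = Ep_mat, reflectance = refl,
                 incident = incident, layer_area = L,
                 layer_kind = vapply(layers, function(l) l$component$kind,
                                     character(1)),
                 geom = geom),
            class = "flux_profile")
}
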