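#' Canopy layer
#'
#' One homogeneous horizontal layer containing a single component (leaf or
#' branch) with a given one-sided area index and inclination distribution.
#' By convention leaves are spherical and branches planophile unless stated
#' otherwise.
#'
#' @param component A [component_optics()] object (kind leaf or branch).
#' @param area_index One-sided component area per unit ground area (>= 0).
#' @param lidf Inclination distribution; defaults to `"spherical"` for
#'   leaves and `"planophile"` for branches.
#' @return An object of class `"canopy_layer"`.
#' @export
canopy_layer <- function(component, area_index, lidf = NULL) {
  stopifnot(inherits(component, "component_optics"))
  if (component$kind == "soil") stop("soil cannot form a canopy layer")
  if (!is.numeric(area_index) || area_index < 0) {
    stop("area_index must be a non-negative number")
  }
  if (is.null(lidf)) {
    lidf <- if (component$kind == "leaf") "spherical" else "planophile"
  }
  lidf <- match.arg(lidf, .lidf_names)
  structure(list(component = component, area_index = area_index,
                 lidf = lidf), class = "canopy_layer")
}

#' Canopy stack
#'
#' An ordered top-to-bottom sequence of single-component layers over a
#' Lambertian soil background.  All component and soil optics must share
#' one wavelength grid.
#'
#' @param layers List of [canopy_layer()] objects, top first; may be empty.
#' @param soil A [component_optics()] object of kind `"soil"`.
#' @return An object of class `"canopy_stack"` with accessors for total
#'   plant area index (`$pai`) and green proportion (`$green_proportion`).
#' @export
canopy_stack <- function(layers, soil) {
  stopifnot(inherits(soil, "component_optics"))
  if (soil$kind != "soil") stop("background optics must have kind 'soil'")
  if (inherits(layers, "canopy_layer")) layers <- list(layers)
  for (ly in layers) {
    if (!inherits(ly, "canopy_layer")) stop("layers must be canopy_layer objects")
    if (!isTRUE(all.equal(ly$component$wavelength, soil$wavelength))) {
      stop("all layers and the soil must share one wavelength grid")
    }
  }
  pai <- sum(vapply(layers, `[[`, numeric(1), "area_index"))
  leaf_area <- sum(vapply(layers, function(l) {
    if (l$component$kind == "leaf") l$area_index else 0
  }, numeric(1)))
  structure(list(layers = layers, soil = soil, pai = pai,
                 green_proportion = if (pai > 0) leaf_area / pai else NA_real_),
            class = "canopy_stack")
}

#' @export
print.canopy_stack <- function(x, ...) {
  cat(sprintf("Canopy stack: %d layer(s), PAI %.3f, green proportion %s\n",
              length(x$layers), x$pai,
              if (is.na(x$green_proportion)) "NA"
              else sprintf("%.3f", x$green_proportion)))
  invisible(x)
}

# Coefficients for every layer of a stack (shared by the analytic solver
# and the finite-difference oracle).
stack_coefficients <- function(stack, geom) {
  lapply(stack$layers, function(ly) {
    sail_coefficients(ly$component, ly$lidf, geom)
  })
}

# phi(z) = (exp(z) - 1)/z, stable near zero.
.phi <- function(z) ifelse(abs(z) < 1e-9, 1 + z / 2, expm1(z) / z)

#' Solve the four-stream fluxes of a layered canopy
#'
#' Analytic per-layer solution of the four-stream equations: the direct
#' beam decays exponentially within each layer, the coupled diffuse
#' up/down system is solved through its eigenmodes (eigenvalue
#' `m = sqrt(a^2 - sigma^2)`) plus a particular solution driven by the
#' beam, and the per-layer constants are fixed by continuity of both
#' diffuse fluxes at every interior boundary, the incident fluxes at the
#' top, and the Lambertian soil condition at the bottom.  The
#' viewer-direction radiance is accumulated bottom-up from its source
#' integral, giving the directional reflectance factor at the top.
#'
#' @param stack A [canopy_stack()].
#' @param geom A [geometry()].
#' @param incident Per-wavelength incident irradiance at the top of the
#'   canopy (non-negative); defaults to 1 at every wavelength.
#' @return An object of class `"flux_profile"`: boundary depths `x`
#'   (cumulative downward area index, 0 at the top), matrices `Es`,
#'   `E_minus`, `E_plus` (wavelength x boundary), per-wavelength
#'   `reflectance` factor, the `incident` spectrum and bookkeeping fields.
#' @export
#' @examples
#' opt <- synthetic_forest_optics("DBF", seed = 1)
#' st <- build_stack(3, 0.9, opt$leaf, opt$branch, opt$soil)
#' fp <- solve_stack(st, geometry())
#' partition_canopy_fpar(fp, st)
solve_stack <- function(stack, geom, incident = NULL) {
  stopifnot(inherits(stack, "canopy_stack"), inherits(geom, "geometry"))
  wl <- stack$soil$wavelength
  nw <- length(wl)
  if (is.null(incident)) incident <- rep(1, nw)
  if (length(incident) != nw) stop("incident must match the wavelength grid")
  if (any(incident < 0)) stop("incident irradiance must be non-negative")

  layers <- stack$layers
  N <- length(layers)
  L <- vapply(layers, `[[`, numeric(1), "area_index")
  r_s <- stack$soil$reflectance
  Es_top <- geom$direct_fraction * incident
  Ed_top <- (1 - geom$direct_fraction) * incident

  if (N == 0L) {
    Es <- matrix(Es_top, nw, 1)
    Em <- matrix(Ed_top, nw, 1)
    Ep <- matrix(r_s * (Es_top + Ed_top), nw, 1)
    refl <- ifelse(incident > 0, Ep[, 1] / incident, NA_real_)
    return(structure(list(wavelength = wl, x = 0, Es = Es, E_minus = Em,
                          E_plus = Ep, reflectance = refl,
                          incident = incident, layer_area = numeric(0),
                          layer_kind = character(0), geom = geom),
                     class = "flux_profile"))
  }

  cf <- stack_coefficients(stack, geom)
  # per-layer, per-wavelength derived quantities
  mm <- hh <- PP <- QQ <- kk <- matrix(0, nw, N)
  for (i in seq_len(N)) {
    a <- cf[[i]]$a; sg <- cf[[i]]$sigma
    m2 <- a^2 - sg^2
    if (any(m2 < -1e-12)) {
      bad <- wl[which(m2 < -1e-12)[1L]]
      stop(sprintf("non-physical optics (a^2 < sigma^2) at wavelength %g nm", bad))
    }
    m <- sqrt(pmax(m2, 0))
    m <- pmax(m, 1e-6)              # floor: conditions the conservative limit
    k <- cf[[i]]$k
    res <- abs(m - k) < 1e-6        # beam/eigenvalue resonance
    m[res] <- k[res] + 1e-6
    h <- sg / (a + m)
    den <- m^2 - k^2
    PP[, i] <- (((a + k) * cf[[i]]$s + sg * cf[[i]]$s_prime) / den)
    QQ[, i] <- (((a - k) * cf[[i]]$s_prime + sg * cf[[i]]$s) / den)
    mm[, i] <- m; hh[, i] <- h; kk[, i] <- k
  }

  # direct beam at each boundary (exact exponential decay)
  Es_b <- matrix(0, nw, N + 1)
  Es_b[, 1] <- Es_top
  for (i in seq_len(N)) Es_b[, i + 1] <- Es_b[, i] * exp(-kk[, i] * L[i])

  # solve the 2N interface system per wavelength for the mode amplitudes
  A <- matrix(0, nw, N); B <- matrix(0, nw, N)
  for (j in seq_len(nw)) {
    M <- matrix(0, 2 * N, 2 * N)
    rhs <- numeric(2 * N)
    em <- exp(-mm[j, ] * L); ep <- exp(mm[j, ] * L)
    # top: E-(layer1, x=0) = Ed_top
    M[1, 1] <- 1; M[1, 2] <- hh[j, 1]
    rhs[1] <- Ed_top[j] - PP[j, 1] * Es_b[j, 1]
    row <- 2
    if (N > 1) {
      for (i in seq_len(N - 1)) {
        ia <- 2 * i - 1; ib <- 2 * i; ja <- 2 * i + 1; jb <- 2 * i + 2
        botP <- PP[j, i] * Es_b[j, i] * exp(-kk[j, i] * L[i])
        botQ <- QQ[j, i] * Es_b[j, i] * exp(-kk[j, i] * L[i])
        # E- continuity
        M[row, ia] <- em[i]; M[row, ib] <- hh[j, i] * ep[i]
        M[row, ja] <- -1;    M[row, jb] <- -hh[j, i + 1]
        rhs[row] <- PP[j, i + 1] * Es_b[j, i + 1] - botP
        row <- row + 1
        # E+ continuity
        M[row, ia] <- hh[j, i] * em[i]; M[row, ib] <- ep[i]
        M[row, ja] <- -hh[j, i + 1];    M[row, jb] <- -1
        rhs[row] <- QQ[j, i + 1] * Es_b[j, i + 1] - botQ
        row <- row + 1
      }
    }
    # soil: E+(N, L) = r_s (Es(bottom) + E-(N, L))
    i <- N
    botP <- PP[j, i] * Es_b[j, i] * exp(-kk[j, i] * L[i])
    botQ <- QQ[j, i] * Es_b[j, i] * exp(-kk[j, i] * L[i])
    ia <- 2 * N - 1; ib <- 2 * N
    M[row, ia] <- hh[j, i] * em[i] - r_s[j] * em[i]
    M[row, ib] <- ep[i] - r_s[j] * hh[j, i] * ep[i]
    rhs[row] <- r_s[j] * (Es_b[j, N + 1] + botP) - botQ
    sol <- tryCatch(solve(M, rhs), error = function(e) {
      stop(sprintf("singular interface system at wavelength %g nm", wl[j]))
    })
    A[j, ] <- sol[seq(1, 2 * N, by = 2)]
    B[j, ] <- sol[seq(2, 2 * N, by = 2)]
  }

  # boundary diffuse fluxes
  Em <- Ep <- matrix(0, nw, N + 1)
  for (i in seq_len(N)) {   # value at the top of layer i
    Em[, i] <- A[, i] + B[, i] * hh[, i] + PP[, i] * Es_b[, i]
    Ep[, i] <- A[, i] * hh[, i] + B[, i] + QQ[, i] * Es_b[, i]
  }
  em_bot <- exp(-mm[, N] * L[N]); ep_bot <- exp(mm[, N] * L[N])
  dec <- exp(-kk[, N] * L[N])
  Em[, N + 1] <- A[, N] * em_bot + B[, N] * hh[, N] * ep_bot +
    PP[, N] * Es_b[, N] * dec
  Ep[, N + 1] <- A[, N] * hh[, N] * em_bot + B[, N] * ep_bot +
    QQ[, N] * Es_b[, N] * dec

  # viewer-direction radiance accumulated bottom-up
  E0 <- r_s * (Es_b[, N + 1] + Em[, N + 1])
  for (i in rev(seq_len(N))) {
    Kv <- cf[[i]]$K
    C1 <- A[, i] * (cf[[i]]$v + cf[[i]]$u * hh[, i])
    C2 <- B[, i] * (cf[[i]]$v * hh[, i] + cf[[i]]$u)
    C3 <- Es_b[, i] *
      (cf[[i]]$w + cf[[i]]$v * PP[, i] + cf[[i]]$u * QQ[, i])
    E0 <- E0 * exp(-Kv * L[i]) +
      C1 * L[i] * .phi((-mm[, i] - Kv) * L[i]) +
      C2 * L[i] * .phi((mm[, i] - Kv) * L[i]) +
      C3 * L[i] * .phi((-kk[, i] - Kv) * L[i])
  }
  refl <- ifelse(incident > 0, E0 / incident, NA_real_)

  structure(list(wavelength = wl, x = c(0, cumsum(L)), Es = Es_b,
                 E_minus = Em, E_plus = Ep, reflectance = refl,
                 incident = incident, layer_area = L,
                 layer_kind = vapply(layers, function(l) l$component$kind,
                                     character(1)),
                 geom = geom),
            class = "flux_profile")
}

#' @export
print.flux_profile <- function(x, ...) {
  cat(sprintf(
    "Flux profile: %d wavelengths, %d layer(s), total area index %.3f\n",
    length(x$wavelength), length(x$layer_area), sum(x$layer_area)))
  cat(sprintf("  nadir-view reflectance factor: %.4f-%.4f\n",
              min(x$reflectance, na.rm = TRUE),
              max(x$reflectance, na.rm = TRUE)))
  invisible(x)
}
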