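# Steady-state tissue oxygen transport over a counting frame. Governing
# equation (free + myoglobin-facilitated diffusion, Michaelis-Menten
# consumption):
#
#   div[ (D*alpha + D_Mb*C_Mb*S'(P)) grad P ] = M0 * P / (P + P_crit),
#   S(P) = P / (P + P50_Mb)
#
# Perfused capillaries are internal fixed-value discs at P_cap; the outer
# frame boundary is no-flux. Discretised by finite volumes on a uniform grid
# and solved by Picard iteration (successive linearisation of the sink and
# freezing of the P-dependent diffusivity) with under-relaxation.

#' Oxygen transport parameters
#'
#' Defaults are literature-typical values for rat fast hindlimb muscle:
#' capillary radius 2.0e-4 cm, maximal demand 15.7e-5 ml O2 ml^-1 s^-1 (rest
#' = 0.1 x maximal), myoglobin O2 capacity 10.2e-3 ml O2 ml^-1, solubility
#' 3.89e-5 ml O2 ml^-1 mmHg^-1, O2 diffusivity 1.73e-7 cm^2 s^-1.
#'
#' @param r_c Capillary radius, cm.
#' @param M0 Maximal oxygen demand, ml O2 ml^-1 s^-1.
#' @param rest_fraction Rest demand as a fraction of maximal (default 0.1).
#' @param C_Mb Myoglobin O2 capacity, ml O2 ml^-1.
#' @param alpha O2 solubility, ml O2 ml^-1 mmHg^-1.
#' @param D O2 diffusivity, cm^2 s^-1.
#' @param D_Mb Myoglobin diffusivity, cm^2 s^-1 (0 disables facilitation).
#' @param P50_Mb Myoglobin half-saturation PO2, mmHg.
#' @param P_crit Consumption half-saturation PO2, mmHg.
#' @param P_cap Capillary boundary PO2, mmHg.
#' @param P_hypoxia Hypoxia threshold, mmHg (default 0.5).
#' @return Object of class `transport_params`.
#' @export
transport_params <- function(r_c = 2.0e-4, M0 = 15.7e-5, rest_fraction = 0.1,
                             C_Mb = 10.2e-3, alpha = 3.89e-5, D = 1.73e-7,
                             D_Mb = 1.0e-7, P50_Mb = 5.3, P_crit = 0.5,
                             P_cap = 40, P_hypoxia = 0.5) {
  p <- list(r_c = r_c, M0 = M0, rest_fraction = rest_fraction, C_Mb = C_Mb,
            alpha = alpha, D = D, D_Mb = D_Mb, P50_Mb = P50_Mb,
            P_crit = P_crit, P_cap = P_cap, P_hypoxia = P_hypoxia)
  if (any(!is.finite(unlist(p))) ||
      any(unlist(p[c("r_c", "C_Mb", "alpha", "D", "P50_Mb", "P_crit",
                     "P_cap")]) <= 0) ||
      p$M0 < 0 || p$D_Mb < 0 || p$rest_fraction < 0 || p$P_hypoxia < 0) {
    stop("transport parameters must be positive (M0, D_Mb, rest_fraction, ",
         "P_hypoxia may be zero)")
  }
  structure(p, class = "transport_params")
}

# P-dependent effective diffusivity K(P) = D*alpha + D_Mb*C_Mb*S'(P)
k_eff <- function(P, params) {
  params$D * params$alpha +
    params$D_Mb * params$C_Mb * params$P50_Mb / (P + params$P50_Mb)^2
}

resolve_demand <- function(demand, params) {
  if (is.character(demand)) {
    switch(match.arg(demand, c("max", "rest")),
           max = params$M0,
           rest = params$rest_fraction * params$M0)
  } else {
    stopifnot(is.numeric(demand), demand >= 0)
    demand
  }
}

#' Solve the steady-state tissue PO2 field
#'
#' @param capillaries Perfused capillary coordinates: a data frame with
#'   columns `x`, `y` in um (rows flagged `perfused = FALSE` are dropped),
#'   or a `capillary_section` (its perfused capillaries are used).
#' @param frame A [counting_frame()] delimiting the solved region.
#' @param params A [transport_params()].
#' @param h Grid spacing in um (must be <= 2).
#' @param demand `"max"`, `"rest"`, or a numeric demand in
#'   ml O2 ml^-1 s^-1.
#' @param consumption `"michaelis"` (default) or `"constant"`
#'   (zeroth-order, used for closed-form checks).
#' @param tol Picard convergence tolerance on max |delta P|, mmHg.
#' @param max_iter Iteration cap; non-convergence raises an error carrying
#'   the residual history.
#' @param relax Under-relaxation factor in (0, 1].
#' @return Object of class `po2_field`: matrix `po2` (mmHg; rows index x,
#'   columns y), node coordinates, capillary mask, iteration diagnostics.
#' @export
solve_po2 <- function(capillaries, frame, params = transport_params(),
                      h = 2, demand = "max", consumption = "michaelis",
                      tol = 1e-6, max_iter = 300L, relax = 0.7) {
  if (inherits(capillaries, "capillary_section")) {
    capillaries <- capillaries$capillaries[capillaries$capillaries$perfused, ]
  }
  if (h > 2 + 1e-9) stop("grid spacing h must be <= 2 um")
  consumption <- match.arg(consumption, c("michaelis", "constant"))
  M0 <- resolve_demand(demand, params)
  xl <- frame_xlim(frame); yl <- frame_ylim(frame)
  inside <- capillaries$x >= xl[1L] & capillaries$x <= xl[2L] &
            capillaries$y >= yl[1L] & capillaries$y <= yl[2L]
  caps <- capillaries[inside, , drop = FALSE]

  nx <- max(2L, round(frame$side / h))
  ny <- nx
  h_cm <- frame$side / nx * 1e-4
  gx <- (seq_len(nx) - 0.5) * frame$side / nx   # um, frame-local
  gy <- (seq_len(ny) - 0.5) * frame$side / ny

  if (nrow(caps) == 0L) {
    warning("no perfused capillaries in frame: returning the degenerate ",
            "all-hypoxic field")
    return(structure(list(
      po2 = matrix(0, nx, ny), x = gx, y = gy, h = frame$side / nx,
      cap_mask = matrix(FALSE, nx, ny), iterations = 0L,
      residuals = numeric(0), converged = TRUE, degenerate = TRUE,
      demand = M0, params = params, frame = frame), class = "po2_field"))
  }

  # capillary mask: nodes within r_c of a capillary centre; isolated
  # capillaries smaller than the grid take their nearest node
  r_c_um <- params$r_c * 1e4
  cap_mask <- matrix(FALSE, nx, ny)
  cxl <- caps$x - xl[1L]
  cyl <- caps$y - yl[1L]
  for (k in seq_len(nrow(caps))) {
    ix <- which(abs(gx - cxl[k]) <= r_c_um + 1e-12)
    iy <- which(abs(gy - cyl[k]) <= r_c_um + 1e-12)
    hitany <- FALSE
    for (i in ix) for (j in iy) {
      if ((gx[i] - cxl[k])^2 + (gy[j] - cyl[k])^2 <= r_c_um^2 + 1e-12) {
        cap_mask[i, j] <- TRUE
        hitany <- TRUE
      }
    }
    if (!hitany) {
      i <- which.min(abs(gx - cxl[k]))
      j <- which.min(abs(gy - cyl[k]))
      cap_mask[i, j] <- TRUE
    }
  }

  tissue <- !cap_mask
  nt <- sum(tissue)
  tidx <- matrix(0L, nx, ny)
  tidx[tissue] <- seq_len(nt)

  idx <- matrix(seq_len(nx * ny), nx, ny)
  pa <- c(idx[-nx, ], idx[, -ny])   # neighbour pairs (a left/below b)
  pb <- c(idx[-1L, ], idx[, -1L])

  P <- matrix(params$P_cap, nx, ny)
  residuals <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    Kn <- k_eff(P, params)
    Kf <- (Kn[pa] + Kn[pb]) / 2 / h_cm^2
    at <- tissue[pa]; bt <- tissue[pb]

    both <- at & bt
    ia <- tidx[pa[both]]; ib <- tidx[pb[both]]; kb <- Kf[both]
    acap <- !at & bt     # a is capillary, b tissue
    bcap <- at & !bt
    icap_b <- tidx[pb[acap]]; k_ab <- Kf[acap]
    icap_a <- tidx[pa[bcap]]; k_ba <- Kf[bcap]

    ii <- c(ia, ib, ia, ib, icap_b, icap_a)
    jj <- c(ia, ib, ib, ia, icap_b, icap_a)
    xx <- c(kb, kb, -kb, -kb, k_ab, k_ba)

    rhs <- numeric(nt)
    # tissue nodes may have several capillary faces; accumulate per face
    for (pair in list(list(icap_b, k_ab), list(icap_a, k_ba))) {
      if (length(pair[[1L]])) {
        add <- rowsum(pair[[2L]] * params$P_cap, pair[[1L]])
        rhs[as.integer(rownames(add))] <-
          rhs[as.integer(rownames(add))] + add[, 1L]
      }
    }
    if (consumption == "michaelis") {
      cvec <- M0 / (P[tissue] + params$P_crit)
      ii <- c(ii, seq_len(nt)); jj <- c(jj, seq_len(nt)); xx <- c(xx, cvec)
    } else {
      rhs <- rhs - M0
    }
    A <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(nt, nt))
    sol <- as.numeric(Matrix::solve(A, rhs))
    res <- max(abs(sol - P[tissue]))
    residuals <- c(residuals, res)
    P[tissue] <- P[tissue] + relax * (sol - P[tissue])
    if (res < tol) {
      P[tissue] <- sol
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("PO2 solver failed to converge in ", max_iter,
         " iterations; final residual ", signif(tail(residuals, 1L), 4),
         " mmHg (history: ",
         paste(signif(tail(residuals, 5L), 3), collapse = ", "), ")")
  }
  P[tissue] <- pmax(P[tissue], 0)
  P[cap_mask] <- params$P_cap

  structure(list(po2 = P, x = gx, y = gy, h = frame$side / nx,
                 cap_mask = cap_mask, iterations = length(residuals),
                 residuals = residuals, converged = TRUE, degenerate = FALSE,
                 demand = M0, consumption = consumption,
                 params = params, frame = frame),
            class = "po2_field")
}

#' @export
print.po2_field <- function(x, ...) {
  cat("<po2_field>", nrow(x$po2), "x", ncol(x$po2), "nodes, h =", x$h,
      "um;", x$iterations, "iterations\n")
  ti <- !x$cap_mask
  cat(sprintf("  PO2 (tissue): mean %.2f, min %.2f mmHg; demand %.3g\n",
              mean(x$po2[ti]), min(x$po2[ti]), x$demand))
  invisible(x)
}

#' Hypoxic-area summary of a PO2 field
#'
#' @param field A `po2_field`.
#' @param threshold Hypoxia threshold in mmHg (default: the field's
#'   `P_hypoxia` parameter, 0.5 mmHg).
#' @return Object of class `hypoxia_summary`: hypoxic fraction of
#'   non-capillary tissue, mean and min tissue PO2, demand label.
#' @export
hypoxic_fraction <- function(field, threshold = NULL) {
  stopifnot(inherits(field, "po2_field"))
  thr <- threshold %||% field$params$P_hypoxia
  ti <- !field$cap_mask
  structure(list(
    hypoxic_fraction = mean(field$po2[ti] < thr),
    mean_po2 = mean(field$po2[ti]),
    min_po2 = min(field$po2[ti]),
    threshold = thr,
    demand = field$demand), class = "hypoxia_summary")
}

#' @export
print.hypoxia_summary <- function(x, ...) {
  cat(sprintf(
    "<hypoxia_summary> %.1f%% of tissue below %.2g mmHg (mean %.2f, min %.2f)\n",
    100 * x$hypoxic_fraction, x$threshold, x$mean_po2, x$min_po2))
  invisible(x)
}

#' Sweep oxygen demand levels over one frame
#'
#' @param capillaries Perfused capillaries (see [solve_po2()]).
#' @param frame A [counting_frame()].
#' @param params A [transport_params()].
#' @param demands Vector of demand levels: `"rest"`, `"max"`, or numeric.
#' @param ... Passed to [solve_po2()].
#' @return Data frame: demand label, demand value, hypoxic fraction, mean
#'   and min tissue PO2.
#' @export
demand_sweep <- function(capillaries, frame, params = transport_params(),
                         demands = c("rest", "max"), ...) {
  rows <- lapply(demands, function(d) {
    fld <- tryCatch(
      solve_po2(capillaries, frame, params, demand = d, ...),
      error = function(e) stop("demand ", d, ": ", conditionMessage(e)))
    hs <- hypoxic_fraction(fld)
    data.frame(demand = as.character(d), demand_value = fld$demand,
               hypoxic_fraction = hs$hypoxic_fraction,
               mean_po2 = hs$mean_po2, min_po2 = hs$min_po2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Radial Krogh-cylinder solver and closed form

#' Krogh-Erlang closed-form radial PO2 profile
#'
#' Solution of the Krogh tissue-cylinder model with uniform (zeroth-order)
#' consumption and free diffusion only:
#' `P(r) = P_cap - (M0 / (D alpha)) * ((r_t^2 / 2) ln(r / r_c) -
#' (r^2 - r_c^2) / 4)`.
#'
#' @param r Radii, cm (vectorised), in `[r_c, r_t]`.
#' @param params A [transport_params()] (uses `r_c`, `M0`, `D`, `alpha`,
#'   `P_cap`).
#' @param r_t Tissue cylinder radius, cm.
#' @param demand Demand level (default maximal).
#' @return PO2 at `r`, mmHg (may be negative if the cylinder outruns the
#'   supply; the caller decides how to interpret that regime).
#' @export
krogh_erlang <- function(r, params = transport_params(), r_t,
                         demand = "max") {
  M0 <- resolve_demand(demand, params)
  K <- params$D * params$alpha
  params$P_cap - (M0 / K) *
    ((r_t^2 / 2) * log(r / params$r_c) - (r^2 - params$r_c^2) / 4)
}

#' Radial finite-difference solver for the Krogh cylinder
#'
#' Solves `(1/r) d/dr ( r K(P) dP/dr ) = M(P)` on `[r_c, r_t]` with
#' `P(r_c) = P_cap` and no flux at `r_t`, by finite volumes and Picard
#' iteration. With `consumption = "constant"` and `D_Mb = 0` the solution
#' has the Krogh-Erlang closed form, which serves as the solver oracle.
#'
#' @param params A [transport_params()].
#' @param r_t Tissue cylinder radius, cm.
#' @param h Grid spacing in um (default 0.5).
#' @param demand Demand level.
#' @param consumption `"michaelis"` or `"constant"`.
#' @param tol,max_iter Picard controls.
#' @return Data frame with columns `r` (cm) and `po2` (mmHg); attributes
#'   `iterations`.
#' @export
solve_po2_radial <- function(params = transport_params(), r_t, h = 0.5,
                             demand = "max", consumption = "michaelis",
                             tol = 1e-8, max_iter = 200L) {
  consumption <- match.arg(consumption, c("michaelis", "constant"))
  M0 <- resolve_demand(demand, params)
  h_cm <- h * 1e-4
  r <- seq(params$r_c, r_t, by = h_cm)
  if (abs(tail(r, 1L) - r_t) > 1e-12) r <- c(r, r_t)
  n <- length(r)
  P <- rep(params$P_cap, n)
  for (it in seq_len(max_iter)) {
    K <- k_eff(P, params)
    A <- matrix(0, n, n)
    b <- numeric(n)
    A[1L, 1L] <- 1
    b[1L] <- params$P_cap
    for (j in 2:n) {
      hm <- r[j] - r[j - 1L]
      rm <- (r[j] + r[j - 1L]) / 2
      km <- (K[j] + K[j - 1L]) / 2
      wm <- rm * km / hm
      if (j < n) {
        hp <- r[j + 1L] - r[j]
        rp <- (r[j] + r[j + 1L]) / 2
        kp <- (K[j] + K[j + 1L]) / 2
        wp <- rp * kp / hp
        vol <- r[j] * (hm + hp) / 2
        A[j, j - 1L] <- -wm
        A[j, j + 1L] <- -wp
        A[j, j] <- wm + wp
      } else {
        vol <- r[j] * hm / 2
        A[j, j - 1L] <- -wm
        A[j, j] <- wm
      }
      if (consumption == "michaelis") {
        A[j, j] <- A[j, j] + vol * M0 / (P[j] + params$P_crit)
      } else {
        b[j] <- -vol * M0
      }
    }
    sol <- solve(A, b)
    res <- max(abs(sol - P))
    P <- sol
    if (res < tol) break
  }
  out <- data.frame(r = r, po2 = P)
  attr(out, "iterations") <- it
  out
}

#' Discrete flux balance of a converged PO2 field
#'
#' Total oxygen consumption over tissue nodes versus total diffusive efflux
#' across capillary-node faces; the two agree at convergence (discrete
#' conservation).
#'
#' @param field A converged `po2_field`.
#' @return List: `consumption`, `efflux` (ml O2 s^-1 per cm of section
#'   thickness), `rel_imbalance`.
#' @export
po2_flux_balance <- function(field) {
  stopifnot(inherits(field, "po2_field"), !field$degenerate)
  P <- field$po2
  params <- field$params
  h_cm <- field$h * 1e-4
  ti <- !field$cap_mask
  M <- if (identical(field$consumption, "constant")) {
    matrix(field$demand, nrow(P), ncol(P))
  } else {
    field$demand * P / (P + params$P_crit)
  }
  consumption <- sum(M[ti]) * h_cm^2

  Kn <- k_eff(P, params)
  nx <- nrow(P); ny <- ncol(P)
  idx <- matrix(seq_len(nx * ny), nx, ny)
  pa <- c(idx[-nx, ], idx[, -ny])
  pb <- c(idx[-1L, ], idx[, -1L])
  capface <- xor(field$cap_mask[pa], field$cap_mask[pb])
  kf <- (Kn[pa] + Kn[pb]) / 2
  dP <- ifelse(field$cap_mask[pa], P[pa] - P[pb], P[pb] - P[pa])
  efflux <- sum((kf * dP)[capface])  # K (P_cap - P_tissue) per unit length
  list(consumption = consumption, efflux = efflux,
       rel_imbalance = abs(consumption - efflux) / max(consumption, 1e-30))
}
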