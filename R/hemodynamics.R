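# Reduced-order pulsatile hemodynamics over the extracted vascular tree: a
# quasi-static Poiseuille (0D) network. Each vessel segment is a resistor
# R = 8*mu*L/(pi*r^4); at every time step nodal pressures solve the linear
# conservation equations with the inlet flow prescribed and outlet pressures
# fixed. The solver produces per-face (inlet/outlet cross-section) flowrate
# and pressure time series and the summary features used for
# classification. Internal units are CGS (cm, s, dyn); with a half-sine
# inlet pulse this emulates one cardiac ejection into the optic-disc
# vasculature.

#' Build a 0D flow network from a centerline profile
#'
#' One edge per profiled vessel segment, with physical length equal to the
#' polyline length and radius equal to the segment's median measured radius
#' (both scaled by `px_size`). The inlet is the degree-1 node whose adjacent
#' segment is thickest (the root vessel) unless given explicitly; every
#' other degree-1 node is an outlet held at the reference pressure.
#'
#' @param profile a `centerline_profile` (radii in px; `px_size` converts to
#'   cm) or any list with compatible `segments`/`nodes`.
#' @param mu dynamic viscosity in dyn s/cm^2 (default 0.035, whole blood).
#' @param px_size physical pixel size in cm (default: the profile's).
#' @param inlet node id of the inlet; default chosen as above.
#' @param outlet_pressure reference (gauge) pressure at outlets, dyn/cm^2.
#' @return object of class `flow_network`: `nodes` (id, row, col, degree),
#'   `edges` (from, to, L, r, R_hyd), `inlet`, `outlets`, `mu`,
#'   `outlet_pressure`.
#' @export
build_flow_network <- function(profile, mu = 0.035, px_size = NULL,
                               inlet = NULL, outlet_pressure = 0) {
  ps <- px_size %||% profile$px_size %||% 1
  segs <- profile$segments
  if (length(segs) == 0L) stop("profile has no segments")
  edges <- do.call(rbind, lapply(segs, function(s) {
    L <- polyline_length(s$points) * ps
    r <- stats::median(s$radii_px) * ps
    data.frame(from = s$from, to = s$to, L = L, r = r)
  }))
  if (any(edges$L <= 0) || any(edges$r <= 0)) {
    stop("edges must have positive length and radius after scaling")
  }
  edges$R_hyd <- 8 * mu * edges$L / (pi * edges$r^4)
  ids <- sort(unique(c(edges$from, edges$to)))
  # connectivity (union-find)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$from[k], ids)); b <- find(match(edges$to[k], ids))
    if (a != b) parent[a] <- b
  }
  comps <- vapply(seq_along(ids), find, integer(1L))
  if (length(unique(comps)) > 1L) {
    stop("flow network is disconnected; components: ",
         paste(tapply(ids, comps, paste, collapse = ","), collapse = " | "))
  }
  degree <- table(c(edges$from, edges$to))
  deg <- as.integer(degree[as.character(ids)])
  terminals <- ids[deg == 1L]
  if (length(terminals) < 2L) stop("network needs an inlet and at least one outlet")
  if (is.null(inlet)) {
    term_r <- vapply(terminals, function(id) {
      max(edges$r[edges$from == id | edges$to == id])
    }, numeric(1L))
    inlet <- terminals[which.max(term_r)]
  }
  if (!inlet %in% terminals) stop("inlet must be a degree-1 node")
  nd <- if (!is.null(profile$nodes)) {
    profile$nodes[match(ids, profile$nodes$id), c("id", "row", "col")]
  } else data.frame(id = ids, row = NA_real_, col = NA_real_)
  nd$degree <- deg
  structure(list(nodes = nd, edges = edges, inlet = inlet,
                 outlets = setdiff(terminals, inlet), mu = mu,
                 outlet_pressure = outlet_pressure, px_size = ps),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("<flow_network> %d nodes, %d edges, inlet %d, %d outlets, mu=%g\n",
              nrow(x$nodes), nrow(x$edges), x$inlet, length(x$outlets), x$mu))
  invisible(x)
}

#' Inlet flow waveform
#'
#' Parametric pulse sampled at T steps over one period using midpoint
#' sampling (t_k = (k - 1/2) * period / T). The default half-sine has a
#' single interior maximum, mimicking one systolic ejection.
#'
#' @param shape "halfsine" or "constant".
#' @param T number of time steps (>= 2).
#' @param period pulse duration in seconds.
#' @param peak peak flow in cm^3/s (> 0).
#' @return list with `t` (times), `q` (flows), `period`, `shape`.
#' @export
inlet_waveform <- function(shape = c("halfsine", "constant"), T = 32L,
                           period = 1, peak = 1) {
  shape <- match.arg(shape)
  stopifnot(T >= 2L)
  if (peak <= 0) stop("peak flow must be positive")
  tt <- (seq_len(T) - 0.5) / T * period
  q <- switch(shape,
              halfsine = peak * sin(pi * tt / period),
              constant = rep(peak, T))
  list(t = tt, q = q, period = period, shape = shape)
}

#' Solve the network for all time steps
#'
#' Quasi-static: at each step the nodal pressures solve the linear system of
#' flow conservation with edge law Q = dP / R_hyd, the inlet flow
#' prescribed, and outlet pressures fixed at the reference value. Returns
#' per-face series (faces = inlet + outlets, the model's cross-sections) and
#' the full nodal/edge solution for diagnostics.
#'
#' @param net a `flow_network`.
#' @param waveform from [inlet_waveform()].
#' @return object of class `hemo_solution`: `faces` (node ids, inlet
#'   first, then outlets ordered by image position), `face_names`, `Q`
#'   (faces x T, positive into the network at the inlet and out of it at
#'   outlets), `P` (faces x T), `node_pressure` (nodes x T), `edge_flow`
#'   (edges x T), `waveform`, `net`.
#' @export
solve_network <- function(net, waveform) {
  ids <- net$nodes$id
  n <- length(ids)
  ei <- match(net$edges$from, ids)
  ej <- match(net$edges$to, ids)
  g <- 1 / net$edges$R_hyd
  G <- matrix(0, n, n)
  for (k in seq_along(g)) {
    G[ei[k], ei[k]] <- G[ei[k], ei[k]] + g[k]
    G[ej[k], ej[k]] <- G[ej[k], ej[k]] + g[k]
    G[ei[k], ej[k]] <- G[ei[k], ej[k]] - g[k]
    G[ej[k], ei[k]] <- G[ej[k], ei[k]] - g[k]
  }
  fixed <- match(net$outlets, ids)
  if (length(fixed) == 0L) stop("no outlet pressure constraints; system singular")
  free <- setdiff(seq_len(n), fixed)
  inlet_i <- match(net$inlet, ids)
  T <- length(waveform$q)
  P <- matrix(0, n, T)
  A <- G[free, free, drop = FALSE]
  for (t in seq_len(T)) {
    b <- rep(0, n)
    b[inlet_i] <- waveform$q[t]
    rhs <- b[free] - G[free, fixed, drop = FALSE] %*% rep(net$outlet_pressure, length(fixed))
    p <- rep(net$outlet_pressure, n)
    p[free] <- solve(A, rhs)
    P[, t] <- p
  }
  edge_flow <- (P[ei, , drop = FALSE] - P[ej, , drop = FALSE]) * g
  # faces: inlet first, outlets ordered by (row, col) position for stable
  # naming across subjects
  out_ids <- net$outlets
  ord <- order(net$nodes$row[match(out_ids, ids)],
               net$nodes$col[match(out_ids, ids)])
  faces <- c(net$inlet, out_ids[ord])
  face_names <- c("inlet", sprintf("outlet_%d", seq_along(out_ids)))
  Q <- matrix(0, length(faces), T)
  Q[1L, ] <- waveform$q
  for (f in seq_along(out_ids)) {
    id <- out_ids[ord][f]
    i <- match(id, ids)
    adj <- which(ei == i | ej == i)
    # net flow out of the network at this terminal
    qf <- rep(0, T)
    for (k in adj) {
      s <- if (ej[k] == i) 1 else -1
      qf <- qf + s * edge_flow[k, ]
    }
    Q[f + 1L, ] <- qf
  }
  Pf <- P[match(faces, ids), , drop = FALSE]
  rownames(Q) <- rownames(Pf) <- face_names
  structure(list(faces = faces, face_names = face_names, Q = Q, P = Pf,
                 node_pressure = P, edge_flow = edge_flow,
                 waveform = waveform, net = net),
            class = "hemo_solution")
}

#' @export
print.hemo_solution <- function(x, ...) {
  cat(sprintf("<hemo_solution> %d faces x %d steps; peak inlet pressure %.4g dyn/cm^2\n",
              length(x$faces), ncol(x$Q), max(x$P[1L, ])))
  invisible(x)
}

#' Mass-conservation residual of a solution
#'
#' Largest over internal nodes and steps of |net flow| relative to the peak
#' inlet flow.
#' @param sol a `hemo_solution`.
#' @return numeric scalar.
#' @export
hemo_mass_residual <- function(sol) {
  net <- sol$net
  ids <- net$nodes$id
  ei <- match(net$edges$from, ids)
  ej <- match(net$edges$to, ids)
  internal <- setdiff(seq_along(ids),
                      match(c(net$inlet, net$outlets), ids))
  if (length(internal) == 0L) return(0)
  worst <- 0
  for (i in internal) {
    bal <- rep(0, ncol(sol$edge_flow))
    for (k in which(ei == i)) bal <- bal - sol$edge_flow[k, ]
    for (k in which(ej == i)) bal <- bal + sol$edge_flow[k, ]
    worst <- max(worst, max(abs(bal)))
  }
  worst / max(abs(sol$waveform$q))
}

#' Extract the named hemodynamic feature vector
#'
#' Emits, in a documented fixed order:
#' 1. `Q_<face>_step_<k>`: flowrate series per face (cm^3/s);
#' 2. `P_<face>_step_<k>`: pressure series per face (dyn/cm^2);
#' 3. per face `Q_mean/Q_max/Q_min/P_mean/P_max/P_min`;
#' 4. derived: `Qmax_Time` (time at which the across-face mean flowrate is
#'    maximal, waveform time units; ties broken to the earliest step),
#'    `Qmax_Time_from_cm` (same statistic with flow converted from cm^3/s
#'    to L/min), and `Step_<k>_mean` (across-face mean flowrate at step k)
#'    for every step.
#'
#' Blocks 1-3 contribute 2*F*T + 6*F features for F faces and T steps —
#' e.g. F = 2, T = 32 gives 140 — and block 4 adds T + 2 derived features.
#'
#' @param sol a `hemo_solution` with at least 13 steps (so `Step_12_mean`
#'   exists).
#' @return named numeric vector.
#' @export
extract_hemo_features <- function(sol) {
  T <- ncol(sol$Q)
  if (T < 13L) stop("need at least 13 time steps for the step features")
  F <- nrow(sol$Q)
  out <- c()
  for (f in seq_len(F)) {
    v <- sol$Q[f, ]
    names(v) <- sprintf("Q_%s_step_%d", sol$face_names[f], seq_len(T))
    out <- c(out, v)
  }
  for (f in seq_len(F)) {
    v <- sol$P[f, ]
    names(v) <- sprintf("P_%s_step_%d", sol$face_names[f], seq_len(T))
    out <- c(out, v)
  }
  for (f in seq_len(F)) {
    v <- c(mean(sol$Q[f, ]), max(sol$Q[f, ]), min(sol$Q[f, ]),
           mean(sol$P[f, ]), max(sol$P[f, ]), min(sol$P[f, ]))
    names(v) <- sprintf("%s_%s", c("Q_mean", "Q_max", "Q_min",
                                   "P_mean", "P_max", "P_min"),
                        sol$face_names[f])
    out <- c(out, v)
  }
  mean_q <- colMeans(sol$Q)
  qmax_i <- which.max(mean_q) # which.max takes the earliest maximum
  mean_q_lmin <- mean_q * 60 / 1000
  qmax_i_cm <- which.max(mean_q_lmin)
  der <- c(Qmax_Time = sol$waveform$t[qmax_i],
           Qmax_Time_from_cm = sol$waveform$t[qmax_i_cm])
  steps <- mean_q
  names(steps) <- sprintf("Step_%d_mean", seq_len(T))
  c(out, der, steps)
}
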