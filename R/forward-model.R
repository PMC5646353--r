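#' Five-concentric-sphere volume conductor
#'
#' Head model with five concentric spherical shells (white matter, gray
#' matter, cerebrospinal fluid, skull, skin) of given radii and isotropic
#' conductivities. The defaults are conventional published shell values
#' scaled to an 88 mm scalp sphere; they are configuration, not a claim about
#' any individual head.
#'
#' @param radii five strictly increasing shell radii in mm (white, gray, CSF,
#'   skull, skin).
#' @param conductivities five positive conductivities in S/m, same order.
#' @return An object of class `head_model`.
#' @export
head_model <- function(radii = c(63, 72, 78, 85, 88),
                       conductivities = c(0.14, 0.33, 1.79, 0.01, 0.43)) {
  if (length(radii) != 5L || length(conductivities) != 5L)
    stop("need five radii and five conductivities")
  if (any(diff(radii) <= 0))
    stop("shell radii must be strictly increasing (white ... skin)")
  if (any(conductivities <= 0))
    stop("conductivities must be positive")
  structure(list(radii = as.numeric(radii),
                 conductivities = as.numeric(conductivities)),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> 5 concentric shells\n")
  cat("  radii (mm):        ", paste(x$radii, collapse = ", "), "\n")
  cat("  conductivity (S/m):", paste(x$conductivities, collapse = ", "), "\n")
  invisible(x)
}

# ---- idealized 10-10 electrode template ------------------------------------

# unit vector from inclination theta (deg, from vertex) and azimuth phi
# (deg, 0 = nasion/front, positive to the right); x right, y front, z up
.sph_point <- function(theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

# spherical linear interpolation (supports extrapolation f > 1)
.slerp <- function(p0, p1, f) {
  om <- acos(max(-1, min(1, sum(p0 * p1))))
  if (om < 1e-9) return(p0)
  (sin((1 - f) * om) * p0 + sin(f * om) * p1) / sin(om)
}

# row geometry: midline inclination and circumferential-ring azimuth (deg)
.row_geom <- list(
  Fp = list(mid = c(72, 0),   end = c(72, 18)),
  AF = list(mid = c(54, 0),   end = c(72, 36)),
  F  = list(mid = c(36, 0),   end = c(72, 54)),
  FC = list(mid = c(18, 0),   end = c(72, 72)),
  C  = list(mid = c(0, 0),    end = c(72, 90)),
  CP = list(mid = c(18, 180), end = c(72, 108)),
  P  = list(mid = c(36, 180), end = c(72, 126)),
  PO = list(mid = c(54, 180), end = c(72, 144)),
  O  = list(mid = c(72, 180), end = c(72, 162)),
  OI = list(mid = c(81, 180), end = c(81, 171)),
  I  = list(mid = c(90, 180), end = c(90, 180)))

# parse a 10-10 label into row, side and arc fraction
.parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)([0-9]+|z)$", label))[[1L]]
  if (length(m) != 3L) stop("cannot parse electrode label: ", label)
  prefix <- m[2L]; idx <- m[3L]
  row <- switch(prefix,
                T = "C", FT = "FC", TP = "CP",
                Fp = "Fp", AF = "AF", F = "F", FC = "FC", C = "C",
                CP = "CP", P = "P", PO = "PO", O = "O", OI = "OI", I = "I",
                stop("unknown electrode row in label: ", label))
  if (idx == "z") return(list(row = row, side = 0, f = 0))
  k <- as.integer(idx)
  side <- if (k %% 2 == 1) -1 else 1        # odd left, even right
  rank <- ceiling(k / 2)
  # T/FT/TP/P7-style labels sit one rank further out than their digit implies
  # relative to the row's own numbering (..1,3,5 are interior, 7 the ring,
  # 9 below the ring); Fp and O rows only have their ring positions
  f <- if (row %in% c("Fp", "O")) 1 else rank * 0.25
  list(row = row, side = side, f = f)
}

#' Idealized 10-10 electrode positions
#'
#' Constructs template electrode positions on the unit sphere for 10-20/10-10
#' labels by great-circle interpolation between the midline position of each
#' coronal row and the row's end point on the 10% circumferential ring
#' (extrapolating one step beyond the ring for the 9/10 positions). This is a
#' synthetic idealized template, adequate for spherical head models; it is
#' not a digitized montage.
#'
#' @param labels electrode labels; defaults to the 60-channel montage used
#'   throughout the package.
#' @return Data frame with `label`, `x`, `y`, `z` on the unit sphere
#'   (x right, y front, z up).
#' @export
electrode_positions_1020 <- function(labels = default_montage()) {
  pos <- t(vapply(labels, function(lb) {
    p <- .parse_label(lb)
    g <- .row_geom[[p$row]]
    mid <- .sph_point(g$mid[1], g$mid[2])
    if (p$f == 0) return(mid)
    endp <- .sph_point(g$end[1], p$side * g$end[2])
    v <- .slerp(mid, endp, p$f)
    v / sqrt(sum(v^2))
  }, numeric(3)))
  data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

#' Default 60-channel montage labels
#'
#' The 60 scalp positions (10-20 system selection) assumed by the cohort
#' simulator and the packaged electrode template.
#'
#' @return Character vector of 60 labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T7", "T8", "P7", "P8", "Iz", "Cz", "Pz",
    "FC1", "FC2", "CP1", "CP2", "FC5", "FC6", "CP5", "CP6",
    "TP9", "TP10", "Fpz", "Oz", "FT9", "FT10", "PO9", "PO10",
    "C1", "C2", "PO1", "PO2", "Fz", "AFz", "F5", "F6", "FT7", "FT8",
    "FC3", "FC4", "C5", "C6", "TP7", "TP8", "CP3", "CP4", "P5", "P6",
    "OI1", "OI2", "FCz", "CPz", "POz")
}

#' Load the packaged electrode template
#'
#' Reads the tab-separated idealized 10-10 template shipped with the package
#' (label, x, y, z on the unit sphere).
#'
#' @return Data frame with `label`, `x`, `y`, `z`.
#' @export
load_electrode_template <- function() {
  path <- system.file("extdata", "electrodes_1020_synthetic.tsv",
                      package = "sourceflow")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# ---- multishell spherical forward solution ---------------------------------

# per-degree interface transfer and source-to-scalp responses.
# Works in radii normalized by the scalp radius; returns for each degree n
# and each possible source shell s the scalp-coefficient response to a unit
# inner (r^n) and unit outer (r^-(n+1)) source term.
.shell_responses <- function(hm, n_terms) {
  rr <- hm$radii / hm$radii[5L]
  sig <- hm$conductivities
  g_in <- matrix(0, n_terms, 4L)   # response to unit inner source coef
  g_out <- matrix(0, n_terms, 4L)  # response to unit outer source coef
  for (n in seq_len(n_terms)) {
    M <- vector("list", 4L)
    for (j in 1:4) {
      a <- rr[j]; kap <- sig[j] / sig[j + 1L]
      a_p <- a^(2 * n + 1)
      M[[j]] <- matrix(c((n + 1 + kap * n) / (2 * n + 1),
                         n * (1 - kap) * a_p / (2 * n + 1),
                         (n + 1) * (1 - kap) / ((2 * n + 1) * a_p),
                         (n + kap * (n + 1)) / (2 * n + 1)),
                       2L, 2L)
    }
    # cumulative propagation from shell s to the outermost shell
    P <- vector("list", 5L)
    P[[5L]] <- diag(2)
    for (s in 4:1) P[[s]] <- P[[s + 1L]] %*% M[[s]]
    phi <- function(cc) n * cc[1L] - (n + 1) * cc[2L]   # outer Neumann form
    psi <- function(cc) cc[1L] + cc[2L]                 # value at scalp
    for (s in 1:4) {
      # inward-regular homogeneous solution propagated from shell 1
      u <- c(1, 0)
      if (s > 1) for (j in seq_len(s - 1L)) u <- M[[j]] %*% u
      v <- P[[s]] %*% u
      solve_src <- function(d) {
        pd <- P[[s]] %*% d
        alpha <- -phi(pd) / phi(v)
        psi(alpha * v + pd)
      }
      # unit inner source term (r^n); absent below the source for shell 1
      g_in[n, s] <- if (s == 1) 0 else solve_src(c(-1, 0))
      g_out[n, s] <- solve_src(c(0, 1))
    }
  }
  # The raw per-degree responses are differences/products of terms carrying
  # radius-ratio powers ~ a^(2n+1), so beyond some degree they hit the
  # double-precision noise floor and then explode, while the true responses
  # decay smoothly (inner-image reflections ~ r^(2n+1)) or level off
  # (transmission factors). Detect the noise takeover (loss of smooth decay)
  # and continue the true tail geometrically from the last trusted terms.
  for (s in 1:4) {
    g_in[, s] <- .stabilize_tail(g_in[, s])
    g_out[, s] <- .stabilize_tail(g_out[, s])
  }
  list(g_in = g_in, g_out = g_out, rr = rr)
}

# replace the noise-dominated tail of a geometrically decaying response
# sequence by geometric extrapolation from its last trusted terms
.stabilize_tail <- function(g) {
  n <- length(g)
  if (n < 6L || all(g == 0)) return(g)
  a <- abs(g)
  bad <- n + 1L
  for (k in 5:n) {
    if (!is.finite(g[k]) || a[k] == 0 || a[k] > 1.5 * a[k - 1L]) {
      bad <- k
      break
    }
  }
  if (bad > n) return(g)
  k0 <- bad - 1L
  q <- if (k0 >= 3L) stats::median(g[(k0 - 1L):k0] / g[(k0 - 2L):(k0 - 1L)])
  else 0.9
  if (!is.finite(q)) q <- 0.9
  q <- sign(q) * min(abs(q), 0.999)
  g[(k0 + 1L):n] <- g[k0] * q^(seq_len(n - k0))
  g
}

# Legendre P_n(x) and associated P_n^1(x) = sin * P_n'(x) for n = 1..N,
# vectorized over x; returns list of two (length(x) x N) matrices
.legendre_table <- function(x, n_terms) {
  sing <- sqrt(pmax(0, 1 - x^2))
  P <- matrix(0, length(x), n_terms)
  P1 <- matrix(0, length(x), n_terms)
  pm1 <- rep(1, length(x))   # P_0
  p <- x                     # P_1
  for (n in seq_len(n_terms)) {
    P[, n] <- p
    num <- n * (pm1 - x * p)
    P1[, n] <- ifelse(sing > 1e-12, num / sing, 0)
    pn1 <- ((2 * n + 1) * x * p - n * pm1) / (n + 1)
    pm1 <- p
    p <- pn1
  }
  list(P = P, P1 = P1)
}

# scalp potentials (one per electrode) for one dipole; positions in mm,
# moment in A*m, output in volts. `resp` from .shell_responses, `edir`
# electrode unit vectors.
.dipole_potentials <- function(hm, resp, edir, pos_mm, moment) {
  R_m <- hm$radii[5L] / 1000
  b <- sqrt(sum(pos_mm^2)) / hm$radii[5L]
  if (b < 1e-8)
    stop("dipole at the sphere center is orientation-degenerate")
  s <- findInterval(b, resp$rr, left.open = TRUE) + 1L
  if (s > 4L) stop("dipole outside the skull shell")
  sig_s <- hm$conductivities[s]
  n_terms <- nrow(resp$g_in)
  nvec <- seq_len(n_terms)
  b_out <- b^(nvec - 1)
  b_in <- b^(-(nvec + 2))
  K <- 1 / (4 * pi * sig_s * R_m^2)
  c_rad <- K * (nvec * b_out * resp$g_out[, s] -
                  (nvec + 1) * b_in * resp$g_in[, s])
  c_tan <- K * (b_out * resp$g_out[, s] + b_in * resp$g_in[, s])

  r0 <- pos_mm / sqrt(sum(pos_mm^2))
  cosg <- drop(edir %*% r0)
  cosg <- pmax(-1, pmin(1, cosg))
  leg <- .legendre_table(cosg, n_terms)
  v_rad <- drop(leg$P %*% c_rad)     # per unit radial moment
  v_tan <- drop(leg$P1 %*% c_tan)    # per unit tangential moment

  # tangential unit vector in the dipole-electrode plane, toward electrode
  tvec <- edir - outer(cosg, r0)
  tn <- sqrt(rowSums(tvec^2))
  tvec <- tvec / ifelse(tn > 1e-12, tn, 1)

  m_r <- sum(moment * r0)
  m_t <- drop(tvec %*% moment)
  v_rad * m_r + v_tan * m_t
}

#' Lead field on a regular source grid
#'
#' Computes the analytic five-shell spherical forward solution (Legendre
#' series truncated at `n_terms` terms) for every node of a regular grid
#' masked to the inside of the gray-matter shell (shell radius minus one grid
#' step, where beamformer weights are well behaved), for three orthogonal
#' unit dipole moments per node. Gain columns are average-referenced.
#'
#' @param hm a [head_model()].
#' @param electrodes data frame with `label`, `x`, `y`, `z`: positions on the
#'   scalp sphere in mm, or template positions on the unit sphere (which are
#'   scaled to the scalp radius). Positions off the scalp sphere by less than
#'   5 mm are projected onto it.
#' @param grid_spacing grid step in mm (5 mm default).
#' @param n_terms series truncation; 80 terms bound the relative series
#'   remainder below 1e-7 for sources one grid step inside the gray shell.
#' @return An object of class `lead_field`: list with `grid` (voxels x 3,
#'   mm), `gains` (voxels x channels x 3 array, V per A*m),
#'   `channel_labels`, `spacing`, `head_model`, `electrodes_mm`.
#' @export
compute_lead_field <- function(hm, electrodes = electrode_positions_1020(),
                               grid_spacing = 5, n_terms = 80) {
  stopifnot(inherits(hm, "head_model"))
  R <- hm$radii[5L]
  pos <- as.matrix(electrodes[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(pos^2))
  if (all(nrm < 1.5)) {
    pos <- pos * R            # unit-sphere template
  } else if (any(abs(nrm - R) >= 5)) {
    stop("electrode positions must lie within 5 mm of the scalp sphere")
  }
  edir <- pos / sqrt(rowSums(pos^2))

  r_mask <- hm$radii[2L] - grid_spacing
  ax <- seq(0, R, by = grid_spacing)
  ax <- sort(unique(c(-ax, ax)))
  ax <- ax[abs(ax) <= r_mask + 1e-9]
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rad <- sqrt(rowSums(grid^2))
  grid <- grid[rad <= r_mask & rad > 1e-6, , drop = FALSE]

  resp <- .shell_responses(hm, n_terms)
  n_ch <- nrow(edir)
  gains <- array(0, dim = c(nrow(grid), n_ch, 3L))
  I3 <- diag(3)
  for (v in seq_len(nrow(grid))) {
    for (a in 1:3) {
      g <- .dipole_potentials(hm, resp, edir, grid[v, ], I3[, a])
      gains[v, , a] <- g - mean(g)
    }
  }
  if (!all(is.finite(gains))) stop("non-finite lead-field gains")
  structure(list(grid = grid, gains = gains,
                 channel_labels = electrodes$label,
                 spacing = grid_spacing, head_model = hm,
                 electrodes_mm = pos, n_terms = n_terms),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d voxels @ %g mm, %d channels\n",
              nrow(x$grid), x$spacing, length(x$channel_labels)))
  invisible(x)
}

#' Forward potentials for arbitrary dipoles
#'
#' Evaluates the five-shell forward solution at exact (off-grid) dipole
#' positions, reusing a lead field's head model and electrode layout.
#'
#' @param lf a [compute_lead_field()] result.
#' @param positions dipoles x 3 matrix, mm.
#' @param moments dipoles x 3 matrix of dipole moments (A*m).
#' @return channels x dipoles matrix of average-referenced potentials (V).
#' @export
forward_potentials <- function(lf, positions, moments) {
  stopifnot(inherits(lf, "lead_field"))
  positions <- rbind(positions)
  moments <- rbind(moments)
  resp <- .shell_responses(lf$head_model, lf$n_terms)
  edir <- lf$electrodes_mm / sqrt(rowSums(lf$electrodes_mm^2))
  r_in <- lf$head_model$radii[2L]
  out <- vapply(seq_len(nrow(positions)), function(k) {
    if (sqrt(sum(positions[k, ]^2)) > r_in)
      stop(sprintf("dipole %d lies outside the gray-matter shell", k))
    g <- .dipole_potentials(lf$head_model, resp, edir,
                            positions[k, ], moments[k, ])
    g - mean(g)
  }, numeric(nrow(edir)))
  matrix(out, nrow = nrow(edir))
}

#' Single-sphere analytic potentials
#'
#' Classical homogeneous-sphere surface potential for an internal dipole
#' (per-degree coefficients (2n+1)/n), used as an independent oracle for the
#' multishell solver in the equal-conductivity limit.
#'
#' @param radius_mm sphere radius, mm.
#' @param sigma conductivity, S/m.
#' @param edir electrodes x 3 unit direction matrix.
#' @param pos_mm dipole position, mm.
#' @param moment dipole moment, A*m.
#' @param n_terms series truncation.
#' @return Potentials in volts, one per electrode (not average-referenced).
#' @export
single_sphere_potentials <- function(radius_mm, sigma, edir, pos_mm, moment,
                                     n_terms = 120) {
  R_m <- radius_mm / 1000
  b <- sqrt(sum(pos_mm^2)) / radius_mm
  nvec <- seq_len(n_terms)
  coef <- (2 * nvec + 1) / nvec * b^(nvec - 1) / (4 * pi * sigma * R_m^2)
  r0 <- pos_mm / sqrt(sum(pos_mm^2))
  cosg <- pmax(-1, pmin(1, drop(edir %*% r0)))
  leg <- .legendre_table(cosg, n_terms)
  tvec <- edir - outer(cosg, r0)
  tn <- sqrt(rowSums(tvec^2))
  tvec <- tvec / ifelse(tn > 1e-12, tn, 1)
  m_r <- sum(moment * r0)
  m_t <- drop(tvec %*% moment)
  drop(leg$P %*% (coef * nvec)) * m_r + drop(leg$P1 %*% coef) * m_t
}

#' Save / load a lead field
#'
#' Lead fields are expensive to build; these helpers serialize them to RDS.
#'
#' @param lf a `lead_field`.
#' @param path file path.
#' @return `save_lead_field` returns the path invisibly; `load_lead_field`
#'   the restored object.
#' @export
save_lead_field <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  saveRDS(lf, path)
  invisible(path)
}

#' @rdname save_lead_field
#' @export
load_lead_field <- function(path) {
  lf <- readRDS(path)
  stopifnot(inherits(lf, "lead_field"))
  lf
}
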