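# Shared fixtures and independent oracles, built in code at test time.

# Dense matrix of a linear operator on n-vectors (columns = images of basis
# vectors). Used to build explicit oracles on tiny grids.
dense_operator <- function(op, n, complex = FALSE) {
  M <- matrix(if (complex) complex(real = 0) else 0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- 1
    M[, j] <- as.vector(op(e))
  }
  M
}

# Forward-difference matrix along one axis of a d-grid with zero padding,
# built from index arithmetic (independent of the package implementation).
dense_gradient <- function(d, axis) {
  n <- prod(d)
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  lin <- function(m) m[, 1] + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]
  G <- matrix(0, n, n)
  nxt <- idx
  nxt[, axis] <- nxt[, axis] + 1
  ok <- nxt[, axis] <= d[axis]
  rows <- seq_len(n)
  G[cbind(rows, rows)] <- -1
  G[cbind(rows[ok], lin(nxt[ok, , drop = FALSE]))] <-
    G[cbind(rows[ok], lin(nxt[ok, , drop = FALSE]))] + 1
  G
}

# Accelerated proximal-style solver (FISTA on the smoothed objective)
#   J(x) = 0.5 * cw * ||D x - t||^2 + lambda * sum_i m_i |G_i x|_eps
# with dense (possibly complex) D and dense real G_i. Independent of the
# package's nonlinear-CG path.
fista_l1_dense <- function(D, target, cw, Gs, ms, lambda, eps, x0,
                           n_iter = 20000) {
  rho <- function(g) sqrt(g^2 + eps^2)
  Dh <- Conj(t(D))
  L <- cw * max(svd(D)$d)^2 +
    lambda * sum(vapply(Gs, function(G) max(svd(G)$d)^2, numeric(1))) / eps
  gradf <- function(x) {
    g <- cw * Re(Dh %*% (D %*% x - target))
    for (i in seq_along(Gs)) {
      gi <- Gs[[i]] %*% x
      g <- g + lambda * t(Gs[[i]]) %*% (ms[[i]] * gi / rho(gi))
    }
    as.vector(g)
  }
  x <- x0
  y <- x0
  tk <- 1
  for (it in seq_len(n_iter)) {
    x_new <- y - gradf(y) / L
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + ((tk - 1) / t_new) * (x_new - x)
    x <- x_new
    tk <- t_new
  }
  x
}

# ---------------------------------------------------------------------------
# Scaled-phantom study products, computed once and shared by the acceptance
# tests (noise seed fixed at 42 for the whole suite).
.study_env <- new.env(parent = emptyenv())

study_products <- function() {
  if (!is.null(.study_env$s)) {
    return(.study_env$s)
  }
  spec <- phantom_spec()
  sim <- simulate_acquisition(spec, seed = 42)
  cfg <- recon_config()
  delta <- vol3d(vol_data(sim$delta) * sim$brain_mask, sim$delta$voxel_size)
  w <- sim$brain_mask
  kern <- make_dipole_kernel(dim(vol_data(delta)), delta$voxel_size)
  m_nma <- make_magic_angle_mask(kern, cfg$m_th)
  m_h <- make_highfreq_weight(dim(vol_data(delta)), delta$voxel_size,
                              cfg$k_th, cfg$k_cur, cfg$kth_scale)
  chi_l <- wls_cg(delta, w, kern, cfg$n_l)
  ns_grid <- 1:10
  chi_s_l <- list()
  chi_p_l <- list()
  final_l <- list()
  for (ns in ns_grid) {
    chi_s_l[[ns]] <- wls_cg(delta, w, kern, ns)
    edges <- build_edge_masks(chi_s_l[[ns]], w > 0, cfg$alpha_rule)
    chi_p_l[[ns]] <- solve_masked_l1(chi_l, m_nma, edges, cfg$lambda, cfg)
    final_l[[ns]] <- combine_highfreq(chi_p_l[[ns]], chi_s_l[[ns]], m_h)
  }
  small_roi <- sim$rois$vein[["d0.25_chi0.10"]]
  cv_ns <- vapply(ns_grid, function(ns) cv(final_l[[ns]], small_roi),
                  numeric(1))
  chi_tkd <- tkd_invert(delta, kern, cfg$tkd_threshold, cfg$tkd_mode)
  chi_medi <- medi_baseline(delta, w, sim$magnitude, cfg$medi_lambda, cfg,
                            kern)
  .study_env$s <- list(
    spec = spec, sim = sim, cfg = cfg, delta = delta, w = w, kern = kern,
    m_nma = m_nma, m_h = m_h, chi_l = chi_l, chi_s_l = chi_s_l,
    chi_p_l = chi_p_l, final_l = final_l, cv_ns = cv_ns,
    chi_mudick = final_l[[cfg$n_s]], chi_tkd = chi_tkd, chi_medi = chi_medi
  )
  .study_env$s
}
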